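# Synthetic Zipfian lexicons and the deterministic demonstration fixture,
# so every pipeline stage is testable without any corpus download.

#' Specification of a synthetic Zipfian lexicon
#'
#' Frequencies follow a power law over ranks,
#' `freq(r) = max(1, round(top_freq * r^-zipf_exponent))`; forms are random
#' distinct strings, consonant-vowel alternating by default so that CVCV
#' coding and n-gram chains are exercised realistically.
#'
#' @param n_types number of word types to generate.
#' @param zipf_exponent power-law exponent (1 gives the canonical slope -1
#'   rank-frequency law).
#' @param top_freq frequency of rank 1; with the default 1e5 the rounding
#'   floor never flattens the law for a few thousand types.
#' @param alphabet named list with `consonants` and `vowels` character
#'   vectors.
#' @param length_mean,length_sd word-length distribution (rounded normal,
#'   clipped to `length_range`); the defaults emulate the 7-8 letter mode
#'   typical of Romance-language lexicons.
#' @param length_range admissible lengths, within 1..30.
#' @param category_mix named numeric vector of category proportions
#'   (summing to 1); the default mirrors a POS-tagged corpus dominated by
#'   verbs and nouns, with adjectives about half as many and closed
#'   classes rare.
#' @param cv_alternate if `FALSE`, sample letters uniformly instead of
#'   alternating consonants and vowels.
#' @param seed integer seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_types = 1000L, zipf_exponent = 1,
                           top_freq = 1e5,
                           alphabet = list(
                             consonants = strsplit("bcdfglmnprstvz",
                                                   "")[[1]],
                             vowels = strsplit("aeiou", "")[[1]]),
                           length_mean = 7, length_sd = 2.5,
                           length_range = c(2L, 14L),
                           category_mix = c(ver = 0.45, nom = 0.34,
                                            adj = 0.19, adv = 0.008,
                                            gram = 0.007, num = 0.005),
                           cv_alternate = TRUE, seed = 1L) {
  if (n_types < 1L) stop("n_types must be >= 1", call. = FALSE)
  if (zipf_exponent <= 0) stop("zipf_exponent must be > 0", call. = FALSE)
  if (abs(sum(category_mix) - 1) > 1e-8) {
    stop("category_mix proportions must sum to 1", call. = FALSE)
  }
  .assert_categories(names(category_mix))
  list(n_types = as.integer(n_types), zipf_exponent = zipf_exponent,
       top_freq = top_freq, alphabet = alphabet,
       length_mean = length_mean, length_sd = length_sd,
       length_range = as.integer(length_range),
       category_mix = category_mix, cv_alternate = isTRUE(cv_alternate),
       seed = as.integer(seed))
}

.random_forms <- function(n, spec) {
  cons <- spec$alphabet$consonants
  vows <- spec$alphabet$vowels
  pool <- c(cons, vows)
  out <- character(0L)
  for (round in 1:100) {
    need <- n - length(out)
    if (need <= 0L) break
    lens <- pmin(pmax(round(stats::rnorm(2L * need, spec$length_mean,
                                         spec$length_sd)),
                      spec$length_range[1]), spec$length_range[2])
    forms <- vapply(lens, function(L) {
      if (spec$cv_alternate) {
        start_c <- stats::runif(1) < 0.7
        sets <- if (start_c) list(cons, vows) else list(vows, cons)
        paste(vapply(seq_len(L), function(i) {
          sample(sets[[(i - 1L) %% 2L + 1L]], 1L)
        }, character(1L)), collapse = "")
      } else {
        paste(sample(pool, L, replace = TRUE), collapse = "")
      }
    }, character(1L))
    out <- unique(c(out, forms))
  }
  if (length(out) < n) {
    stop("alphabet too small to produce ", n, " distinct forms",
         call. = FALSE)
  }
  out[seq_len(n)]
}

#' Generate a synthetic Zipfian lexicon
#'
#' @param spec a [synthetic_spec()].
#' @return named list of per-category data.frames (`orthography`,
#'   `gram_cat`, `ortho_freq`), the same shape [read_frequency_list()]
#'   returns; identical output for identical seeds.
#' @export
#' @examples
#' lists <- generate_synthetic_lexicon(synthetic_spec(n_types = 50))
generate_synthetic_lexicon <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  forms <- .random_forms(spec$n_types, spec)
  ranks <- seq_len(spec$n_types)
  freqs <- pmax(1, round(spec$top_freq * ranks^(-spec$zipf_exponent)))
  cats <- sample(names(spec$category_mix), spec$n_types, replace = TRUE,
                 prob = spec$category_mix)
  df <- data.frame(orthography = forms, gram_cat = cats,
                   ortho_freq = as.integer(freqs),
                   stringsAsFactors = FALSE)
  split(df, factor(df$gram_cat,
                   levels = intersect(gram_categories(), unique(cats))))
}

#' Write synthetic frequency lists to a directory
#'
#' One `<category>.txt` per category, in the `form count` format that
#' [read_frequency_list()] parses.
#'
#' @param lists output of [generate_synthetic_lexicon()].
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_frequency_lists <- function(lists, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(lists), function(cat) {
    p <- file.path(dir, paste0(cat, ".txt"))
    writeLines(paste(lists[[cat]]$orthography, lists[[cat]]$ortho_freq),
               p, useBytes = TRUE)
    p
  }, character(1L))
  invisible(paths)
}

#' Deterministic demonstration lexicon
#'
#' A small fixed set of per-category frequency lists embedding the classic
#' worked examples: "cachorro" as a noun with frequency 397, "ativa" as a
#' three-way homograph (adjective, noun, verb), the wildcard demonstration
#' sets ("amor", "anos", "aloe", "após", "amora"; "ama", "amei", "amava"),
#' and filler words covering hyphens, accents, digits and an open
#' frequency interval (counts 7, 8, 9), so that searches and statistics
#' are non-degenerate. Byte-identical across calls.
#'
#' Corpus-relative printed values from the full source corpus (uniqueness
#' point, neighborhood, OLD20 of "cachorro") are not reproduced here: they
#' depend on the complete 200k-type lexicon, not on any fixture.
#'
#' @return named list of per-category data.frames (`orthography`,
#'   `gram_cat`, `ortho_freq`).
#' @export
demo_frequency_lists <- function() {
  mk <- function(cat, ...) {
    v <- c(...)
    data.frame(orthography = names(v), gram_cat = cat,
               ortho_freq = as.integer(v), stringsAsFactors = FALSE)
  }
  list(
    nom = mk("nom",
             casa = 120, cachorro = 397, cama = 80, cana = 15, dama = 12,
             amor = 50, anos = 40, aloe = 7, amora = 9, ativa = 8,
             dedo = 30, roda = 25, "tábua" = 5, "guarda-chuva" = 3,
             flor = 18, flores = 6),
    ver = mk("ver",
             ama = 60, amei = 11, amava = 13, comer = 35, falas = 9,
             ativa = 6, viajou = 4),
    adj = mk("adj",
             ativa = 20, caro = 22, linda = 10, velho = 17),
    adv = mk("adv", quase = 28, sempre = 45),
    gram = mk("gram",
              "após" = 200, com = 900, que = 1500, "até" = 300),
    num = mk("num", "9" = 14, "3" = 22))
}
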