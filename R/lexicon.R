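# Lexicon assembly: the 25-column table, totals, ordering, CSV round trip.

#' Assemble a lexicon from cleaned frequency entries
#'
#' Takes cleaned per-category entries (see [normalize_and_merge()] and
#' [filter_entries()]) and computes the full 25-column lexicon:
#' frequency transforms, orthographic structure, corpus-relative measures,
#' positional n-gram frequency sums, grammatical information, a seeded
#' random column, and the identity column.
#'
#' Entries are ordered by descending orthographic frequency, then by
#' orthography under the package collation (letters a-z, digits 0-9,
#' hyphen; accents collate with their base letter), then by category order;
#' `id` is the resulting position.
#'
#' @param entries data.frame with columns `orthography`, `gram_cat`,
#'   `ortho_freq` (cleaned, one row per word type within category), or a
#'   named list of such data.frames which will be row-bound.
#' @param seed integer seed for the `random` column.
#' @param lemmas optional data.frame (same shape) of lemma lists, used only
#'   for per-category lemma totals.
#' @param gram_inf_rules optional suffix rule table for
#'   [annotate_grammatical_info()]; `NULL` leaves `gram_inf` empty.
#' @param cvcv_mapping character-class mapping for [cvcv_code()].
#' @param old20_k neighborhood size for [old20()].
#' @return a `lexicon` object: list with `entries` (25-column data.frame),
#'   `token_total`, `type_total`, `category_totals` (per-category token and
#'   type counts), and `lemma_totals` (or `NULL`).
#' @export
assemble_lexicon <- function(entries, seed, lemmas = NULL,
                             gram_inf_rules = NULL,
                             cvcv_mapping = cvcv_default_mapping(),
                             old20_k = 20L) {
  if (is.list(entries) && !is.data.frame(entries)) {
    entries <- do.call(rbind, c(entries, list(make.row.names = FALSE)))
  }
  if (is.null(entries) || nrow(entries) == 0L) {
    stop("empty lexicon", call. = FALSE)
  }
  .assert_categories(entries$gram_cat)
  if (missing(seed)) stop("a seed for the random column is required",
                          call. = FALSE)

  ortho <- entries$orthography
  freq <- as.integer(entries$ortho_freq)
  cats <- entries$gram_cat

  # total order: frequency desc, collation, category order as final tie
  cat_rank <- match(cats, gram_categories())
  ord <- order(-freq, .collation_primary(ortho), ortho, cat_rank,
               method = "radix")
  ortho <- ortho[ord]; freq <- freq[ord]; cats <- cats[ord]

  token_total <- sum(freq)
  type_total <- length(ortho)

  lx <- data.frame(orthography = ortho, gram_cat = cats,
                   stringsAsFactors = FALSE, check.names = FALSE)
  lx$gram_inf <- annotate_grammatical_info(ortho, cats, gram_inf_rules)
  lx$ortho_freq <- freq
  lx[["ortho_freq/M"]] <- per_million(freq, token_total)
  lx$log10_ortho_freq <- log10_frequency(pmax(freq, 1L))
  lx$zipf_scale <- zipf_scale(pmax(freq, 1L), token_total)
  lx$zipf_rank <- zipf_rank(freq)
  lx$nb_letters <- letter_count(ortho)

  hp <- homograph_profile(lx)
  lx$nb_homogr <- hp$nb_homogr
  lx$homographs <- hp$homographs

  pooled <- unique(ortho)
  lx$pu_ortho <- uniqueness_point(ortho, pooled)
  lx$ortho_neigh <- coltheart_n(ortho, pooled)
  lx$old20 <- if (length(pooled) > 1L) {
    round(old20(ortho, pooled, k = old20_k), 4L)
  } else {
    rep(NA_real_, type_total)
  }

  lx$cvcv_ortho <- cvcv_code(ortho, cvcv_mapping)
  lx$bigrams <- ngram_decompose(ortho, 2L)
  lx$trigrams <- ngram_decompose(ortho, 3L)
  lx$rev_ortho <- reverse_form(ortho)
  lx$rev_cvcv_ortho <- reverse_form(lx$cvcv_ortho)
  lx$rev_bigrams <- ngram_decompose(lx$rev_ortho, 2L)
  lx$rev_trigrams <- ngram_decompose(lx$rev_ortho, 3L)

  bigram_table <- build_ngram_table(lx, 2L)
  trigram_table <- build_ngram_table(lx, 3L)
  lx$bigram_freq <- word_ngram_frequency(ortho, cats, bigram_table)
  lx$trigram_freq <- word_ngram_frequency(ortho, cats, trigram_table)

  set.seed(as.integer(seed))
  lx$random <- round(stats::runif(type_total), 8L)
  lx$id <- seq_len(type_total)

  lx <- lx[, lexicon_columns()]

  cat_tokens <- tapply(freq, factor(cats, levels = gram_categories()), sum)
  cat_types <- table(factor(cats, levels = gram_categories()))
  category_totals <- data.frame(
    gram_cat = gram_categories(),
    tokens = as.integer(ifelse(is.na(cat_tokens), 0L, cat_tokens)),
    types = as.integer(cat_types),
    stringsAsFactors = FALSE)

  lemma_totals <- NULL
  if (!is.null(lemmas)) {
    if (is.list(lemmas) && !is.data.frame(lemmas)) {
      lemmas <- do.call(rbind, c(lemmas, list(make.row.names = FALSE)))
    }
    lt <- table(factor(lemmas$gram_cat, levels = gram_categories()))
    lemma_totals <- data.frame(gram_cat = gram_categories(),
                               lemmas = as.integer(lt),
                               stringsAsFactors = FALSE)
  }

  structure(list(entries = lx,
                 token_total = token_total,
                 type_total = type_total,
                 category_totals = category_totals,
                 lemma_totals = lemma_totals,
                 seed = as.integer(seed)),
            class = "lexicon")
}

#' Build a lexicon from raw per-category lists
#'
#' Convenience pipeline: reads (or accepts) per-category raw entries, runs
#' [normalize_and_merge()] and [filter_entries()] on each category, and
#' assembles the lexicon.
#'
#' @param sources named list: category code -> file path, character vector
#'   of lines, or data.frame of raw entries.
#' @param seed seed for the random column.
#' @param rules cleaning rules, see [cleaning_rules()].
#' @param ... passed to [assemble_lexicon()].
#' @return a `lexicon`; the combined `cleaning_report` is attached as
#'   attribute `"cleaning"`.
#' @export
build_lexicon <- function(sources, seed, rules = cleaning_rules(), ...) {
  .assert_categories(names(sources))
  reports <- list()
  cleaned <- lapply(names(sources), function(cat) {
    src <- sources[[cat]]
    raw <- if (is.data.frame(src)) src else read_frequency_list(src, cat)
    nm <- normalize_and_merge(raw)
    fl <- filter_entries(nm$entries, rules)
    reports[[cat]] <<- list(normalize = nm$report, filter = fl$report)
    fl$entries
  })
  lex <- assemble_lexicon(do.call(rbind, cleaned), seed = seed, ...)
  attr(lex, "cleaning") <- reports
  lex
}

#' @export
print.lexicon <- function(x, ...) {
  cat("Lexicon:", x$type_total, "word types,",
      format(x$token_total, big.mark = ","), "word tokens\n")
  tt <- x$category_totals[x$category_totals$types > 0L, , drop = FALSE]
  for (i in seq_len(nrow(tt))) {
    cat(sprintf("  %-5s %7d types %12s tokens\n", tt$gram_cat[i],
                tt$types[i], format(tt$tokens[i], big.mark = ",")))
  }
  invisible(x)
}

#' Write a lexicon to CSV
#'
#' The 25 canonical columns, in order, RFC 4180 quoting, UTF-8.
#'
#' @param lexicon a `lexicon` or a data.frame of its entries.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_lexicon_csv <- function(lexicon, path) {
  entries <- if (inherits(lexicon, "lexicon")) lexicon$entries else lexicon
  utils::write.csv(entries, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a lexicon CSV written by [write_lexicon_csv()]
#'
#' @param path CSV path.
#' @return a `lexicon` object with totals recomputed from the entries.
#' @export
read_lexicon_csv <- function(path) {
  entries <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                             stringsAsFactors = FALSE,
                             colClasses = c(orthography = "character"))
  missing_cols <- setdiff(lexicon_columns(), names(entries))
  if (length(missing_cols) > 0L) {
    stop("not a lexicon CSV; missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  entries$gram_inf[is.na(entries$gram_inf)] <- ""
  cat_tokens <- tapply(entries$ortho_freq,
                       factor(entries$gram_cat, levels = gram_categories()),
                       sum)
  cat_types <- table(factor(entries$gram_cat, levels = gram_categories()))
  structure(list(entries = entries,
                 token_total = sum(entries$ortho_freq),
                 type_total = nrow(entries),
                 category_totals = data.frame(
                   gram_cat = gram_categories(),
                   tokens = as.integer(ifelse(is.na(cat_tokens), 0L,
                                              cat_tokens)),
                   types = as.integer(cat_types),
                   stringsAsFactors = FALSE),
                 lemma_totals = NULL,
                 seed = NA_integer_),
            class = "lexicon")
}
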