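# Pseudoword generation by left-to-right chain sampling over positional
# n-gram tables, plus a legality score for candidate strings.

#' N-gram legality score of a candidate string
#'
#' The sum of positional type counts of the string's bounded n-grams for a
#' grammatical category: the same quantity as [word_ngram_frequency()]
#' applied to an arbitrary candidate. Unattested n-grams contribute 0, so
#' higher scores mean more lexicon-like sub-lexical structure; a string
#' whose every positional n-gram is attested has every window scoring >= 1.
#'
#' @inheritParams word_ngram_frequency
#' @return numeric vector of scores.
#' @export
ngram_legality <- function(form, gram_cat, table,
                           collapse = c("none", "position",
                                        "category", "both")) {
  word_ngram_frequency(form, gram_cat, table, collapse = match.arg(collapse))
}

#' Pseudoword generation settings
#'
#' @param gram_cat grammatical category whose n-gram structure to imitate.
#' @param count number of pseudowords requested.
#' @param length_min,length_max admissible word length in letters
#'   (1 <= min <= max <= 30).
#' @param order `"bigram"` or `"trigram"` chain sampling.
#' @param seed integer seed (same seed, same output).
#' @param max_attempts sampling budget before giving up; defaults to
#'   `1000 * count`.
#' @param uniform if `TRUE`, candidate extensions are sampled uniformly
#'   instead of proportionally to their positional type counts (useful for
#'   stimulus balancing).
#' @return a `pseudoword_config` list.
#' @export
pseudoword_config <- function(gram_cat, count, length_min = 3L,
                              length_max = 10L, order = c("bigram",
                                                          "trigram"),
                              seed = 1L, max_attempts = NULL,
                              uniform = FALSE) {
  order <- match.arg(order)
  .assert_categories(gram_cat)
  if (count < 1L) stop("count must be >= 1", call. = FALSE)
  if (!(length_min >= 1L && length_min <= length_max && length_max <= 30L)) {
    stop("lengths must satisfy 1 <= min <= max <= 30", call. = FALSE)
  }
  list(gram_cat = gram_cat, count = as.integer(count),
       length_min = as.integer(length_min),
       length_max = as.integer(length_max),
       order = order, seed = as.integer(seed),
       max_attempts = if (is.null(max_attempts)) 1000L * as.integer(count)
                      else as.integer(max_attempts),
       uniform = isTRUE(uniform))
}

# One chain-sampling attempt over position-indexed windows of the bounded
# string "#word#". The chain keeps the bounded prefix built so far (sb):
# the window at position p must reproduce sb's last n-1 characters and
# appends one more (the whole window at p = 1). Returns NA on a dead end
# or a length-bound violation.
.sample_chain <- function(by_pos, n, length_min, length_max, uniform) {
  pick_from <- function(cands) {
    w <- if (uniform) rep(1, nrow(cands)) else cands$type_count
    cands$ngram[sample.int(nrow(cands), 1L, prob = w)]
  }
  cands <- by_pos[["1"]]
  if (is.null(cands) || nrow(cands) == 0L) return(NA_character_)
  sb <- pick_from(cands)
  p <- 2L
  repeat {
    if (endsWith(sb, "#")) {
      word <- substr(sb, 2L, nchar(sb) - 1L)
      if (nchar(word) >= length_min && nchar(word) <= length_max) {
        return(word)
      }
      return(NA_character_)
    }
    cands <- by_pos[[as.character(p)]]
    if (is.null(cands) || nrow(cands) == 0L) return(NA_character_)
    suffix <- substring(sb, nchar(sb) - n + 2L)
    cands <- cands[substr(cands$ngram, 1L, n - 1L) == suffix, ,
                   drop = FALSE]
    if (nrow(cands) > 0L) {
      terminal <- endsWith(cands$ngram, "#")
      final_len <- nchar(sb) - 1L        # letters if we close the word now
      partial_len <- nchar(sb)           # letters if we extend instead
      keep <- (terminal & final_len >= length_min &
                 final_len <= length_max) |
              (!terminal & partial_len <= length_max)
      cands <- cands[keep, , drop = FALSE]
    }
    if (nrow(cands) == 0L) return(NA_character_)
    nxt <- pick_from(cands)
    sb <- paste0(sb, substring(nxt, n))
    p <- p + 1L
  }
}

#' Generate pseudowords from a positional n-gram table
#'
#' Builds candidate strings left to right: start from a word-initial
#' n-gram (`#x...`), repeatedly extend with an n-gram attested at the next
#' position that overlaps the current suffix, and stop on a word-final
#' n-gram (`...x#`) within the length bounds. Extensions are sampled with
#' probability proportional to their positional type counts (or uniformly).
#' Candidates that spell a word already in the lexicon, fall outside the
#' length bounds, or duplicate an earlier pseudoword are rejected.
#'
#' @param config a [pseudoword_config()].
#' @param table an `ngram_table` for the config's category and order
#'   (n = 2 for `"bigram"`, 3 for `"trigram"`).
#' @param lexicon a `lexicon` (or data.frame with `orthography`) whose
#'   forms are excluded.
#' @return character vector of up to `count` distinct pseudowords. If the
#'   sampling budget is exhausted first, the partial list is returned with
#'   attribute `"warning"` describing the shortfall.
#' @export
generate_pseudowords <- function(config, table, lexicon) {
  n_expected <- if (config$order == "bigram") 2L else 3L
  if (table$n != n_expected) {
    stop("table order (n = ", table$n, ") does not match config order '",
         config$order, "'", call. = FALSE)
  }
  entries <- if (inherits(lexicon, "lexicon")) lexicon$entries else lexicon
  excluded <- unique(entries$orthography)
  cts <- table$counts[table$counts$gram_cat == config$gram_cat, ,
                      drop = FALSE]
  if (nrow(cts) == 0L) {
    stop("the n-gram table has no cells for category '", config$gram_cat,
         "'", call. = FALSE)
  }
  by_pos <- split(cts[, c("ngram", "type_count")], cts$position)

  set.seed(config$seed)
  out <- character(0L)
  attempts <- 0L
  while (length(out) < config$count && attempts < config$max_attempts) {
    attempts <- attempts + 1L
    cand <- .sample_chain(by_pos, table$n, config$length_min,
                          config$length_max, config$uniform)
    if (is.na(cand) || cand %in% excluded || cand %in% out) next
    out <- c(out, cand)
  }
  if (length(out) < config$count) {
    attr(out, "warning") <- sprintf(
      "generated %d of %d pseudowords in %d attempts",
      length(out), config$count, attempts)
  }
  out
}
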