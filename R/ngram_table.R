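# Positional n-gram tables: type counts by (category, position, n-gram),
# word-level n-gram frequency sums, TSV export.

.ngram_key <- function(gram_cat, position, ngram) {
  paste(gram_cat, position, ngram, sep = "\r")
}

#' Build a positional n-gram table
#'
#' Counts, for every (grammatical category, window position, n-gram) cell,
#' the number of distinct word types whose bounded decomposition places
#' that n-gram at that position. Raw token frequencies are ignored: a type
#' counts once per cell regardless of how frequent it is.
#'
#' @param lexicon a `lexicon` object, or a data.frame with columns
#'   `orthography` and `gram_cat`.
#' @param n 2 for bigrams, 3 for trigrams.
#' @return an `ngram_table`: list with `n` and `counts`
#'   (data.frame `gram_cat`, `position`, `ngram`, `type_count`).
#' @export
build_ngram_table <- function(lexicon, n) {
  if (!n %in% c(2L, 3L)) stop("n must be 2 or 3", call. = FALSE)
  entries <- if (inherits(lexicon, "lexicon")) lexicon$entries else lexicon
  types <- unique(entries[, c("orthography", "gram_cat")])
  grams <- lapply(types$orthography, .bounded_windows, n = n)
  len <- lengths(grams)
  long <- data.frame(
    gram_cat = rep(types$gram_cat, len),
    position = unlist(lapply(len, seq_len)),
    ngram = unlist(grams),
    stringsAsFactors = FALSE)
  key <- .ngram_key(long$gram_cat, long$position, long$ngram)
  first <- !duplicated(key)
  counts <- long[first, , drop = FALSE]
  counts$type_count <- as.integer(tabulate(match(key, key[first])))
  rownames(counts) <- NULL
  structure(list(n = as.integer(n), counts = counts), class = "ngram_table")
}

#' @export
print.ngram_table <- function(x, ...) {
  cat("Positional ", x$n, "-gram table: ", nrow(x$counts),
      " (category, position, n-gram) cells\n", sep = "")
  invisible(x)
}

# Marginal count vectors for the requested collapse mode, as a named
# numeric lookup (names are composite keys).
.ngram_lookup <- function(table, collapse = c("none", "position",
                                              "category", "both")) {
  collapse <- match.arg(collapse)
  cts <- table$counts
  key <- switch(collapse,
    none     = .ngram_key(cts$gram_cat, cts$position, cts$ngram),
    position = paste(cts$gram_cat, cts$ngram, sep = "\r"),
    category = paste(cts$position, cts$ngram, sep = "\r"),
    both     = cts$ngram)
  rowsum(cts$type_count, key)
}

#' Positional type count of one n-gram
#'
#' @param table an `ngram_table`.
#' @param gram_cat category code.
#' @param position 1-based window position.
#' @param ngram the n-gram string (with `#` bounds where applicable).
#' @return integer count; 0 for an absent cell.
#' @export
ngram_count <- function(table, gram_cat, position, ngram) {
  cts <- table$counts
  hit <- cts$gram_cat == gram_cat & cts$position == position &
    cts$ngram == ngram
  if (any(hit)) cts$type_count[hit][1L] else 0L
}

#' Word-level n-gram frequency
#'
#' Sums the table's type counts over a word's bounded n-gram decomposition.
#' By default the positional, category-specific counts are summed; the
#' `collapse` switch instead sums position-collapsed and/or
#' category-collapsed marginals. Unattested n-grams contribute 0.
#'
#' @param form character vector of forms to score.
#' @param gram_cat category code(s), recycled to the length of `form`
#'   (ignored when category is collapsed).
#' @param table an `ngram_table` built with the matching `n`.
#' @param collapse `"none"` (default), `"position"`, `"category"`, or
#'   `"both"`.
#' @return numeric vector of summed type counts.
#' @export
word_ngram_frequency <- function(form, gram_cat, table,
                                 collapse = c("none", "position",
                                              "category", "both")) {
  collapse <- match.arg(collapse)
  if (!inherits(table, "ngram_table")) {
    stop("table must be an ngram_table", call. = FALSE)
  }
  lookup <- .ngram_lookup(table, collapse)
  gram_cat <- rep_len(gram_cat, length(form))
  vapply(seq_along(form), function(i) {
    grams <- .bounded_windows(form[i], table$n)
    key <- switch(collapse,
      none     = .ngram_key(gram_cat[i], seq_along(grams), grams),
      position = paste(gram_cat[i], grams, sep = "\r"),
      category = paste(seq_along(grams), grams, sep = "\r"),
      both     = grams)
    sum(lookup[match(key, rownames(lookup))], na.rm = TRUE)
  }, numeric(1L))
}

#' Export an n-gram table as TSV
#'
#' Writes columns `gram_cat`, `position`, `ngram`, `type_count`,
#' tab-separated, UTF-8.
#'
#' @param table an `ngram_table`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_ngram_tsv <- function(table, path) {
  utils::write.table(table$counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
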