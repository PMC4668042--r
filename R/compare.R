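# Cross-corpus comparison: homograph collapsing, alignment, Zipf-scale
# correlations, Fisher r-to-z contrasts, containment, discrepancy lists,
# and within-lexicon distribution profiles.

#' A named external frequency list
#'
#' @param name corpus label.
#' @param forms character vector of orthographic forms (lower-cased on
#'   construction; accents preserved).
#' @param freqs raw frequencies aligned with `forms`.
#' @param token_total corpus token total; defaults to `sum(freqs)` (external
#'   lists rarely ship an independent total).
#' @return a `corpus_freq_list`.
#' @export
corpus_freq_list <- function(name, forms, freqs, token_total = NULL) {
  if (length(forms) != length(freqs)) {
    stop("forms and freqs must be aligned", call. = FALSE)
  }
  if (any(freqs < 0)) stop("frequencies must be >= 0", call. = FALSE)
  forms <- tolower(forms)
  if (anyDuplicated(forms)) {
    s <- rowsum(as.numeric(freqs), forms)
    freqs <- as.vector(s)
    forms <- rownames(s)
  }
  structure(list(name = name, forms = forms, freqs = as.numeric(freqs),
                 token_total = if (is.null(token_total)) sum(freqs)
                               else as.numeric(token_total)),
            class = "corpus_freq_list")
}

#' Read a two-column frequency TSV as a corpus list
#'
#' @param path TSV with columns form and count (no header expected; a
#'   header line is detected and skipped when its count field is not
#'   numeric).
#' @param name corpus label; defaults to the file name.
#' @return a `corpus_freq_list`.
#' @export
read_corpus_tsv <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8",
                           colClasses = c("character", "character"))
  if (nrow(raw) > 0L && !grepl("^[0-9.]+$", raw[[2]][1L])) {
    raw <- raw[-1L, , drop = FALSE]
  }
  corpus_freq_list(name, raw[[1]], as.numeric(raw[[2]]))
}

#' Collapse homographs into a form-level frequency list
#'
#' Sums the raw frequencies of entries sharing an orthographic form across
#' grammatical categories, yielding one record per distinct form (the
#' shape external, untagged corpora use).
#'
#' @param lexicon a `lexicon` object.
#' @param name label for the resulting corpus list.
#' @return a `corpus_freq_list` with `token_total` = the lexicon's.
#' @export
collapse_homographs <- function(lexicon, name = "lexicon") {
  e <- lexicon$entries
  s <- rowsum(as.numeric(e$ortho_freq), e$orthography)
  corpus_freq_list(name, rownames(s), as.vector(s),
                   token_total = lexicon$token_total)
}

#' Align corpora on their common attested forms
#'
#' Restricts a set of corpus lists to the forms present with frequency > 0
#' in every list.
#'
#' @param lists a list of `corpus_freq_list` objects (>= 2).
#' @return data.frame: column `form` plus one frequency column per corpus
#'   (named by corpus label); zero rows when the intersection is empty.
#' @export
align_corpora <- function(lists) {
  if (length(lists) < 2L) stop("need at least two corpora", call. = FALSE)
  attested <- lapply(lists, function(x) x$forms[x$freqs > 0])
  common <- Reduce(intersect, attested)
  common <- sort(common, method = "radix")
  out <- data.frame(form = common, stringsAsFactors = FALSE)
  for (x in lists) {
    out[[x$name]] <- x$freqs[match(common, x$forms)]
  }
  out
}

#' Pearson correlation matrix of Zipf-scale frequencies
#'
#' Converts each corpus column of an aligned table to the Zipf scale using
#' that corpus's own token total, then correlates all pairs.
#'
#' @param aligned output of [align_corpora()] (>= 3 common forms).
#' @param totals named numeric vector of token totals, one per corpus
#'   column of `aligned`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
zipf_correlation <- function(aligned, totals) {
  corpora <- setdiff(names(aligned), "form")
  if (nrow(aligned) < 3L) {
    stop("need at least 3 aligned forms to correlate", call. = FALSE)
  }
  if (!all(corpora %in% names(totals))) {
    stop("totals must be named for every corpus column", call. = FALSE)
  }
  z <- vapply(corpora, function(nm) {
    zipf_scale(aligned[[nm]], totals[[nm]], digits = NULL)
  }, numeric(nrow(aligned)))
  stats::cor(z, method = "pearson")
}

#' Fisher r-to-z contrast of two correlations
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, the
#' independent-samples test of the difference between two Pearson
#' correlations.
#'
#' @param r1,r2 correlations, strictly inside (-1, 1).
#' @param n1,n2 sample sizes, > 3.
#' @return the z statistic.
#' @export
#' @examples
#' fisher_rz_contrast(0.8, 45968, 0.7, 45968)
fisher_rz_contrast <- function(r1, n1, r2, n2) {
  if (any(abs(c(r1, r2)) >= 1)) {
    stop("correlations must be strictly inside (-1, 1)", call. = FALSE)
  }
  if (any(c(n1, n2) <= 3)) stop("sample sizes must exceed 3", call. = FALSE)
  (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
}

#' Pairwise word-type containment matrix
#'
#' Cell (A, B) is the percentage of A's word types that also occur in B:
#' `100 * |types(A) & types(B)| / |types(A)|`. The diagonal is 100.
#'
#' @param lists a list of `corpus_freq_list` objects (>= 2, none empty).
#' @return square percentage matrix with corpus labels as dimnames.
#' @export
containment_matrix <- function(lists) {
  if (length(lists) < 2L) stop("need at least two corpora", call. = FALSE)
  sizes <- vapply(lists, function(x) length(x$forms), integer(1L))
  if (any(sizes == 0L)) stop("empty corpus", call. = FALSE)
  nms <- vapply(lists, `[[`, character(1L), "name")
  k <- length(lists)
  m <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      m[i, j] <- 100 * length(intersect(lists[[i]]$forms,
                                        lists[[j]]$forms)) / sizes[i]
    }
  }
  m
}

#' Over- and under-estimated words between two corpora
#'
#' Overestimated: the `k` most frequent forms of corpus A that are absent
#' from corpus B. Underestimated: the `k` most frequent forms of B absent
#' from A. Each list carries the word's Zipf-scale value in its own corpus
#' and is ordered by descending frequency.
#'
#' @param a,b `corpus_freq_list` objects (A is the reference corpus).
#' @param k list length (default 10).
#' @return list with data.frames `overestimated` and `underestimated`
#'   (columns `form`, `freq`, `zipf_scale`).
#' @export
estimation_discrepancies <- function(a, b, k = 10L) {
  one_side <- function(x, other) {
    absent <- !(x$forms %in% other$forms)
    forms <- x$forms[absent]
    freqs <- x$freqs[absent]
    ord <- order(-freqs, forms, method = "radix")
    take <- utils::head(ord, k)
    data.frame(form = forms[take], freq = freqs[take],
               zipf_scale = zipf_scale(pmax(freqs[take], 1),
                                       x$token_total),
               stringsAsFactors = FALSE)
  }
  list(overestimated = one_side(a, b), underestimated = one_side(b, a))
}

#' Outlier thresholds for [distribution_profile()]
#'
#' @param max_letters,max_neighbors,max_old20,max_homographs upper bounds;
#'   entries exceeding any bound are excluded from the profile. Use `Inf`
#'   to disable a filter.
#' @return named list of thresholds.
#' @export
profile_thresholds <- function(max_letters = 20, max_neighbors = 40,
                               max_old20 = 14, max_homographs = 5) {
  list(max_letters = max_letters, max_neighbors = max_neighbors,
       max_old20 = max_old20, max_homographs = max_homographs)
}

#' Distribution profile of a lexicon
#'
#' Applies the outlier filters (over-long words, extreme neighborhoods,
#' extreme OLD20, many-way homographs), reports the removed fraction, and
#' tabulates: word types by category, types by length within category,
#' the log10 frequency / log10 rank arrays per category (the rank-frequency
#' law view), and mean neighborhood size and mean OLD20 by length within
#' category.
#'
#' @param lexicon a `lexicon` object.
#' @param thresholds see [profile_thresholds()].
#' @return list with `removed_fraction`, `n_kept`, `types_by_category`,
#'   `types_by_length_category`, `rank_frequency` (data.frame `gram_cat`,
#'   `log10_rank`, `log10_freq`), `mean_neigh_by_length_category`,
#'   `mean_old20_by_length_category`.
#' @export
distribution_profile <- function(lexicon,
                                 thresholds = profile_thresholds()) {
  e <- lexicon$entries
  if (is.null(e) || nrow(e) == 0L) stop("empty lexicon", call. = FALSE)
  keep <- e$nb_letters <= thresholds$max_letters &
    e$ortho_neigh <= thresholds$max_neighbors &
    (is.na(e$old20) | e$old20 <= thresholds$max_old20) &
    e$nb_homogr <= thresholds$max_homographs
  removed_fraction <- mean(!keep)
  e <- e[keep, , drop = FALSE]
  cats <- factor(e$gram_cat, levels = gram_categories())

  by_cat <- as.data.frame(table(gram_cat = cats),
                          stringsAsFactors = FALSE)
  names(by_cat)[2] <- "types"

  by_len_cat <- as.data.frame(table(gram_cat = cats,
                                    nb_letters = e$nb_letters),
                              stringsAsFactors = FALSE)
  names(by_len_cat)[3] <- "types"
  by_len_cat$nb_letters <- as.integer(by_len_cat$nb_letters)
  by_len_cat <- by_len_cat[by_len_cat$types > 0L, , drop = FALSE]
  rownames(by_len_cat) <- NULL

  rf <- do.call(rbind, lapply(levels(cats), function(cc) {
    f <- sort(e$ortho_freq[e$gram_cat == cc], decreasing = TRUE)
    f <- f[f >= 1]
    if (length(f) == 0L) return(NULL)
    data.frame(gram_cat = cc, log10_rank = log10(seq_along(f)),
               log10_freq = log10(f), stringsAsFactors = FALSE)
  }))

  agg <- function(v) {
    out <- stats::aggregate(v, by = list(gram_cat = e$gram_cat,
                                         nb_letters = e$nb_letters),
                            FUN = mean, na.rm = TRUE)
    names(out)[3] <- "mean"
    out[order(out$gram_cat, out$nb_letters), , drop = FALSE]
  }

  list(removed_fraction = removed_fraction,
       n_kept = nrow(e),
       types_by_category = by_cat,
       types_by_length_category = by_len_cat,
       rank_frequency = rf,
       mean_neigh_by_length_category = agg(e$ortho_neigh),
       mean_old20_by_length_category = agg(e$old20))
}
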