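# Corpus-relative measures over the pooled set of distinct orthographic
# forms: uniqueness point, Coltheart's N, OLD20, homograph profiles.

#' Orthographic uniqueness point
#'
#' The leftmost letter position k at which a form's k-character prefix is
#' shared by no other form in the corpus. A form that is a prefix of
#' another form never becomes unique and gets `nb_letters + 1`.
#'
#' Computed via sorted-neighbor longest-common-prefix: in lexicographic
#' order, the longest prefix a form shares with any other form is attained
#' at one of its two sorted neighbors.
#'
#' @param form character vector of target forms; each must occur in `forms`.
#' @param forms the set of distinct orthographic forms of the corpus.
#' @return integer vector of uniqueness points.
#' @export
#' @examples
#' uniqueness_point("cama", c("cama", "casa", "casas"))   # 3
uniqueness_point <- function(form, forms) {
  forms <- unique(forms)
  if (!all(form %in% forms)) {
    stop("target form(s) absent from the corpus form set", call. = FALSE)
  }
  sorted <- sort(forms, method = "radix")
  chars <- strsplit(sorted, "")
  lens <- lengths(chars)
  n <- length(sorted)
  lcp_pair <- function(a, b) {
    m <- min(length(a), length(b))
    if (m == 0L) return(0L)
    neq <- which(a[seq_len(m)] != b[seq_len(m)])
    if (length(neq) == 0L) m else neq[1L] - 1L
  }
  # lcp with previous sorted neighbor, for each position
  lcp_prev <- c(0L, vapply(seq_len(n - 1L) + 1L, function(i) {
    lcp_pair(chars[[i]], chars[[i - 1L]])
  }, integer(1L)))
  max_shared <- pmax(lcp_prev, c(lcp_prev[-1L], 0L))
  pu <- ifelse(max_shared >= lens, lens + 1L, max_shared + 1L)
  pu[match(form, sorted)]
}

#' Coltheart's orthographic neighborhood size
#'
#' Counts the other forms of identical length at Hamming distance exactly 1
#' (one substituted letter). Implemented by hashing each form with one
#' position masked: two same-length forms are neighbors iff they share
#' exactly one masked key.
#'
#' @param form character vector of target forms.
#' @param forms set of distinct orthographic forms (targets need not be in
#'   it; a target present in `forms` is not its own neighbor).
#' @return integer vector of neighborhood sizes.
#' @export
#' @examples
#' coltheart_n("cama", c("cama", "cana", "casa", "dama"))   # 3
coltheart_n <- function(form, forms) {
  forms <- unique(forms)
  all_forms <- unique(c(form, forms))
  lens <- nchar(all_forms)
  in_corpus <- all_forms %in% forms
  counts <- integer(length(all_forms))
  for (L in unique(lens)) {
    if (L == 0L) next
    grp <- which(lens == L)
    mat <- matrix(unlist(strsplit(all_forms[grp], "")), nrow = length(grp),
                  ncol = L, byrow = TRUE)
    for (pos in seq_len(L)) {
      # two same-length forms are Hamming-1 neighbors iff they agree on
      # every position but one, i.e. share exactly one masked key
      masked <- apply(mat[, -pos, drop = FALSE], 1L, paste, collapse = "")
      masked <- paste0(pos, "\r", masked)
      tab_corpus <- table(masked[in_corpus[grp]])
      mates <- as.integer(tab_corpus[match(masked, names(tab_corpus))])
      mates[is.na(mates)] <- 0L
      counts[grp] <- counts[grp] + mates - as.integer(in_corpus[grp])
    }
  }
  counts[match(form, all_forms)]
}

#' OLD20: mean Levenshtein distance to the closest words
#'
#' For each target, the mean unit-cost Levenshtein distance (insertions,
#' deletions, substitutions) to its `k` nearest other forms in the corpus;
#' when fewer than `k` other forms exist, all of them are averaged. Ties at
#' the k-th distance are resolved on the distance multiset (the k smallest
#' distances are used, never word identity).
#'
#' @param form character vector of target forms.
#' @param forms set of distinct orthographic forms; must contain at least
#'   one form different from each target.
#' @param k neighborhood size (default 20).
#' @param chunk_size number of targets per distance-matrix block.
#' @return numeric vector of mean distances.
#' @export
old20 <- function(form, forms, k = 20L, chunk_size = 500L) {
  forms <- unique(forms)
  if (length(forms) == 0L) {
    stop("OLD20 needs at least one other form in the corpus", call. = FALSE)
  }
  out <- numeric(length(form))
  for (start in seq(1L, length(form), by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, length(form))
    d <- utils::adist(form[idx], forms)
    for (j in seq_along(idx)) {
      di <- d[j, ]
      di <- di[!(forms == form[idx[j]])]   # a form is not its own neighbor
      if (length(di) == 0L) {
        stop("OLD20 needs at least one other form in the corpus",
             call. = FALSE)
      }
      kk <- min(k, length(di))
      out[idx[j]] <- mean(sort.int(di, partial = kk)[seq_len(kk)])
    }
  }
  out
}

#' Homograph profile of a lexicon
#'
#' For each entry, the number of distinct grammatical categories in which
#' its orthographic form occurs (its own category included) and the list of
#' those category codes in conventional order.
#'
#' @param lexicon a `lexicon` object or a data.frame with columns
#'   `orthography` and `gram_cat`.
#' @return data.frame with columns `nb_homogr` (integer) and `homographs`
#'   (comma-separated codes), aligned with the entries.
#' @export
homograph_profile <- function(lexicon) {
  entries <- if (inherits(lexicon, "lexicon")) lexicon$entries else lexicon
  cat_rank <- match(entries$gram_cat, gram_categories())
  ord <- order(entries$orthography, cat_rank, method = "radix")
  types <- unique(data.frame(orthography = entries$orthography[ord],
                             gram_cat = entries$gram_cat[ord],
                             stringsAsFactors = FALSE))
  joined <- tapply(types$gram_cat, types$orthography,
                   function(x) paste(x, collapse = ", "))
  counts <- tapply(types$gram_cat, types$orthography, length)
  i <- match(entries$orthography, names(joined))
  data.frame(nb_homogr = as.integer(counts[i]),
             homographs = as.character(joined[i]),
             stringsAsFactors = FALSE)
}
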