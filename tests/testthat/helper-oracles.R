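# Independent brute-force oracles used to cross-check the implementation.

# Textbook dynamic-programming Levenshtein distance (unit costs).
lev_dp <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (x[i] == y[j]) 0L else 1L
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L,
                               d[i + 1L, j] + 1L,
                               d[i, j] + cost)
    }
  }
  d[n + 1L, m + 1L]
}

# Coltheart's N by exhaustive pairwise Hamming comparison.
oracle_coltheart <- function(target, forms) {
  forms <- setdiff(unique(forms), target)
  same_len <- forms[nchar(forms) == nchar(target)]
  if (length(same_len) == 0L) return(0L)
  tc <- strsplit(target, "")[[1]]
  sum(vapply(strsplit(same_len, ""), function(ch) {
    sum(ch != tc) == 1L
  }, logical(1L)))
}

# OLD20 from the full distance matrix: compute every pairwise distance,
# sort, average the k smallest.
oracle_old20 <- function(target, forms, k = 20L) {
  others <- setdiff(unique(forms), target)
  d <- sort(utils::adist(target, others)[1L, ])
  mean(d[seq_len(min(k, length(d)))])
}

# Random letter strings for property tests.
random_strings <- function(n, min_len = 1L, max_len = 12L,
                           alphabet = letters[1:10]) {
  vapply(sample(min_len:max_len, n, replace = TRUE), function(L) {
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
  }, character(1L))
}

# A small assembled lexicon from the demo lists, shared across tests.
demo_lexicon <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- assemble_lexicon(demo_frequency_lists(),
                                                   seed = 42)
    cache
  }
})

# Brute-force predicate filter equivalent of complex_search, evaluated
# row by row with plain R comparisons.
oracle_filter <- function(criteria, lexicon) {
  e <- lexicon$entries
  keep <- rep(TRUE, nrow(e))
  fold <- function(x) chartr("áàâãäéèêëíìîïóòôõöúùûüçñ",
                             "aaaaaeeeeiiiiooooouuuucn", tolower(x))
  for (cr in criteria) {
    if (cr$mode == "off") next
    v <- e[[cr$column]]
    if (is.character(v)) {
      pat <- fold(cr$expression)
      rx <- gsub("%", ".*", gsub("_", ".", pat, fixed = TRUE), fixed = TRUE)
      m <- grepl(paste0("^", rx, "$"), fold(v))
    } else {
      expr <- trimws(cr$expression)
      lt <- regmatches(expr, regexec("<\\s*([-0-9.eE+]+)", expr))[[1]]
      gt <- regmatches(expr, regexec(">\\s*([-0-9.eE+]+)", expr))[[1]]
      m <- rep(TRUE, nrow(e))
      if (length(lt) == 2L) m <- m & as.numeric(v) < as.numeric(lt[2])
      if (length(gt) == 2L) m <- m & as.numeric(v) > as.numeric(gt[2])
      if (length(lt) != 2L && length(gt) != 2L) {
        m <- as.numeric(v) == as.numeric(expr)
      }
    }
    keep <- if (cr$mode == "include") keep & m else keep & !m
  }
  e[keep, , drop = FALSE]
}
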