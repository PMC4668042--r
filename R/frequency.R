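# Frequency transforms: per-million, common log, Zipf scale, Zipf rank.

#' Frequency per million tokens
#'
#' Scales a raw occurrence count to occurrences per million corpus tokens:
#' `freq / total * 1e6`.
#'
#' @param freq raw count(s), >= 0.
#' @param total corpus token total, >= 1.
#' @param digits rounding applied to the reported value (default 4 decimals;
#'   `NULL` for no rounding).
#' @return numeric vector of per-million frequencies.
#' @export
#' @examples
#' per_million(397, 31377670)   # 12.6523
per_million <- function(freq, total, digits = 4L) {
  if (any(total < 1)) stop("corpus token total must be >= 1", call. = FALSE)
  if (any(freq < 0)) stop("frequencies must be non-negative", call. = FALSE)
  out <- freq / total * 1e6
  if (!is.null(digits)) out <- round(out, digits) else out
}

#' Common logarithm of a raw frequency
#'
#' @param freq raw count(s), >= 1 (transforms are defined for attested
#'   words only; zeros are rejected rather than smoothed).
#' @param digits rounding (default 4 decimals; `NULL` for none).
#' @return numeric vector, log10 of the count.
#' @export
log10_frequency <- function(freq, digits = 4L) {
  if (any(freq < 1)) {
    stop("log10 frequency is defined for counts >= 1", call. = FALSE)
  }
  out <- log10(freq)
  if (!is.null(digits)) out <- round(out, digits) else out
}

#' Zipf scale
#'
#' The standardized frequency scale `log10(per-million frequency) + 3`,
#' interpretable across corpora roughly as a 1-7 scale (values below 3 are
#' low-frequency words, above 4 high-frequency).
#'
#' @inheritParams per_million
#' @param digits rounding (default 4 decimals; `NULL` for none).
#' @return numeric vector of Zipf-scale values.
#' @export
#' @examples
#' zipf_scale(397, 30705945)    # 4.1116
zipf_scale <- function(freq, total, digits = 4L) {
  if (any(freq < 1)) {
    stop("Zipf scale is defined for counts >= 1", call. = FALSE)
  }
  out <- log10(per_million(freq, total, digits = NULL)) + 3
  if (!is.null(digits)) out <- round(out, digits) else out
}

#' Zipf rank (dense ranking by descending frequency)
#'
#' Rank 1 goes to the highest distinct frequency; each lower distinct
#' frequency increments the rank by one, so tied frequencies share a rank
#' and the ranks used are exactly 1..K for K distinct frequencies.
#'
#' @param freqs non-empty vector of raw counts.
#' @return integer vector of ranks, aligned with `freqs`.
#' @export
#' @examples
#' zipf_rank(c(10, 7, 7, 3))    # 1 2 2 3
zipf_rank <- function(freqs) {
  if (length(freqs) == 0L) stop("cannot rank an empty list", call. = FALSE)
  distinct <- sort(unique(freqs), decreasing = TRUE)
  match(freqs, distinct)
}
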