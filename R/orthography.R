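# Character-level structure: letter counts, CVCV coding, reversal,
# bounded bigram/trigram decomposition.

#' Count the characters of a form
#'
#' Every character counts as one letter: accented letters, digits and
#' hyphens included. This convention keeps the bigram-count identity
#' (number of bigrams = letters + 1) exact for hyphenated compounds.
#'
#' @param form non-empty character vector.
#' @return integer vector of lengths.
#' @export
#' @examples
#' letter_count("cachorro")   # 8
letter_count <- function(form) {
  if (any(!nzchar(form))) stop("empty form", call. = FALSE)
  nchar(form, type = "chars")
}

#' Default character-class mapping for CVCV coding
#'
#' Unaccented vowels map to `V`, consonants (including c-cedilla) to `C`,
#' accented vowel characters to `A`, digits to `N`, hyphen and apostrophe
#' to `P` (punctuation), and the ordinal indicators to `S` (symbol). Extend
#' or replace the returned named vector to change the coding.
#'
#' @return named character vector: names are characters, values are class
#'   letters from \{C, V, N, A, P, S\}.
#' @export
cvcv_default_mapping <- function() {
  vowels <- strsplit("aeiou", "")[[1]]
  consonants <- strsplit("bcdfghjklmnpqrstvwxyzç", "")[[1]]
  accented <- strsplit("áàâãäéèêëíìîïóòôõöúùûü", "")[[1]]
  digits <- as.character(0:9)
  punct <- c("-", "'")
  symbols <- c("º", "ª")
  stats::setNames(
    c(rep("V", length(vowels)), rep("C", length(consonants)),
      rep("A", length(accented)), rep("N", length(digits)),
      rep("P", length(punct)), rep("S", length(symbols))),
    c(vowels, consonants, accented, digits, punct, symbols))
}

#' CVCV structural code of a form
#'
#' Maps each character to its class letter (consonant/vowel/number/accent/
#' punctuation/symbol), producing a string of the same length as the form.
#'
#' @param form character vector of non-empty forms.
#' @param mapping named character-class vector; see [cvcv_default_mapping()].
#' @return character vector of class strings.
#' @export
#' @examples
#' cvcv_code("cachorro")   # "CVCCVCCV"
cvcv_code <- function(form, mapping = cvcv_default_mapping()) {
  if (any(!nzchar(form))) stop("empty form", call. = FALSE)
  vapply(strsplit(form, ""), function(ch) {
    cls <- mapping[ch]
    if (anyNA(cls)) {
      stop("no CVCV class for character '", ch[which(is.na(cls))[1L]], "'",
           call. = FALSE)
    }
    paste(cls, collapse = "")
  }, character(1L))
}

#' Reverse a form character-wise
#'
#' @param form character vector of non-empty forms.
#' @return character vector with characters in reverse order.
#' @export
#' @examples
#' reverse_form("cachorro")   # "orrohcac"
reverse_form <- function(form) {
  if (any(!nzchar(form))) stop("empty form", call. = FALSE)
  vapply(strsplit(form, ""),
         function(ch) paste(rev(ch), collapse = ""),
         character(1L))
}

.bounded_windows <- function(form, n) {
  bounded <- paste0("#", form, "#")
  len <- nchar(bounded)
  starts <- seq_len(len - n + 1L)
  substring(bounded, starts, starts + n - 1L)
}

#' Bounded n-gram decomposition
#'
#' Slides a window of width `n` over the form bounded by `#` markers
#' (`#form#`) and joins the windows with underscores. A word of L letters
#' yields L+1 bigrams and L trigrams (for L >= 2; a one-letter word yields
#' the single trigram `#x#`).
#'
#' @param form character vector of non-empty forms.
#' @param n window width, 2 (bigrams) or 3 (trigrams).
#' @return character vector of underscore-joined n-gram strings.
#' @export
#' @examples
#' ngram_decompose("cachorro", 2)   # "#c_ca_ac_ch_ho_or_rr_ro_o#"
#' ngram_decompose("cachorro", 3)   # "#ca_cac_ach_cho_hor_orr_rro_ro#"
ngram_decompose <- function(form, n) {
  if (!n %in% c(2L, 3L)) stop("n must be 2 or 3", call. = FALSE)
  if (any(!nzchar(form))) stop("empty form", call. = FALSE)
  vapply(form, function(f) {
    paste(.bounded_windows(f, n), collapse = "_")
  }, character(1L), USE.NAMES = FALSE)
}
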