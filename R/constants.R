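# Shared vocabulary: category codes, feature codes, column schema, collation.

#' Grammatical category codes
#'
#' The seven part-of-speech codes used throughout the lexicon, in their
#' conventional order: adjective, adverb, grammatical word, noun, numeral,
#' verb, proper name.
#'
#' @return Character vector of category codes.
#' @export
#' @examples
#' gram_categories()
gram_categories <- function() {
  c("adj", "adv", "gram", "nom", "num", "ver", "prop")
}

#' Grammatical-information feature codes
#'
#' The controlled vocabulary for the `gram_inf` column: categories beyond the
#' seven POS codes (conjunction, determinant, preposition, pronoun), gender,
#' number, person, verb conjugation class, mood and tense codes.
#'
#' @return Character vector of admissible feature codes.
#' @export
gram_features <- function() {
  c(gram_categories(),
    "conj", "det", "prep", "pro",
    "m", "f", "s", "p",
    "1", "2", "3",
    "c1", "c2", "c3",
    "ind", "sub", "imp",
    "pre", "perf", "fut",
    "inf", "ger", "pp")
}

#' Lexicon column schema
#'
#' The 25 columns of an assembled lexicon, in canonical order. These are the
#' exact headers used by [export_csv()] and [write_lexicon_csv()].
#'
#' @return Character vector of 25 column names.
#' @export
lexicon_columns <- function() {
  c("orthography", "gram_cat", "gram_inf",
    "ortho_freq", "ortho_freq/M", "log10_ortho_freq", "zipf_scale",
    "zipf_rank", "nb_letters", "nb_homogr", "homographs",
    "pu_ortho", "ortho_neigh", "old20",
    "cvcv_ortho", "bigrams", "bigram_freq", "trigrams", "trigram_freq",
    "rev_ortho", "rev_cvcv_ortho", "rev_bigrams", "rev_trigrams",
    "random", "id")
}

# Accented characters and their unaccented bases, used both for accent-
# insensitive matching and for primary collation weight.
.accented <- paste0(
  "áàâãä",  # a acute/grave/circumflex/tilde/umlaut
  "éèêë",
  "íìîï",
  "óòôõö",
  "úùûü",
  "çñ")                    # c-cedilla, n-tilde
.accent_base <- "aaaaaeeeeiiiiooooouuuucn"

#' Fold case and accents
#'
#' Lower-cases a string and maps accented Latin letters (and c-cedilla,
#' n-tilde) to their base letters. This is the default comparison key of the
#' search engines, under which e.g. "apos" matches "após".
#'
#' @param x character vector.
#' @return folded character vector.
#' @export
#' @examples
#' fold_key("Após")
fold_key <- function(x) {
  chartr(.accented, .accent_base, tolower(x))
}

# Collation for the id sort and for ordering string columns:
# letters a-z first, then digits 0-9, then hyphen and apostrophe, then
# everything else; accented letters take the weight of their base letter;
# ties broken by raw code point. Implemented as a sortable primary-key
# string compared bytewise ahead of the raw UTF-8 string.
.collation_primary <- function(x) {
  key <- chartr(.accented, .accent_base, x)
  # letters -> A..Z (sort before remapped digits), digits -> a..j,
  # hyphen -> '{', apostrophe -> '|'
  key <- chartr("-abcdefghijklmnopqrstuvwxyz0123456789'",
                "{ABCDEFGHIJKLMNOPQRSTUVWXYZabcdefghij|", key)
  gsub("[^A-Zabcdefghij{|]", "}", key)
}

#' Order strings under the lexicon collation
#'
#' Total, locale-independent ordering: Latin letters a-z first, then digits
#' 0-9, then hyphen; accented letters collate with their base letter; any
#' residual tie is broken by code point.
#'
#' @param x character vector to order.
#' @param ... further atomic vectors used as subsequent tie-breaks.
#' @return integer permutation, as [order()].
#' @export
collate_order <- function(x, ...) {
  order(.collation_primary(x), x, ..., method = "radix")
}

.assert_categories <- function(cats) {
  bad <- setdiff(unique(cats), gram_categories())
  if (length(bad) > 0L) {
    stop("unknown grammatical category code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
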