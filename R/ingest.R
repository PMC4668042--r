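# Reading, cleaning and merging POS-tagged word-frequency lists.

#' Read a word-frequency list
#'
#' Parses a plain-text frequency list: one entry per non-blank line, the
#' orthographic form and a non-negative integer count separated by
#' whitespace. Every entry receives the supplied grammatical category.
#'
#' @param source a file path, connection, or character vector of lines.
#' @param gram_cat a single category code; see [gram_categories()].
#' @return data.frame with columns `orthography`, `gram_cat`, `ortho_freq`,
#'   in input order.
#' @export
#' @examples
#' read_frequency_list(c("casa 123", "cachorro 397"), "nom")
read_frequency_list <- function(source, gram_cat) {
  if (length(gram_cat) != 1L) {
    stop("gram_cat must be a single category code", call. = FALSE)
  }
  .assert_categories(gram_cat)
  if (is.character(source) && length(source) == 1L && file.exists(source)) {
    lines <- readLines(source, encoding = "UTF-8", warn = FALSE)
  } else if (inherits(source, "connection")) {
    lines <- readLines(source, encoding = "UTF-8", warn = FALSE)
  } else {
    lines <- as.character(source)
  }
  keep <- !grepl("^\\s*$", lines)
  idx <- which(keep)
  lines <- trimws(lines[keep])
  if (length(lines) == 0L) {
    return(data.frame(orthography = character(), gram_cat = character(),
                      ortho_freq = integer(), stringsAsFactors = FALSE))
  }
  parts <- regmatches(lines, regexec("^(\\S+)\\s+(\\S+)$", lines))
  ok <- lengths(parts) == 3L
  if (any(!ok)) {
    stop("malformed line ", idx[which(!ok)[1L]],
         ": expected 'form count', got '", lines[which(!ok)[1L]], "'",
         call. = FALSE)
  }
  form <- vapply(parts, `[`, character(1L), 2L)
  count_str <- vapply(parts, `[`, character(1L), 3L)
  bad <- !grepl("^[0-9]+$", count_str)
  if (any(bad)) {
    stop("malformed line ", idx[which(bad)[1L]],
         ": count '", count_str[which(bad)[1L]], "' is not an integer",
         call. = FALSE)
  }
  data.frame(orthography = form,
             gram_cat = rep(gram_cat, length(form)),
             ortho_freq = as.integer(count_str),
             stringsAsFactors = FALSE)
}

.new_report <- function(kept = 0L, removed_numeric = 0L,
                        removed_too_long = 0L, merged_case_variants = 0L) {
  structure(list(kept = as.integer(kept),
                 removed_numeric = as.integer(removed_numeric),
                 removed_too_long = as.integer(removed_too_long),
                 merged_case_variants = as.integer(merged_case_variants)),
            class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report:",
      x$kept, "kept,",
      x$removed_numeric, "numeric removed,",
      x$removed_too_long, "over-long removed,",
      x$merged_case_variants, "case variants merged\n")
  invisible(x)
}

#' Lower-case entries and merge duplicates
#'
#' Homogenizes orthographies to lower case and merges entries that become
#' identical in (orthography, category), summing their raw frequencies so
#' that the token total is conserved.
#'
#' @param entries data.frame as returned by [read_frequency_list()].
#' @return list with `entries` (merged data.frame) and `report`
#'   (a `cleaning_report`; `merged_case_variants` counts merges performed).
#' @export
normalize_and_merge <- function(entries) {
  entries$orthography <- tolower(entries$orthography)
  key <- paste(entries$orthography, entries$gram_cat, sep = "\r")
  first <- !duplicated(key)
  n_merged <- sum(!first)
  if (n_merged > 0L) {
    freq <- tapply(entries$ortho_freq, factor(key, levels = key[first]), sum)
    out <- entries[first, , drop = FALSE]
    out$ortho_freq <- as.integer(freq)
  } else {
    out <- entries
  }
  rownames(out) <- NULL
  list(entries = out,
       report = .new_report(kept = nrow(out),
                            merged_case_variants = n_merged))
}

#' Cleaning rules for [filter_entries()]
#'
#' @param max_length maximum orthography length in characters; longer
#'   entries are dropped.
#' @param numeric_whitelist forms containing digits that are kept anyway:
#'   by default the single digits 0-9 and the ordinals 1º-9º / 1ª-9ª.
#' @param whitelist_categories categories under which whitelisted numeric
#'   forms are kept; elsewhere they are removed like any numeric entry.
#' @return list of rules.
#' @export
cleaning_rules <- function(max_length = 30L,
                           numeric_whitelist = c(as.character(0:9),
                                                 paste0(1:9, "º"),
                                                 paste0(1:9, "ª")),
                           whitelist_categories = c("adj", "nom", "num")) {
  list(max_length = as.integer(max_length),
       numeric_whitelist = numeric_whitelist,
       whitelist_categories = whitelist_categories)
}

#' Remove over-long and numeric entries
#'
#' Applies the corpus cleaning filters: entries longer than 30 characters
#' are removed, and entries containing a digit are removed unless the form
#' is a whitelisted single digit or ordinal occurring under an adjective,
#' noun or numeral tag.
#'
#' @param entries normalized data.frame of entries.
#' @param rules filter configuration from [cleaning_rules()].
#' @return list with `entries` and `report`.
#' @export
filter_entries <- function(entries, rules = cleaning_rules()) {
  too_long <- nchar(entries$orthography) > rules$max_length
  numeric_like <- grepl("[0-9]", entries$orthography)
  whitelisted <- entries$orthography %in% rules$numeric_whitelist &
    entries$gram_cat %in% rules$whitelist_categories
  drop_numeric <- numeric_like & !whitelisted & !too_long
  keep <- !too_long & !drop_numeric
  out <- entries[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(entries = out,
       report = .new_report(kept = nrow(out),
                            removed_numeric = sum(drop_numeric),
                            removed_too_long = sum(too_long)))
}

#' Annotate grammatical information from suffix rules
#'
#' Looks up the longest matching suffix rule for each entry's category and
#' returns the rule's comma-separated feature codes (gender, number, person,
#' mood, tense, conjugation class), or an empty string when no rule matches.
#'
#' @param orthography character vector of forms.
#' @param gram_cat matching vector of category codes.
#' @param rule_table data.frame with columns `gram_cat`, `suffix`,
#'   `features` (a comma-separated string of codes from [gram_features()]).
#' @return character vector of feature strings.
#' @export
#' @examples
#' rules <- data.frame(gram_cat = "ver", suffix = "as",
#'                     features = "ind, pre, 2, s")
#' annotate_grammatical_info("falas", "ver", rules)
annotate_grammatical_info <- function(orthography, gram_cat, rule_table) {
  if (is.null(rule_table) || nrow(rule_table) == 0L) {
    return(rep("", length(orthography)))
  }
  codes <- unlist(strsplit(rule_table$features, ",\\s*"))
  bad <- setdiff(codes, gram_features())
  if (length(bad) > 0L) {
    stop("rule table uses feature code(s) outside the convention: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  # longest suffix wins; pre-sort rules so the first match is the longest
  ord <- order(-nchar(rule_table$suffix))
  rule_table <- rule_table[ord, , drop = FALSE]
  vapply(seq_along(orthography), function(i) {
    rules_i <- rule_table[rule_table$gram_cat == gram_cat[i], , drop = FALSE]
    if (nrow(rules_i) == 0L) return("")
    hit <- vapply(rules_i$suffix, function(s) {
      endsWith(orthography[i], s)
    }, logical(1L))
    if (!any(hit)) "" else rules_i$features[which(hit)[1L]]
  }, character(1L))
}
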