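# Search engines: word-list search, wildcard/range multi-criterion search,
# ordering, paging, result statistics, CSV export.

.stats_columns <- c("ortho_freq", "log10_ortho_freq", "zipf_scale",
                    "bigram_freq", "trigram_freq", "nb_letters",
                    "ortho_neigh", "old20")

.string_columns <- c("orthography", "gram_cat", "gram_inf", "homographs",
                     "cvcv_ortho", "bigrams", "trigrams", "rev_ortho",
                     "rev_cvcv_ortho", "rev_bigrams", "rev_trigrams")

.new_result <- function(all_rows, total_found, page = 1L,
                        page_size = NA_integer_, unmatched = character()) {
  structure(list(rows = .page_rows(all_rows, page, page_size),
                 all_rows = all_rows,
                 total_found = as.integer(total_found),
                 page = as.integer(page), page_size = page_size,
                 unmatched = unmatched),
            class = "lexicon_search")
}

#' @export
print.lexicon_search <- function(x, ...) {
  cat("Search result:", x$total_found, "entries found")
  if (!is.na(x$page_size)) {
    cat(" (page", x$page, "of",
        max(1L, ceiling(x$total_found / x$page_size)), ")")
  }
  cat("\n")
  if (length(x$unmatched) > 0L) {
    cat("Unmatched words:", paste(x$unmatched, collapse = ", "), "\n")
  }
  invisible(x)
}

.page_rows <- function(rows, page, page_size) {
  if (is.null(page_size) || is.na(page_size)) return(rows)
  from <- (page - 1L) * page_size + 1L
  to <- min(page * page_size, nrow(rows))
  if (from > nrow(rows)) rows[0L, , drop = FALSE]
  else rows[from:to, , drop = FALSE]
}

.order_rows <- function(rows, order_by = "id", direction = "asc") {
  if (is.null(order_by)) return(rows)
  if (!order_by %in% names(rows)) {
    stop("unknown ordering column: ", order_by, call. = FALSE)
  }
  v <- rows[[order_by]]
  idx <- if (is.character(v)) {
    collate_order(v, rows$id)
  } else {
    order(v, rows$id, method = "radix")
  }
  if (identical(direction, "desc")) idx <- rev(idx)
  rows[idx, , drop = FALSE]
}

#' Word-list ("simple") search
#'
#' Looks up a list of words in the lexicon. Comparison folds case and
#' accents by default ("CASA" and "cásá" both match "casa"); words with no
#' match are reported in the result's `unmatched` field.
#'
#' @param words non-empty character vector of words to look up.
#' @param lexicon a `lexicon` object.
#' @param strict if `TRUE`, compare orthographies byte-wise instead of
#'   folding case and accents.
#' @param order_by,direction ordering column and `"asc"`/`"desc"`.
#' @param page,page_size optional paging of the returned rows.
#' @return a `lexicon_search`: `rows`, `total_found`, `unmatched`, paging.
#' @export
simple_search <- function(words, lexicon, strict = FALSE,
                          order_by = "id", direction = "asc",
                          page = 1L, page_size = NA_integer_) {
  if (length(words) == 0L) stop("empty word list", call. = FALSE)
  entries <- lexicon$entries
  key <- if (strict) entries$orthography else fold_key(entries$orthography)
  wkey <- if (strict) words else fold_key(words)
  hit <- key %in% wkey
  unmatched <- words[!(wkey %in% key)]
  rows <- .order_rows(entries[hit, , drop = FALSE], order_by, direction)
  .new_result(rows, sum(hit), page, page_size, unmatched)
}

#' Wildcard pattern match
#'
#' `_` matches exactly one character; `%` matches any (possibly empty)
#' chain of characters; all other characters are literals. Literals compare
#' case- and accent-insensitively unless `strict`.
#'
#' @param pattern non-empty wildcard pattern.
#' @param value character vector of values to test.
#' @param strict disable case/accent folding.
#' @return logical vector.
#' @export
#' @examples
#' match_pattern("a_o_", c("amor", "amora"))   # TRUE FALSE
match_pattern <- function(pattern, value, strict = FALSE) {
  if (!nzchar(pattern)) stop("empty pattern", call. = FALSE)
  if (!strict) {
    pattern <- fold_key(pattern)
    value <- fold_key(value)
  }
  chars <- strsplit(pattern, "")[[1]]
  rx <- paste(vapply(chars, function(ch) {
    if (ch == "_") "."
    else if (ch == "%") ".*"
    else if (grepl("[][\\^$.|?*+(){}]", ch)) paste0("\\", ch)
    else ch
  }, character(1L)), collapse = "")
  grepl(paste0("^", rx, "$"), value)
}

#' Build one search criterion
#'
#' @param column one of the 25 lexicon column names.
#' @param expression wildcard pattern (string columns) or range expression
#'   (numeric columns): `"< x"`, `"> x"`, `"< x > y"` (open interval), or a
#'   bare number for equality.
#' @param mode `"include"` (entry must satisfy), `"exclude"` (entry must
#'   not satisfy), or `"off"` (criterion disabled).
#' @return a `criterion` object.
#' @export
criterion <- function(column, expression,
                      mode = c("include", "exclude", "off")) {
  mode <- match.arg(mode)
  if (!column %in% lexicon_columns()) {
    stop("unknown column: ", column, call. = FALSE)
  }
  structure(list(column = column, expression = as.character(expression),
                 mode = mode),
            class = "criterion")
}

# Parse a numeric range expression into a predicate over a numeric vector.
.range_predicate <- function(expr) {
  expr <- trimws(expr)
  num <- "[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?"
  if (grepl(paste0("^", num, "$"), expr)) {
    target <- as.numeric(expr)
    return(function(v) v == target)
  }
  pieces <- regmatches(expr,
                       gregexpr(paste0("([<>])\\s*(", num, ")"), expr))[[1]]
  if (length(pieces) == 0L ||
      nchar(gsub("\\s+", "", paste(pieces, collapse = ""))) !=
      nchar(gsub("\\s+", "", expr))) {
    stop("malformed range expression: '", expr, "'", call. = FALSE)
  }
  lt <- Inf; gt <- -Inf
  for (p in pieces) {
    op <- substr(p, 1L, 1L)
    val <- as.numeric(trimws(substring(p, 2L)))
    if (op == "<") lt <- min(lt, val) else gt <- max(gt, val)
  }
  function(v) v > gt & v < lt
}

.criterion_mask <- function(crit, entries, strict = FALSE) {
  v <- entries[[crit$column]]
  if (crit$column %in% .string_columns) {
    match_pattern(crit$expression, v, strict = strict)
  } else {
    pred <- .range_predicate(crit$expression)
    out <- pred(as.numeric(v))
    out & !is.na(out)
  }
}

#' Multi-criterion ("complex") search
#'
#' Returns the entries satisfying every include-criterion and violating no
#' exclude-criterion (criteria combine as AND; `"off"` criteria are
#' ignored). String columns take wildcard patterns, numeric columns take
#' strict `<` / `>` bounds or an open interval `"< x > y"`.
#'
#' @param criteria a list of [criterion()] objects (a single criterion is
#'   accepted bare).
#' @param lexicon a `lexicon` object.
#' @param strict byte-wise literal comparison for patterns.
#' @inheritParams simple_search
#' @return a `lexicon_search`.
#' @export
complex_search <- function(criteria, lexicon, strict = FALSE,
                           order_by = "id", direction = "asc",
                           page = 1L, page_size = NA_integer_) {
  if (inherits(criteria, "criterion")) criteria <- list(criteria)
  entries <- lexicon$entries
  keep <- rep(TRUE, nrow(entries))
  for (crit in criteria) {
    if (!inherits(crit, "criterion")) {
      stop("criteria must be built with criterion()", call. = FALSE)
    }
    if (crit$mode == "off") next
    m <- .criterion_mask(crit, entries, strict = strict)
    keep <- if (crit$mode == "include") keep & m else keep & !m
  }
  rows <- .order_rows(entries[keep, , drop = FALSE], order_by, direction)
  .new_result(rows, sum(keep), page, page_size)
}

#' Descriptive statistics of a search result
#'
#' Maximum, minimum and arithmetic mean of the eight numeric columns
#' reported with every search: raw frequency, log10 frequency, Zipf scale,
#' bigram and trigram frequency, letters, neighborhood size, OLD20.
#'
#' @param result a `lexicon_search`.
#' @return data.frame with one row per column (`column`, `max`, `min`,
#'   `mean`); zero rows (an empty-stats marker) for an empty result.
#' @export
result_statistics <- function(result) {
  rows <- if (!is.null(result$all_rows)) result$all_rows else result$rows
  if (is.null(rows) || nrow(rows) == 0L) {
    return(data.frame(column = character(), max = numeric(),
                      min = numeric(), mean = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(.stats_columns, function(cl) {
    v <- as.numeric(rows[[cl]])
    v <- v[!is.na(v)]
    data.frame(column = cl, max = max(v), min = min(v), mean = mean(v),
               stringsAsFactors = FALSE)
  }))
}

#' Export a search result as CSV
#'
#' Writes every matching row (not just the current page), with the 25
#' canonical column headers in order, RFC 4180 quoting, UTF-8.
#'
#' @param result a `lexicon_search` (or a `lexicon`).
#' @param destination output file path.
#' @return the destination, invisibly.
#' @export
export_csv <- function(result, destination) {
  rows <- if (inherits(result, "lexicon")) result$entries else result$all_rows
  utils::write.csv(rows[, lexicon_columns(), drop = FALSE], destination,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(destination)
}
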