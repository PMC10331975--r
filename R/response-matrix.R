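#' Construct a response matrix
#'
#' The container consumed by every stage of the validation pipeline: an
#' N persons x L items matrix of ordinal category codes on the external
#' (printed) scale `1..n_categories`. Missing responses are `NA` and are
#' excluded from all sums downstream; surveys that enforce completeness
#' can be validated with `allow_missing = FALSE` in [read_responses()].
#'
#' @param values integer matrix (persons x items) of codes in
#'   `1..n_categories`, `NA` allowed.
#' @param persons character vector of unique person identifiers
#'   (default `"P1".."PN"`).
#' @param items character vector of unique item identifiers
#'   (default taken from `colnames(values)` or `"I1".."IL"`).
#' @param n_categories number of rating-scale categories (5 for a
#'   five-point agreement scale).
#' @return An object of class `response_matrix`: a list with elements
#'   `values`, `persons`, `items`, `n_categories`, `missing_mask`.
#' @examples
#' m <- response_matrix(matrix(c(1, 5, 3, 4, 2, 5), nrow = 3))
#' dim(m)
#' @export
response_matrix <- function(values, persons = NULL, items = NULL,
                            n_categories = 5L) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  l <- ncol(values)
  if (n < 2L || l < 2L) {
    abort(sprintf("need at least 2 persons and 2 items, got %d x %d", n, l))
  }
  n_categories <- as.integer(n_categories)
  if (is.na(n_categories) || n_categories < 2L) {
    abort("`n_categories` must be an integer >= 2")
  }
  persons <- as.character(persons %||% paste0("P", seq_len(n)))
  items <- as.character(items %||% colnames(values) %||% paste0("I", seq_len(l)))
  if (length(persons) != n) abort("`persons` length must equal nrow(values)")
  if (length(items) != l) abort("`items` length must equal ncol(values)")
  if (anyDuplicated(persons)) {
    abort(sprintf("duplicate person identifier: '%s'",
                  persons[anyDuplicated(persons)]))
  }
  if (anyDuplicated(items)) {
    abort(sprintf("duplicate item identifier: '%s'",
                  items[anyDuplicated(items)]))
  }
  ok <- is.na(values) | (values == round(values) & values >= 1 &
                           values <= n_categories)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "response code %s at person '%s', item '%s' is outside 1..%d",
      format(values[bad[1L], bad[2L]]), persons[bad[1L]], items[bad[2L]],
      n_categories))
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(persons, items)
  structure(
    list(values = values, persons = persons, items = items,
         n_categories = n_categories, missing_mask = is.na(values)),
    class = "response_matrix")
}

#' Coerce to a response matrix
#'
#' @param x a `response_matrix`, a numeric matrix, or a wide data frame
#'   with one identifier column and one column per item.
#' @param id_col name or position of the person-identifier column for
#'   data-frame input (default: first column if non-numeric, else none).
#' @param n_categories number of rating-scale categories.
#' @param ... unused.
#' @return A [response_matrix()].
#' @export
as_response_matrix <- function(x, ..., id_col = NULL, n_categories = 5L) {
  UseMethod("as_response_matrix")
}

#' @export
as_response_matrix.response_matrix <- function(x, ...) x

#' @export
as_response_matrix.matrix <- function(x, ..., id_col = NULL,
                                      n_categories = 5L) {
  response_matrix(x, persons = rownames(x), items = colnames(x),
                  n_categories = n_categories)
}

#' @export
as_response_matrix.data.frame <- function(x, ..., id_col = NULL,
                                          n_categories = 5L) {
  df <- as.data.frame(x)
  if (is.null(id_col)) {
    id_col <- if (ncol(df) > 0L && !is.numeric(df[[1L]])) 1L else 0L
  }
  if (is.character(id_col)) id_col <- match(id_col, names(df))
  persons <- NULL
  if (!is.na(id_col) && id_col >= 1L) {
    persons <- as.character(df[[id_col]])
    df <- df[-id_col]
  }
  vals <- as.matrix(df)
  if (!is.numeric(vals)) abort("response columns must be numeric category codes")
  response_matrix(vals, persons = persons, items = names(df),
                  n_categories = n_categories)
}

#' @export
dim.response_matrix <- function(x) dim(x$values)

#' @export
print.response_matrix <- function(x, ...) {
  n_miss <- sum(x$missing_mask)
  cat(sprintf("<response_matrix> %d persons x %d items, %d categories%s\n",
              nrow(x$values), ncol(x$values), x$n_categories,
              if (n_miss) sprintf(", %d missing", n_miss) else ", complete"))
  invisible(x)
}

#' @export
as_tibble.response_matrix <- function(x, ...) {
  dplyr::bind_cols(tibble(person = x$persons),
                   as_tibble(as.data.frame(x$values)))
}

#' Read a response matrix from a delimited file
#'
#' Expects one header row of item identifiers, one row per person, with
#' the person identifier in the first column.
#'
#' @param path file path of a CSV (or other delimited) table.
#' @param n_categories number of rating-scale categories.
#' @param allow_missing if `FALSE` (the strict mode for surveys that
#'   enforce completeness), any blank cell is an input error.
#' @param delim field delimiter.
#' @return A [response_matrix()].
#' @export
read_responses <- function(path, n_categories = 5L, allow_missing = FALSE,
                           delim = ",") {
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          progress = FALSE, show_col_types = FALSE)
  if (ncol(df) < 3L) abort("expected an identifier column plus >= 2 item columns")
  m <- as_response_matrix(as.data.frame(df), id_col = 1L,
                          n_categories = n_categories)
  if (!allow_missing && any(m$missing_mask)) {
    bad <- which(m$missing_mask, arr.ind = TRUE)[1L, ]
    abort(sprintf("missing response at person '%s', item '%s' (allow_missing = FALSE)",
                  m$persons[bad[1L]], m$items[bad[2L]]))
  }
  m
}

#' Write a response matrix to CSV
#'
#' Inverse of [read_responses()]: writing then reading reproduces the
#' values, identifiers and missingness pattern exactly.
#'
#' @param m a [response_matrix()].
#' @param path output file path.
#' @export
write_responses <- function(m, path) {
  m <- as_response_matrix(m)
  readr::write_csv(as_tibble(m), path, na = "")
  invisible(path)
}

#' Per-item category frequencies
#'
#' Marginal counts of each response category for each item, the form in
#' which short-questionnaire response data are usually published.
#'
#' @param m a [response_matrix()] or coercible object.
#' @return A tibble with one row per item: `item`, then one count column
#'   per external category code. Each row sums to that item's number of
#'   non-missing observations.
#' @export
marginal_frequencies <- function(m) {
  m <- as_response_matrix(m)
  k <- m$n_categories
  counts <- t(apply(m$values, 2L, function(col) {
    tabulate(col[!is.na(col)], nbins = k)
  }))
  out <- as_tibble(as.data.frame(counts))
  names(out) <- paste0("cat_", seq_len(k))
  dplyr::bind_cols(tibble(item = m$items), out)
}

#' Classify an employee net promoter score
#'
#' Deterministic mapping of the 0-10 recommendation rating: 9-10 are
#' promoters, 7-8 passives, 0-6 detractors.
#'
#' @param score integer vector of raw eNPS ratings in 0..10.
#' @return A factor with levels `detractor`, `passive`, `promoter`.
#' @examples
#' classify_enps(c(0, 6, 7, 8, 9, 10))
#' @export
classify_enps <- function(score) {
  if (any(is.na(score) | score < 0 | score > 10 | score != round(score))) {
    abort("eNPS scores must be integers in 0..10")
  }
  factor(dplyr::case_when(score >= 9 ~ "promoter",
                          score >= 7 ~ "passive",
                          TRUE ~ "detractor"),
         levels = c("detractor", "passive", "promoter"))
}

#' Validate a respondent background-factor table
#'
#' Checks a factor table against a response matrix and derives the eNPS
#' class from the raw score where present. Persons without factor rows
#' are allowed (they are excluded from DIF analysis only, never from
#' estimation).
#'
#' @param factors data frame with a `person` identifier column and any
#'   number of categorical background-factor columns; an integer
#'   `enps_raw` column (0-10, `NA` allowed) is expanded into an
#'   `enps_class` factor.
#' @param m the associated [response_matrix()].
#' @return The validated factor tibble.
#' @export
factor_table <- function(factors, m) {
  m <- as_response_matrix(m)
  factors <- as_tibble(factors)
  if (!"person" %in% names(factors)) abort("factor table needs a `person` column")
  factors$person <- as.character(factors$person)
  if (anyDuplicated(factors$person)) abort("duplicate person in factor table")
  unknown <- setdiff(factors$person, m$persons)
  if (length(unknown)) {
    abort(sprintf("factor table person '%s' not present in response matrix",
                  unknown[1L]))
  }
  if ("enps_raw" %in% names(factors)) {
    ok <- !is.na(factors$enps_raw)
    cls <- factor(rep(NA_character_, nrow(factors)),
                  levels = c("detractor", "passive", "promoter"))
    cls[ok] <- classify_enps(factors$enps_raw[ok])
    if ("enps_class" %in% names(factors)) {
      mism <- ok & as.character(factors$enps_class) != as.character(cls)
      if (any(mism, na.rm = TRUE)) {
        abort(sprintf("enps_class for person '%s' contradicts enps_raw",
                      factors$person[which(mism)[1L]]))
      }
    }
    factors$enps_class <- cls
  }
  factors
}
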