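#' Persons-by-items response matrix
#'
#' Container for binary scored responses with optional missingness
#' (persons may answer different item subsets, as adaptive
#' administration produces). Items carry their structural feature
#' annotations so that calibration and diagnostics can relate responses
#' to features.
#'
#' @param scores Numeric/integer matrix, persons in rows, items in
#'   columns; entries 0, 1, or `NA`. Row and column names are used as
#'   person and item identifiers (generated if absent).
#' @param items Optional data frame of item annotations with an
#'   `item_id` column matching the score columns (typically also
#'   `track_id`, `accuracy`, `direction`).
#' @return An object of class `"response_matrix"`.
#' @export
response_matrix <- function(scores, items = NULL) {
  scores <- as.matrix(scores)
  if (!all(scores %in% c(0, 1) | is.na(scores)))
    stop("scores must be 0, 1 or NA", call. = FALSE)
  if (nrow(scores) == 0L || ncol(scores) == 0L)
    stop("empty response matrix", call. = FALSE)
  if (any(rowSums(!is.na(scores)) == 0L))
    stop("every person must have at least one observed score",
         call. = FALSE)
  if (is.null(rownames(scores)))
    rownames(scores) <- sprintf("p%04d", seq_len(nrow(scores)))
  if (is.null(colnames(scores)))
    colnames(scores) <- sprintf("item%03d", seq_len(ncol(scores)))
  if (!is.null(items)) {
    if (!"item_id" %in% names(items))
      stop("`items` must have an `item_id` column", call. = FALSE)
    if (!setequal(items$item_id, colnames(scores)))
      stop("`items$item_id` must match the score columns", call. = FALSE)
    items <- items[match(colnames(scores), items$item_id), , drop = FALSE]
    rownames(items) <- NULL
  }
  structure(list(scores = scores, items = items),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  sc <- x$scores
  cat(sprintf("Response matrix: %d persons x %d items, %.1f%% observed\n",
              nrow(sc), ncol(sc), 100 * mean(!is.na(sc))))
  cat(sprintf("  overall success rate: %.3f\n", mean(sc, na.rm = TRUE)))
  invisible(x)
}

#' Write / read a response matrix as CSV
#'
#' Persons in rows (first column `person_id`), items in columns; cells
#' 0, 1, or empty for missing. Item annotations travel in a separate
#' feature CSV keyed by `item_id`.
#'
#' @param matrix A `"response_matrix"` object.
#' @param path Matrix CSV path.
#' @param items_path Optional path for the item-feature CSV.
#' @return `write_matrix()` returns `path` invisibly; `read_matrix()` a
#'   `"response_matrix"`.
#' @export
write_matrix <- function(matrix, path, items_path = NULL) {
  df <- data.frame(person_id = rownames(matrix$scores),
                   matrix$scores, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  if (!is.null(items_path) && !is.null(matrix$items))
    utils::write.csv(matrix$items, items_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, items_path = NULL) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("response-matrix file is empty", call. = FALSE)
  if (names(df)[1L] != "person_id")
    stop("first column must be `person_id`", call. = FALSE)
  sc <- as.matrix(df[, -1L, drop = FALSE])
  bad_flag <- matrix(!(sc %in% c(0, 1) | is.na(sc)), nrow = nrow(sc))
  bad <- which(bad_flag, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid score at row %d, item %s", bad[1L, 1L],
                 colnames(sc)[bad[1L, 2L]]), call. = FALSE)
  storage.mode(sc) <- "integer"
  rownames(sc) <- df$person_id
  items <- if (!is.null(items_path))
    utils::read.csv(items_path, stringsAsFactors = FALSE) else NULL
  response_matrix(sc, items)
}
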