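# Input validation helpers. User-facing validation failures carry the
# "istclean_validation_error" condition class so the CLI can map them to
# exit code 2, distinct from internal errors.

stop_invalid <- function(msg, ...) {
  abort(paste0(msg, ...), class = "istclean_validation_error")
}

check_cell_table <- function(cells) {
  if (!is.data.frame(cells)) {
    stop_invalid("`cells` must be a data frame with columns cell_id, x, y.")
  }
  missing <- setdiff(c("cell_id", "x", "y"), names(cells))
  if (length(missing) > 0) {
    stop_invalid("`cells` is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(cells$cell_id)) {
    stop_invalid("`cells$cell_id` contains duplicated ids.")
  }
  bad <- !is.finite(cells$x) | !is.finite(cells$y)
  if (any(bad)) {
    stop_invalid(
      "non-finite coordinates for cell_id(s): ",
      paste(head(cells$cell_id[bad], 5L), collapse = ", ")
    )
  }
  invisible(cells)
}

check_transcript_table <- function(tx) {
  if (!is.data.frame(tx)) {
    stop_invalid("`transcripts` must be a data frame with columns x, y, gene.")
  }
  missing <- setdiff(c("x", "y", "gene"), names(tx))
  if (length(missing) > 0) {
    stop_invalid("`transcripts` is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(tx) < 1) stop_invalid("`transcripts` has no rows.")
  if (any(!is.finite(tx$x) | !is.finite(tx$y))) {
    stop_invalid("`transcripts` contains non-finite coordinates.")
  }
  invisible(tx)
}

as_dgc <- function(m) {
  if (!inherits(m, "Matrix")) m <- Matrix::Matrix(m, sparse = TRUE)
  as(as(m, "generalMatrix"), "CsparseMatrix")
}

# Coerce counts to a cells x genes dgCMatrix, checking integer-valuedness.
check_count_matrix <- function(counts, allow_real = FALSE) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!inherits(counts, "sparseMatrix")) {
    if (!is.matrix(counts) || !is.numeric(counts)) {
      stop_invalid("`counts` must be a numeric matrix or sparse Matrix.")
    }
  }
  m <- as_dgc(counts)
  if (any(m@x < 0)) stop_invalid("`counts` contains negative values.")
  if (!allow_real && any(m@x != round(m@x))) {
    stop_invalid(
      "`counts` contains non-integer values; counts must be integers ",
      "(use allow_real = TRUE only for metric computations)."
    )
  }
  m
}
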