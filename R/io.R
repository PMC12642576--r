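# Readers and writers for the on-disk formats: Matrix Market counts with
# sibling gene/cell TSVs, Xenium-dialect transcript CSVs, and JSON
# config/report files. Micrometre coordinates throughout; cell and gene
# order is preserved from the input files.

#' Read a count matrix from Matrix Market format
#'
#' Reads a `.mtx` coordinate file plus sibling TSVs naming the genes and
#' cells. The internal orientation is always cells x genes regardless of the
#' on-disk orientation.
#'
#' @param mtx Path to the `.mtx` file.
#' @param genes,cells Paths to the gene and cell TSVs. Default: `genes.tsv`
#'   and `cells.tsv` next to `mtx`. The first column of each is used as ids.
#' @param orientation `"cells_by_genes"` (default) or `"genes_by_cells"`
#'   describing the on-disk matrix.
#' @param allow_real Accept non-integer values (for metric computations on
#'   weighted counts). Default FALSE.
#' @return Sparse cells x genes `dgCMatrix` with cell/gene dimnames.
#' @export
read_count_matrix <- function(mtx, genes = NULL, cells = NULL,
                              orientation = c("cells_by_genes", "genes_by_cells"),
                              allow_real = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(mtx)) stop_invalid("count matrix file not found: ", mtx)
  genes <- genes %||% file.path(dirname(mtx), "genes.tsv")
  cells <- cells %||% file.path(dirname(mtx), "cells.tsv")
  for (f in c(genes, cells)) {
    if (!file.exists(f)) stop_invalid("sibling table not found: ", f)
  }
  m <- Matrix::readMM(mtx)
  gene_tab <- readr::read_tsv(genes, show_col_types = FALSE)
  cell_tab <- readr::read_tsv(cells, show_col_types = FALSE)
  gene_ids <- as.character(gene_tab[[1]])
  cell_ids <- as.character(cell_tab[[1]])
  if (orientation == "genes_by_cells") m <- Matrix::t(m)
  if (nrow(m) != length(cell_ids) || ncol(m) != length(gene_ids)) {
    stop_invalid(sprintf(
      "matrix is %d x %d (cells x genes) but %s lists %d cells and %s lists %d genes.",
      nrow(m), ncol(m), cells, length(cell_ids), genes, length(gene_ids)
    ))
  }
  dimnames(m) <- list(cell_ids, gene_ids)
  check_count_matrix(m, allow_real = allow_real)
}

#' Write a count matrix in Matrix Market format
#'
#' @param counts Cells x genes matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix; writes `<prefix>.mtx`, `genes.tsv`,
#'   `cells.tsv`.
#' @return Invisibly, the path of the `.mtx` file.
#' @export
write_count_matrix <- function(counts, dir, prefix = "counts") {
  counts <- check_count_matrix(counts, allow_real = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(dir, paste0(prefix, ".mtx"))
  Matrix::writeMM(counts, mtx)
  readr::write_tsv(
    tibble::tibble(gene = colnames(counts) %||% paste0("g", seq_len(ncol(counts)))),
    file.path(dir, "genes.tsv")
  )
  readr::write_tsv(
    tibble::tibble(cell_id = rownames(counts) %||% paste0("c", seq_len(nrow(counts)))),
    file.path(dir, "cells.tsv")
  )
  invisible(mtx)
}

#' Read a transcript table (Xenium-style CSV dialect)
#'
#' @param path CSV/TSV path (gz-compressed accepted).
#' @param col_x,col_y,col_gene Column names in the file; Xenium
#'   `transcripts.csv` defaults.
#' @param col_quality,min_quality Optional quality column and minimum value;
#'   no filtering by default.
#' @return Tibble with columns `x`, `y`, `gene`.
#' @export
read_transcripts <- function(path, col_x = "x_location", col_y = "y_location",
                             col_gene = "feature_name", col_quality = NULL,
                             min_quality = NULL) {
  if (!file.exists(path)) stop_invalid("transcript file not found: ", path)
  tx <- readr::read_delim(path, show_col_types = FALSE)
  need <- c(col_x, col_y, col_gene, col_quality)
  missing <- setdiff(need, names(tx))
  if (length(missing) > 0) {
    stop_invalid(
      "transcript file lacks column(s): ", paste(missing, collapse = ", "),
      " (configure col_x/col_y/col_gene for non-Xenium dialects)."
    )
  }
  out <- tibble::tibble(
    x = as.numeric(tx[[col_x]]),
    y = as.numeric(tx[[col_y]]),
    gene = as.character(tx[[col_gene]])
  )
  if (!is.null(col_quality) && !is.null(min_quality)) {
    out <- out[as.numeric(tx[[col_quality]]) >= min_quality, ]
  }
  check_transcript_table(out)
}

#' Read a cell table (TSV with header `cell_id  x  y`)
#'
#' @param path TSV path.
#' @return Tibble with `cell_id`, `x`, `y` (micrometres).
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop_invalid("cell table not found: ", path)
  cells <- readr::read_tsv(path, show_col_types = FALSE)
  check_cell_table(cells)
  tibble::as_tibble(cells)
}

#' Write a simulated dataset to a directory
#'
#' Writes `counts.mtx` + `genes.tsv` + `cells.tsv` (ids and coordinates),
#' `transcripts.csv` (Xenium dialect), `truth.tsv` (long format of non-zero
#' truth labels) and `labels.tsv`.
#'
#' @param sim A `synthetic_dataset`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(sim$counts, file.path(dir, "counts.mtx"))
  readr::write_tsv(sim$panel, file.path(dir, "genes.tsv"))
  readr::write_tsv(sim$cells, file.path(dir, "cells.tsv"))
  readr::write_csv(
    tibble::tibble(
      x_location = sim$transcripts$x,
      y_location = sim$transcripts$y,
      feature_name = sim$transcripts$gene
    ),
    file.path(dir, "transcripts.csv")
  )
  tr <- Matrix::summary(sim$truth)
  readr::write_tsv(
    tibble::tibble(
      cell_id = rownames(sim$truth)[tr$i],
      gene = colnames(sim$truth)[tr$j],
      label = c("endogenous", "contaminated")[tr$x]
    ),
    file.path(dir, "truth.tsv")
  )
  readr::write_tsv(
    tibble::tibble(cell_id = sim$cells$cell_id, cell_type = sim$labels),
    file.path(dir, "labels.tsv")
  )
  invisible(dir)
}

# --- run configuration ------------------------------------------------------

default_run_config <- function() {
  list(
    radius_um = 50, n_hexbins = 200, alpha_cutoff = 0.75, n_restarts = 10,
    offset_mode = "additive", seed = 0L, min_nonzero_genes = 3L
  )
}

#' Build a validated run configuration
#'
#' Applies defaults and rejects unknown keys. Used by the CLI and the run
#' report.
#'
#' @param ... Named overrides of the defaults `radius_um` (50), `n_hexbins`
#'   (200), `alpha_cutoff` (0.75), `n_restarts` (10), `offset_mode`
#'   ("additive"), `seed` (0), `min_nonzero_genes` (3).
#' @return Named list with all keys populated.
#' @export
run_config <- function(...) {
  overrides <- list(...)
  if (length(overrides) == 1 && is.list(overrides[[1]]) && is.null(names(overrides))) {
    overrides <- overrides[[1]]
  }
  defaults <- default_run_config()
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop_invalid("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(defaults, overrides)
  if (!cfg$offset_mode %in% c("additive", "multiplicative")) {
    stop_invalid("`offset_mode` must be 'additive' or 'multiplicative'.")
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_restarts <- as.integer(cfg$n_restarts)
  cfg$min_nonzero_genes <- as.integer(cfg$min_nonzero_genes)
  cfg
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
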