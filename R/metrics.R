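# Evaluation statistics: mutually exclusive co-expression rate (MECR),
# positive marker purity (PMP), and reference-based derivation of
# cell-type-specific genes, marker sets and mutually exclusive gene pairs.

#' Mutually exclusive co-expression rate
#'
#' For each gene pair, the fraction of cells expressing both genes among the
#' cells expressing either. For biologically mutually exclusive pairs this is
#' a false-positive proxy: co-expression must be a technical artefact, so a
#' good denoiser drives it towards zero. Real-valued inputs (from tools that
#' return weighted counts) are rounded half-up first: a value `>= 0.5` counts
#' as positive.
#'
#' @param counts Cells x genes matrix; real values allowed.
#' @param pairs Data frame with columns `gene_a`, `gene_b`.
#' @return Tibble with `gene_a`, `gene_b`, `n_both`, `n_either`, `mecr`.
#'   Pairs expressed in no cell get `mecr = NA` (0/0) with a warning.
#' @export
mecr <- function(counts, pairs) {
  counts <- check_count_matrix(counts, allow_real = TRUE)
  if (!is.data.frame(pairs) || !all(c("gene_a", "gene_b") %in% names(pairs))) {
    stop_invalid("`pairs` must be a data frame with columns gene_a, gene_b.")
  }
  genes <- colnames(counts)
  if (is.null(genes)) stop_invalid("`counts` must have gene column names.")
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), genes)
  if (length(missing) > 0) {
    stop_invalid("gene(s) absent from `counts`: ", paste(head(missing, 5), collapse = ", "))
  }

  pos <- counts >= 0.5 # rounding half-up: x >= 0.5 is a positive cell
  ia <- match(pairs$gene_a, genes)
  ib <- match(pairs$gene_b, genes)
  n_both <- integer(nrow(pairs))
  n_either <- integer(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- pos[, ia[k]]
    b <- pos[, ib[k]]
    n_both[k] <- sum(a & b)
    n_either[k] <- sum(a | b)
  }
  rate <- ifelse(n_either > 0, n_both / n_either, NA_real_)
  if (anyNA(rate)) {
    warn(sprintf(
      "%d pair(s) expressed in no cell; MECR undefined (NA) for them.",
      sum(is.na(rate))
    ))
  }
  tibble::tibble(
    gene_a = as.character(pairs$gene_a),
    gene_b = as.character(pairs$gene_b),
    n_both = n_both,
    n_either = n_either,
    mecr = rate
  )
}

# Pairwise two-sample AUC (rank-sum with mid-ranks) of `focal` vs `other`
# for every gene (columns).
pairwise_auc <- function(mat_focal, mat_other) {
  n1 <- nrow(mat_focal)
  n2 <- nrow(mat_other)
  vapply(seq_len(ncol(mat_focal)), function(j) {
    r <- rank(c(mat_focal[, j], mat_other[, j]))
    (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  }, numeric(1))
}

#' Derive cell-type-specific genes from a labelled reference
#'
#' Per gene and cell type computes the mean pairwise AUC (mid-rank two-sample
#' AUC of the focal type against each other type, averaged), the in-type
#' detection rate and the out-of-type detection rate (fraction of all other
#' cells with a non-zero count). A gene is type-specific when it is detected
#' in at least `min_in` of the type, at most `max_out` of the rest, and lands
#' in the top `frac_auc` quantile by mean AUC among the genes passing the
#' detection filters for that type (ceiling rounding, descending AUC).
#'
#' @param ref_counts Reference cells x genes count matrix.
#' @param labels Cell-type label per reference cell.
#' @param frac_auc Top fraction by mean AUC retained. Default 0.30.
#' @param min_in Minimum in-type detection rate. Default 0.50.
#' @param max_out Maximum out-of-type detection rate. Default 0.05.
#' @return Tibble with `gene`, `cell_type`, `auc`, `detect_in`, `detect_out`,
#'   `specific` (logical).
#' @export
derive_markers <- function(ref_counts, labels, frac_auc = 0.30,
                           min_in = 0.50, max_out = 0.05) {
  ref_counts <- check_count_matrix(ref_counts, allow_real = TRUE)
  labels <- as.character(labels)
  if (length(labels) != nrow(ref_counts)) {
    stop_invalid("`labels` must have one entry per reference cell.")
  }
  types <- sort(unique(labels))
  if (length(types) < 2) {
    stop_invalid("need at least 2 cell types in the reference.")
  }
  if (min(table(labels)) < 2) {
    stop_invalid("every cell type needs at least 2 reference cells.")
  }
  genes <- colnames(ref_counts)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(ref_counts)))
  dense <- as.matrix(ref_counts)

  res <- purrr::map(types, function(t) {
    in_t <- labels == t
    det_in <- colMeans(dense[in_t, , drop = FALSE] > 0)
    det_out <- colMeans(dense[!in_t, , drop = FALSE] > 0)
    aucs <- sapply(setdiff(types, t), function(u) {
      pairwise_auc(dense[in_t, , drop = FALSE], dense[labels == u, , drop = FALSE])
    })
    mean_auc <- if (is.matrix(aucs)) rowMeans(aucs) else aucs
    passes <- det_in >= min_in & det_out <= max_out
    specific <- logical(length(genes))
    if (any(passes)) {
      pool <- which(passes)
      k <- ceiling(frac_auc * length(pool))
      keep <- pool[order(-mean_auc[pool], pool)][seq_len(k)]
      specific[keep] <- TRUE
    }
    tibble::tibble(
      gene = genes, cell_type = t, auc = as.numeric(mean_auc),
      detect_in = as.numeric(det_in), detect_out = as.numeric(det_out),
      specific = specific
    )
  })
  dplyr::bind_rows(res)
}

#' Derive mutually exclusive gene pairs from a labelled reference
#'
#' Runs [derive_markers()] and pairs every type-specific gene with every
#' specific gene of a *different* type. Pairs are unordered and de-duplicated.
#'
#' @inheritParams derive_markers
#' @return Tibble with `gene_a`, `gene_b`, `type_a`, `type_b`; the full
#'   marker table is attached as attribute `markers`. Empty (with a warning)
#'   when fewer than two types retain specific genes.
#' @export
derive_exclusive_pairs <- function(ref_counts, labels, frac_auc = 0.30,
                                   min_in = 0.50, max_out = 0.05) {
  markers <- derive_markers(ref_counts, labels, frac_auc, min_in, max_out)
  spec <- dplyr::filter(markers, .data$specific)
  types_with <- unique(spec$cell_type)
  if (length(types_with) < 2) {
    warn("fewer than 2 cell types retain specific genes; no exclusive pairs derived.")
    out <- tibble::tibble(
      gene_a = character(), gene_b = character(),
      type_a = character(), type_b = character()
    )
    attr(out, "markers") <- markers
    return(out)
  }
  combos <- utils::combn(sort(types_with), 2, simplify = FALSE)
  out <- purrr::map(combos, function(tt) {
    ga <- spec$gene[spec$cell_type == tt[1]]
    gb <- spec$gene[spec$cell_type == tt[2]]
    tidyr::expand_grid(gene_a = ga, gene_b = gb) |>
      dplyr::mutate(type_a = tt[1], type_b = tt[2])
  }) |>
    dplyr::bind_rows() |>
    dplyr::filter(.data$gene_a != .data$gene_b)
  # unordered de-duplication
  key <- ifelse(out$gene_a < out$gene_b,
                paste(out$gene_a, out$gene_b),
                paste(out$gene_b, out$gene_a))
  out <- out[!duplicated(key), ]
  attr(out, "markers") <- markers
  out
}

#' Positive marker purity
#'
#' Fraction of each cell's total counts that falls in the marker gene set of
#' its assigned cell type; a true-positive proxy (aggressive over-filtering
#' lowers it). The summary `mean_pmp` averages within each cell type first
#' and then across types, so types with few cells weigh equally.
#'
#' @param counts Cells x genes count matrix.
#' @param markers Either a data frame with columns `cell_type`, `gene`, or a
#'   named list of marker gene vectors per cell type.
#' @param labels Cell-type label per cell of `counts`.
#' @return Object of class `pmp_result`: list with `per_cell` (tibble
#'   `cell`, `cell_type`, `pmp`, `total`), `by_type` (within-type means) and
#'   `mean_pmp`. Cells with zero total count are excluded from the means
#'   with a warning.
#' @export
pmp <- function(counts, markers, labels) {
  counts <- check_count_matrix(counts, allow_real = TRUE)
  labels <- as.character(labels)
  if (length(labels) != nrow(counts)) {
    stop_invalid("`labels` must have one entry per cell.")
  }
  if (is.data.frame(markers)) {
    if (!all(c("cell_type", "gene") %in% names(markers))) {
      stop_invalid("`markers` data frame needs columns cell_type, gene.")
    }
    markers <- split(as.character(markers$gene), as.character(markers$cell_type))
  }
  if (is.null(names(markers))) {
    stop_invalid("`markers` must be named by cell type.")
  }
  types <- unique(labels)
  missing <- setdiff(types, names(markers))
  if (length(missing) > 0) {
    stop_invalid("no marker set for cell type(s): ", paste(missing, collapse = ", "))
  }
  genes <- colnames(counts)
  if (is.null(genes)) stop_invalid("`counts` must have gene column names.")

  total <- as.numeric(Matrix::rowSums(counts))
  marker_sum <- numeric(nrow(counts))
  for (t in types) {
    m <- intersect(markers[[t]], genes)
    rows <- which(labels == t)
    if (length(m) == 0) {
      marker_sum[rows] <- 0
      next
    }
    marker_sum[rows] <- as.numeric(
      Matrix::rowSums(counts[rows, m, drop = FALSE])
    )
  }
  pmp_i <- ifelse(total > 0, marker_sum / total, NA_real_)
  if (anyNA(pmp_i)) {
    warn(sprintf(
      "%d cell(s) with zero total count excluded from PMP means.",
      sum(is.na(pmp_i))
    ))
  }
  ids <- rownames(counts) %||% as.character(seq_len(nrow(counts)))
  per_cell <- tibble::tibble(
    cell = ids, cell_type = labels, total = total, pmp = pmp_i
  )
  by_type <- per_cell |>
    dplyr::filter(!is.na(.data$pmp)) |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(mean_pmp = mean(.data$pmp), n_cells = dplyr::n())
  structure(
    list(
      per_cell = per_cell,
      by_type = by_type,
      mean_pmp = mean(by_type$mean_pmp)
    ),
    class = "pmp_result"
  )
}

#' @export
print.pmp_result <- function(x, ...) {
  cat(sprintf(
    "<pmp_result> mean PMP %.4f over %d cell types (%d cells)\n",
    x$mean_pmp, nrow(x$by_type), nrow(x$per_cell)
  ))
  invisible(x)
}

#' @export
tidy.pmp_result <- function(x, ...) x$per_cell

#' @export
glance.pmp_result <- function(x, ...) {
  tibble::tibble(
    mean_pmp = x$mean_pmp,
    n_types = nrow(x$by_type),
    n_cells = nrow(x$per_cell),
    n_zero_total = sum(is.na(x$per_cell$pmp))
  )
}
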