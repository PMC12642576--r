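#' Denoise an image-based spatial transcriptomics count matrix
#'
#' End-to-end contamination removal: builds the radius neighbourhood over
#' cell centroids, optionally estimates the global ambient background from a
#' transcript table (hexagonal binning + two-component Gaussian mixture),
#' assembles the per-(cell, gene) offsets, fits the per-cell two-component
#' Poisson mixture by EM with restarts, and zeroes every gene whose
#' posterior probability of endogenous expression is at or below
#' `alpha_cutoff`. The adjusted matrix is integer-valued: each count is kept
#' whole or removed.
#'
#' Cells with fewer than `min_nonzero_genes` non-zero genes are not fitted
#' (a three-parameter mixture is unidentifiable there); their counts pass
#' through unchanged and they are flagged `skipped` in the fit table.
#' Per-cell computations are independent and use RNG streams derived from
#' `seed` and the cell index, so results do not depend on evaluation order.
#'
#' @param counts Cells x genes integer count matrix (dense or sparse). Row
#'   order must match `cells`.
#' @param cells Data frame with `cell_id`, `x`, `y` centroid coordinates in
#'   micrometres, one row per row of `counts`.
#' @param transcripts Optional transcript-level table (`x`, `y`, `gene`) for
#'   the global ambient background. When `NULL` the global offset is zero.
#' @param radius_um Neighbourhood radius d in micrometres. Default 50.
#' @param n_hexbins Target hexbin count for background estimation. Default 200.
#' @param alpha_cutoff Posterior filtering threshold. Default 0.75.
#' @param n_restarts EM restarts per cell. Default 10.
#' @param offset_mode `"additive"` or `"multiplicative"` component means.
#' @param seed Master seed. Default 0.
#' @param min_nonzero_genes Skip rule threshold. Default 3.
#' @return Object of class `denoise_result`: list with `adjusted` (sparse
#'   integer matrix), `posterior` (dense alpha matrix, `NA` rows for skipped
#'   cells), `fits` (per-cell tibble), `offsets`, `background`, `report`
#'   (config echo and run facts).
#' @export
denoise <- function(counts, cells, transcripts = NULL,
                    radius_um = 50, n_hexbins = 200, alpha_cutoff = 0.75,
                    n_restarts = 10, offset_mode = c("additive", "multiplicative"),
                    seed = 0L, min_nonzero_genes = 3L) {
  offset_mode <- match.arg(offset_mode)
  counts <- check_count_matrix(counts)
  check_cell_table(cells)
  if (nrow(counts) != nrow(cells)) {
    stop_invalid(sprintf(
      "`counts` has %d rows but `cells` has %d rows.", nrow(counts), nrow(cells)
    ))
  }
  if (nrow(counts) < 1 || ncol(counts) < 2) {
    stop_invalid("`counts` must have at least 1 cell and 2 genes.")
  }
  if (is.null(rownames(counts))) rownames(counts) <- as.character(cells$cell_id)

  nbrs <- neighbor_index(cells, radius = radius_um)

  background <- NULL
  warnings_log <- character()
  if (!is.null(transcripts)) {
    grid <- hexbin_transcripts(transcripts, n_bins = n_hexbins)
    gmm <- fit_background_gmm(grid$bins$total, seed = seed)
    background <- background_profile(grid, gmm, radius = radius_um)
  } else {
    warnings_log <- c(warnings_log, "global background disabled (no transcript table)")
  }

  offsets <- withCallingHandlers(
    compute_offsets(counts, nbrs, background),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )

  n <- nrow(counts)
  g <- ncol(counts)
  dense <- as.matrix(counts)
  adjusted <- dense
  posterior <- matrix(NA_real_, n, g, dimnames = dimnames(counts))

  fits <- vector("list", n)
  for (i in seq_len(n)) {
    x <- dense[i, ]
    nnz <- sum(x > 0)
    if (nnz < min_nonzero_genes) {
      fits[[i]] <- tibble::tibble(
        cell_id = rownames(counts)[i], pi = NA_real_, lambda_e = NA_real_,
        lambda_c = NA_real_, loglik = NA_real_, n_iter = NA_integer_,
        converged = NA, restart_index = NA_integer_, skipped = TRUE,
        reason = sprintf("fewer than %d non-zero genes", min_nonzero_genes)
      )
      next
    }
    fit <- suppressWarnings(fit_cell_mixture(
      x, offsets[i, ],
      n_restarts = n_restarts,
      seed = derive_cell_seed(seed, i),
      offset_mode = offset_mode
    ))
    posterior[i, ] <- fit$alpha
    adjusted[i, ] <- filter_counts(x, fit$alpha, cutoff = alpha_cutoff)
    fits[[i]] <- tibble::tibble(
      cell_id = rownames(counts)[i], pi = fit$pi, lambda_e = fit$lambda_e,
      lambda_c = fit$lambda_c, loglik = fit$loglik, n_iter = fit$n_iter,
      converged = fit$converged, restart_index = fit$restart_index,
      skipped = FALSE, reason = NA_character_
    )
  }
  fits <- dplyr::bind_rows(fits)

  report <- list(
    config = list(
      radius_um = radius_um, n_hexbins = n_hexbins,
      alpha_cutoff = alpha_cutoff, n_restarts = n_restarts,
      offset_mode = offset_mode, seed = as.integer(seed),
      min_nonzero_genes = as.integer(min_nonzero_genes),
      global_background = !is.null(background)
    ),
    n_cells = n,
    n_genes = g,
    n_skipped = sum(fits$skipped),
    n_not_converged = sum(!fits$converged, na.rm = TRUE),
    counts_in = sum(dense),
    counts_out = sum(adjusted),
    warnings = warnings_log,
    package_version = as.character(utils::packageVersion("istclean"))
  )

  structure(
    list(
      adjusted = as_dgc(adjusted),
      raw_totals = as.numeric(Matrix::rowSums(dense)),
      posterior = posterior,
      fits = fits,
      cells = tibble::as_tibble(cells),
      offsets = offsets,
      background = background,
      report = report
    ),
    class = "denoise_result"
  )
}

#' @export
print.denoise_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<denoise_result> %d cells x %d genes; %d skipped; counts %d -> %d (%.1f%% removed)\n",
    r$n_cells, r$n_genes, r$n_skipped, r$counts_in, r$counts_out,
    100 * (1 - r$counts_out / max(r$counts_in, 1))
  ))
  invisible(x)
}

#' @rdname denoise
#' @param x A `denoise_result`.
#' @param ... Unused.
#' @export
tidy.denoise_result <- function(x, ...) x$fits

#' @rdname denoise
#' @export
glance.denoise_result <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    n_cells = r$n_cells,
    n_genes = r$n_genes,
    n_skipped = r$n_skipped,
    n_not_converged = r$n_not_converged,
    counts_in = r$counts_in,
    counts_out = r$counts_out,
    frac_counts_removed = 1 - r$counts_out / max(r$counts_in, 1),
    mean_pi = mean(x$fits$pi, na.rm = TRUE)
  )
}

#' @rdname denoise
#' @param object A `denoise_result`.
#' @export
autoplot.denoise_result <- function(object, ...) {
  df <- object$cells
  df$kept_fraction <- as.numeric(Matrix::rowSums(object$adjusted)) /
    pmax(object$raw_totals, 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$kept_fraction), size = 0.8) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Fraction of counts kept per cell",
                  x = "x (um)", y = "y (um)", colour = "kept")
}
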