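# Synthetic image-based spatial transcriptomics generator with planted
# per-(cell, gene) ground truth: endogenous programs, neighbour spillover
# and ambient background, plus a molecule-level transcript table.

#' Simulation configuration
#'
#' Builds and validates the configuration for [simulate_dataset()]. The
#' defaults describe a two-type "interleaved" tissue: cross-type cell pairs
#' on a jittered grid confined to a central tissue block of the extent, so
#' each cell's radius-50 um neighbourhood is dominated by the opposite type
#' and the surrounding area is cell-free (giving the background estimator
#' genuine ambient-only bins).
#'
#' @param n_cells Number of cells. Default 2000.
#' @param extent Side length of the square field of view in micrometres.
#'   Default 7000.
#' @param n_types Number of cell types with disjoint expression programs.
#'   Default 2.
#' @param genes_per_type Program size per type. Default 50.
#' @param n_shared_genes Genes expressed by every type. Default 0.
#' @param n_noise_genes Panel genes expressed by no type (ambient only).
#'   Default 20.
#' @param expr_mean Poisson mean of an expressed gene. Default 10.
#' @param spill_rate Fraction of each neighbour's endogenous transcripts
#'   duplicated into a cell as contamination, in \[0, 1). Default 0.15.
#' @param ambient_rate Expected ambient counts per cell per gene.
#'   Default 0.02.
#' @param neighbor_radius Spillover radius in micrometres. Default 50.
#' @param layout `"paired"` (default; interleaved cross-type pairs) or
#'   `"uniform"` (cells uniform over the extent, types assigned at random).
#' @param pair_sep Centroid separation within a pair (paired layout), um.
#'   Default 25.
#' @param tissue_fraction Fraction of the extent area occupied by the tissue
#'   block (paired layout). Default 0.5.
#' @param cell_radius Disc radius for molecule placement around a cell's
#'   centroid, um. Default 10.
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   config. Default 0.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cells = 2000, extent = 7000, n_types = 2,
                       genes_per_type = 50, n_shared_genes = 0,
                       n_noise_genes = 20, expr_mean = 10, spill_rate = 0.15,
                       ambient_rate = 0.02, neighbor_radius = 50,
                       layout = c("paired", "uniform"), pair_sep = 25,
                       tissue_fraction = 0.5, cell_radius = 10, seed = 0L) {
  layout <- match.arg(layout)
  cfg <- list(
    n_cells = as.integer(n_cells), extent = as.numeric(extent),
    n_types = as.integer(n_types), genes_per_type = as.integer(genes_per_type),
    n_shared_genes = as.integer(n_shared_genes),
    n_noise_genes = as.integer(n_noise_genes),
    expr_mean = as.numeric(expr_mean), spill_rate = as.numeric(spill_rate),
    ambient_rate = as.numeric(ambient_rate),
    neighbor_radius = as.numeric(neighbor_radius), layout = layout,
    pair_sep = as.numeric(pair_sep),
    tissue_fraction = as.numeric(tissue_fraction),
    cell_radius = as.numeric(cell_radius), seed = as.integer(seed)
  )
  with(cfg, {
    if (n_cells < 1) stop_invalid("`n_cells` must be >= 1.")
    if (extent <= 0) stop_invalid("`extent` must be positive.")
    if (n_types < 1) stop_invalid("`n_types` must be >= 1.")
    if (genes_per_type < 1) stop_invalid("`genes_per_type` must be >= 1.")
    if (n_shared_genes < 0 || n_noise_genes < 0) {
      stop_invalid("gene counts must be non-negative.")
    }
    if (expr_mean < 0 || ambient_rate < 0) stop_invalid("rates must be non-negative.")
    if (spill_rate < 0 || spill_rate >= 1) stop_invalid("`spill_rate` must be in [0, 1).")
    if (neighbor_radius <= 0) stop_invalid("`neighbor_radius` must be positive.")
    if (tissue_fraction <= 0 || tissue_fraction > 1) {
      stop_invalid("`tissue_fraction` must be in (0, 1].")
    }
  })
  structure(cfg, class = "sim_config")
}

sim_gene_panel <- function(cfg) {
  panel <- character(0)
  program <- character(0)
  for (t in seq_len(cfg$n_types)) {
    g <- sprintf("T%dG%02d", t, seq_len(cfg$genes_per_type))
    panel <- c(panel, g)
    program <- c(program, rep(paste0("type", t), cfg$genes_per_type))
  }
  if (cfg$n_shared_genes > 0) {
    panel <- c(panel, sprintf("SHG%02d", seq_len(cfg$n_shared_genes)))
    program <- c(program, rep("shared", cfg$n_shared_genes))
  }
  if (cfg$n_noise_genes > 0) {
    panel <- c(panel, sprintf("NSG%02d", seq_len(cfg$n_noise_genes)))
    program <- c(program, rep("none", cfg$n_noise_genes))
  }
  tibble::tibble(gene = panel, program = program)
}

sim_positions <- function(cfg) {
  n <- cfg$n_cells
  if (cfg$layout == "uniform") {
    tibble::tibble(
      x = runif(n, 0, cfg$extent),
      y = runif(n, 0, cfg$extent),
      type = paste0("type", sample(cfg$n_types, n, replace = TRUE))
    )
  } else {
    n_pairs <- ceiling(n / 2)
    ng <- ceiling(sqrt(n_pairs))
    side <- cfg$extent * sqrt(cfg$tissue_fraction)
    pitch <- side / ng
    margin <- (cfg$extent - side) / 2
    slots <- tidyr::expand_grid(ix = seq_len(ng) - 1, iy = seq_len(ng) - 1)
    slots <- slots[sample(nrow(slots), n_pairs), ]
    cx <- margin + (slots$ix + 0.5) * pitch + runif(n_pairs, -0.15, 0.15) * pitch
    cy <- margin + (slots$iy + 0.5) * pitch + runif(n_pairs, -0.15, 0.15) * pitch
    ang <- runif(n_pairs, 0, 2 * pi)
    dx <- cos(ang) * cfg$pair_sep / 2
    dy <- sin(ang) * cfg$pair_sep / 2
    ta <- sample(cfg$n_types, n_pairs, replace = TRUE)
    tb <- if (cfg$n_types == 1) ta else {
      vapply(ta, function(t) {
        others <- setdiff(seq_len(cfg$n_types), t)
        others[sample.int(length(others), 1)]
      }, integer(1))
    }
    out <- tibble::tibble(
      x = c(rbind(cx + dx, cx - dx)),
      y = c(rbind(cy + dy, cy - dy)),
      type = paste0("type", c(rbind(ta, tb)))
    )
    out[seq_len(n), ]
  }
}

#' Simulate an IST dataset with planted contamination ground truth
#'
#' Draws cell positions and type labels, endogenous counts (Poisson on each
#' cell's program genes), spillover contamination (binomial thinning of each
#' within-radius neighbour's realised endogenous counts at `spill_rate`),
#' and ambient counts (Poisson at `ambient_rate` for every cell and gene).
#' Molecule positions are drawn uniformly in a disc around the owning cell,
#' and extracellular ambient molecules (expected count
#' `ambient_rate * n_genes * n_cells`) are scattered uniformly over the
#' extent, forming the transcript table used for background estimation.
#'
#' @param cfg A [sim_config()] (or arguments for one, via `...`).
#' @param ... Passed to [sim_config()] when `cfg` is missing.
#' @return Object of class `synthetic_dataset`: list with `counts` (sparse
#'   cells x genes), `cells` (tibble `cell_id`, `x`, `y`), `labels`
#'   (cell-type vector), `transcripts` (tibble `x`, `y`, `gene`), `endo` and
#'   `contam` (sparse component matrices with `counts = endo + contam`),
#'   `truth` (sparse matrix coded 0 = zero, 1 = endogenous,
#'   2 = contaminated), `panel` (gene/program tibble), `config`.
#' @export
simulate_dataset <- function(cfg = sim_config(...), ...) {
  stopifnot(inherits(cfg, "sim_config"))
  panel <- sim_gene_panel(cfg)
  g <- nrow(panel)
  n <- cfg$n_cells

  withr::with_seed(cfg$seed, {
    pos <- sim_positions(cfg)
    cells <- tibble::tibble(
      cell_id = sprintf("cell_%04d", seq_len(n)),
      x = pos$x, y = pos$y
    )
    labels <- pos$type

    expressed <- outer(labels, panel$program, function(l, p) p == l | p == "shared")
    endo <- matrix(0L, n, g)
    endo[expressed] <- rpois(sum(expressed), cfg$expr_mean)

    nbrs <- neighbor_index(cells, radius = cfg$neighbor_radius)
    contam <- matrix(0L, n, g)
    for (i in seq_len(n)) {
      for (t in nbrs$neighbors[[i]]) {
        src <- endo[t, ]
        nz <- which(src > 0)
        if (length(nz) > 0) {
          contam[i, nz] <- contam[i, nz] +
            rbinom(length(nz), size = src[nz], prob = cfg$spill_rate)
        }
      }
    }
    if (cfg$ambient_rate > 0) {
      contam <- contam + matrix(rpois(n * g, cfg$ambient_rate), n, g)
    }

    counts <- endo + contam
    dimnames(counts) <- list(cells$cell_id, panel$gene)
    dimnames(endo) <- dimnames(counts)
    dimnames(contam) <- dimnames(counts)

    # molecule-level table: every counted molecule in a disc around its cell
    per_cell_tot <- rowSums(counts)
    mol_cell <- rep(seq_len(n), per_cell_tot)
    mol_gene <- unlist(lapply(seq_len(n), function(i) {
      rep(panel$gene, counts[i, ])
    }), use.names = FALSE)
    rad <- cfg$cell_radius * sqrt(runif(length(mol_cell)))
    ang <- runif(length(mol_cell), 0, 2 * pi)
    tx <- tibble::tibble(
      x = cells$x[mol_cell] + rad * cos(ang),
      y = cells$y[mol_cell] + rad * sin(ang),
      gene = mol_gene
    )
    n_extra <- rpois(1, cfg$ambient_rate * g * n)
    if (n_extra > 0) {
      tx <- dplyr::bind_rows(tx, tibble::tibble(
        x = runif(n_extra, 0, cfg$extent),
        y = runif(n_extra, 0, cfg$extent),
        gene = panel$gene[sample.int(g, n_extra, replace = TRUE)]
      ))
    }

    truth <- matrix(0L, n, g, dimnames = dimnames(counts))
    truth[endo > 0] <- 1L
    truth[endo == 0 & contam > 0] <- 2L

    structure(
      list(
        counts = as_dgc(counts),
        cells = cells,
        labels = labels,
        transcripts = tx,
        endo = as_dgc(endo),
        contam = as_dgc(contam),
        truth = as_dgc(truth),
        panel = panel,
        n_extracellular = n_extra,
        config = cfg
      ),
      class = "synthetic_dataset"
    )
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d cells x %d genes, %d molecules (%d extracellular), %d types, seed %d\n",
    nrow(x$counts), ncol(x$counts), nrow(x$transcripts), x$n_extracellular,
    x$config$n_types, x$config$seed
  ))
  invisible(x)
}

#' Marker sets and exclusive pairs implied by the planted programs
#'
#' Convenience accessors for evaluation: the planted program genes per type,
#' and all cross-program gene pairs (never co-endogenous by construction).
#'
#' @param sim A `synthetic_dataset`.
#' @return For `planted_markers`, a tibble `cell_type`, `gene`; for
#'   `planted_pairs`, a tibble `gene_a`, `gene_b`.
#' @export
planted_markers <- function(sim) {
  stopifnot(inherits(sim, "synthetic_dataset"))
  p <- dplyr::filter(sim$panel, startsWith(.data$program, "type"))
  tibble::tibble(cell_type = p$program, gene = p$gene)
}

#' @rdname planted_markers
#' @export
planted_pairs <- function(sim) {
  m <- planted_markers(sim)
  types <- unique(m$cell_type)
  if (length(types) < 2) {
    return(tibble::tibble(gene_a = character(), gene_b = character()))
  }
  purrr::map(utils::combn(sort(types), 2, simplify = FALSE), function(tt) {
    tidyr::expand_grid(
      gene_a = m$gene[m$cell_type == tt[1]],
      gene_b = m$gene[m$cell_type == tt[2]]
    )
  }) |> dplyr::bind_rows()
}

#' Compare a denoising result against the planted ground truth
#'
#' Sensitivity is the fraction of truly endogenous (cell, gene) entries whose
#' counts survive; specificity is the fraction of contaminated entries whose
#' counts are removed. Optionally also reports MECR and mean PMP before and
#' after denoising, given gene pairs and marker sets.
#'
#' @param result A `denoise_result`, or an adjusted cells x genes matrix.
#' @param sim The `synthetic_dataset` the result was computed from.
#' @param pairs Optional pairs for MECR (default: planted cross-type pairs).
#' @param markers Optional marker sets for PMP (default: planted programs).
#' @param metrics Compute MECR/PMP before and after. Default TRUE.
#' @return Object of class `truth_eval`: list with `sensitivity`,
#'   `specificity`, `by_type` tibble, and (if `metrics`) `mecr_raw`,
#'   `mecr_denoised`, `pmp_raw`, `pmp_denoised` (means).
#' @export
evaluate_against_truth <- function(result, sim, pairs = NULL, markers = NULL,
                                   metrics = TRUE) {
  stopifnot(inherits(sim, "synthetic_dataset"))
  adjusted <- if (inherits(result, "denoise_result")) result$adjusted else result
  adjusted <- check_count_matrix(adjusted, allow_real = TRUE)
  if (!all(dim(adjusted) == dim(sim$counts))) {
    stop_invalid("`result` does not match the dimensions of the simulated counts.")
  }
  truth <- as.matrix(sim$truth)
  adj <- as.matrix(adjusted)
  kept <- adj > 0

  is_endo <- truth == 1L
  is_cont <- truth == 2L
  sensitivity <- mean(kept[is_endo])
  specificity <- mean(!kept[is_cont])

  by_type <- purrr::map(sort(unique(sim$labels)), function(t) {
    rows <- sim$labels == t
    tibble::tibble(
      cell_type = t,
      sensitivity = mean(kept[rows, ][is_endo[rows, ]]),
      specificity = mean(!kept[rows, ][is_cont[rows, ]]),
      n_cells = sum(rows)
    )
  }) |> dplyr::bind_rows()

  out <- list(
    sensitivity = sensitivity,
    specificity = specificity,
    by_type = by_type
  )
  if (metrics) {
    if (is.null(pairs)) pairs <- planted_pairs(sim)
    if (is.null(markers)) markers <- planted_markers(sim)
    if (nrow(pairs) > 0) {
      out$mecr_raw <- mean(suppressWarnings(mecr(sim$counts, pairs))$mecr, na.rm = TRUE)
      out$mecr_denoised <- mean(suppressWarnings(mecr(adjusted, pairs))$mecr, na.rm = TRUE)
    }
    out$pmp_raw <- suppressWarnings(pmp(sim$counts, markers, sim$labels))$mean_pmp
    out$pmp_denoised <- suppressWarnings(pmp(adjusted, markers, sim$labels))$mean_pmp
  }
  structure(out, class = "truth_eval")
}

#' @export
print.truth_eval <- function(x, ...) {
  cat(sprintf(
    "<truth_eval> sensitivity %.3f, specificity %.3f\n",
    x$sensitivity, x$specificity
  ))
  if (!is.null(x$mecr_raw)) {
    cat(sprintf("  MECR %.4f -> %.4f; mean PMP %.4f -> %.4f\n",
                x$mecr_raw, x$mecr_denoised, x$pmp_raw, x$pmp_denoised))
  }
  invisible(x)
}

#' @export
glance.truth_eval <- function(x, ...) {
  tibble::tibble(
    sensitivity = x$sensitivity,
    specificity = x$specificity,
    mecr_raw = x$mecr_raw %||% NA_real_,
    mecr_denoised = x$mecr_denoised %||% NA_real_,
    pmp_raw = x$pmp_raw %||% NA_real_,
    pmp_denoised = x$pmp_denoised %||% NA_real_
  )
}

#' @export
autoplot.synthetic_dataset <- function(object, ...) {
  df <- object$cells
  df$type <- object$labels
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$type)) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Simulated cell positions", x = "x (um)", y = "y (um)")
}
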