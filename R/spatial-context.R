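#' Build a radius neighbourhood index over cell centroids
#'
#' For every cell, finds all other cells whose centroid lies within `radius`
#' micrometres (Euclidean distance, boundary inclusive). The neighbourhood of
#' a cell never contains the cell itself, and the relation is symmetric.
#'
#' @param cells Data frame with columns `cell_id`, `x`, `y` (coordinates in
#'   micrometres).
#' @param radius Neighbourhood radius in micrometres. Default 50.
#' @return An object of class `nbr_index`: a list with elements `cell_id`,
#'   `radius`, `neighbors` (list of integer vectors of neighbour row indices)
#'   and `adjacency` (sparse symmetric 0/1 matrix).
#' @export
#' @examples
#' cells <- tibble::tibble(cell_id = c("a", "b", "c"),
#'                         x = c(0, 30, 100), y = 0)
#' neighbor_index(cells, radius = 50)
neighbor_index <- function(cells, radius = 50) {
  check_cell_table(cells)
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) || radius <= 0) {
    stop_invalid("`radius` must be a single positive number (micrometres).")
  }
  n <- nrow(cells)
  x <- cells$x
  y <- cells$y

  # Grid bucketing: candidate neighbours can only sit in the 3x3 block of
  # radius-sized grid squares around a cell, so the pair search stays near
  # O(n) for homogeneous point sets.
  gx <- floor(x / radius)
  gy <- floor(y / radius)
  key <- paste(gx, gy)
  buckets <- split(seq_len(n), key)

  nbrs <- vector("list", n)
  r2 <- radius^2
  for (b in buckets) {
    bx <- gx[b[1]]
    by <- gy[b[1]]
    cand <- unlist(
      buckets[paste(rep(bx + (-1:1), each = 3), rep(by + (-1:1), 3))],
      use.names = FALSE
    )
    for (i in b) {
      d2 <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
      hit <- cand[d2 <= r2]
      nbrs[[i]] <- sort(hit[hit != i])
    }
  }

  deg <- lengths(nbrs)
  adjacency <- Matrix::sparseMatrix(
    i = rep.int(seq_len(n), deg),
    j = unlist(nbrs, use.names = FALSE),
    x = 1,
    dims = c(n, n),
    dimnames = list(cells$cell_id, cells$cell_id)
  )

  structure(
    list(
      cell_id = as.character(cells$cell_id),
      radius = radius,
      neighbors = nbrs,
      adjacency = adjacency
    ),
    class = "nbr_index"
  )
}

#' @export
print.nbr_index <- function(x, ...) {
  cat(sprintf(
    "<nbr_index> %d cells, radius %g um, mean neighbours %.2f\n",
    length(x$cell_id), x$radius, mean(lengths(x$neighbors))
  ))
  invisible(x)
}

#' @export
tidy.nbr_index <- function(x, ...) {
  tibble::tibble(
    cell_id = x$cell_id,
    n_neighbors = lengths(x$neighbors),
    neighbors = lapply(x$neighbors, function(i) x$cell_id[i])
  )
}

# ---------------------------------------------------------------------------
# Hexagonal binning of transcript molecules

# Axial hex coordinates for flat-top hexagons of circumradius r anchored at
# (x0, y0); cube rounding assigns each point to its nearest hexagon centre.
hex_axial <- function(x, y, r, x0, y0) {
  u <- (x - x0) / r
  v <- (y - y0) / r
  q <- (2 / 3) * u
  rr <- (-1 / 3) * u + (sqrt(3) / 3) * v
  s <- -q - rr
  qi <- round(q)
  ri <- round(rr)
  si <- round(s)
  dq <- abs(qi - q)
  dr <- abs(ri - rr)
  ds <- abs(si - s)
  fix_q <- dq > dr & dq > ds
  fix_r <- !fix_q & dr > ds
  qi[fix_q] <- -ri[fix_q] - si[fix_q]
  ri[fix_r] <- -qi[fix_r] - si[fix_r]
  cbind(q = qi, r = ri)
}

hex_center <- function(q, r, rad, x0, y0) {
  cbind(
    x = x0 + 1.5 * rad * q,
    y = y0 + sqrt(3) * rad * (r + q / 2)
  )
}

#' Bin transcript molecules into a regular hexagonal lattice
#'
#' Covers the bounding box of the transcript coordinates with flat-top
#' regular hexagons, choosing the circumradius so that the realised number of
#' bins approximates `n_bins`. Per-bin transcript totals feed the background
#' Gaussian mixture; per-bin per-gene counts feed the background profile.
#'
#' The lattice is anchored at the bounding-box minimum corner. The hexagon
#' area is \eqn{A = (3\sqrt{3}/2) r^2} and the circumradius is
#' \eqn{r = \sqrt{2\,\mathrm{area}/(3\sqrt{3}\,n)}} so that
#' \eqn{A \cdot n \approx \mathrm{area}}.
#'
#' @param transcripts Data frame with columns `x`, `y` (micrometres) and
#'   `gene` (one row per decoded molecule).
#' @param n_bins Target number of hexbins. Default 200.
#' @return An object of class `hexbin_grid`: list with `bins` (tibble of
#'   `bin`, `q`, `r`, `x`, `y`, `total`), `gene_counts` (sparse bins x genes
#'   matrix), `circumradius`, `area`, `origin`.
#' @export
hexbin_transcripts <- function(transcripts, n_bins = 200) {
  check_transcript_table(transcripts)
  if (!is.numeric(n_bins) || length(n_bins) != 1 || n_bins < 2) {
    stop_invalid("`n_bins` must be a single number >= 2.")
  }
  x <- transcripts$x
  y <- transcripts$y
  x0 <- min(x)
  y0 <- min(y)
  w <- max(x) - x0
  h <- max(y) - y0
  bbox_area <- w * h
  if (bbox_area <= 0) {
    stop_invalid(
      "transcript coordinates span a degenerate (zero-area) bounding box; ",
      "a hexbin grid cannot be constructed - disable the global background."
    )
  }
  rad <- sqrt(2 * bbox_area / (3 * sqrt(3) * n_bins))
  area <- 1.5 * sqrt(3) * rad^2

  ax <- hex_axial(x, y, rad, x0, y0)

  # Grid = every hexagon whose centre falls in the bounding box, plus any
  # boundary hexagon that actually received a transcript.
  qmax <- ceiling(w / (1.5 * rad)) + 1L
  rmax <- ceiling(h / (sqrt(3) * rad)) + 1L
  lattice <- expand.grid(q = 0:qmax, r = -qmax:rmax)
  ctr <- hex_center(lattice$q, lattice$r, rad, x0, y0)
  eps <- 1e-9 * max(w, h)
  keep <- ctr[, 1] >= x0 - eps & ctr[, 1] <= x0 + w + eps &
    ctr[, 2] >= y0 - eps & ctr[, 2] <= y0 + h + eps
  grid_keys <- paste(lattice$q[keep], lattice$r[keep])

  tx_keys <- paste(ax[, "q"], ax[, "r"])
  all_keys <- union(grid_keys, unique(tx_keys))
  bin_of_tx <- match(tx_keys, all_keys)

  gene <- factor(transcripts$gene)
  gene_counts <- Matrix::sparseMatrix(
    i = bin_of_tx,
    j = as.integer(gene),
    x = 1,
    dims = c(length(all_keys), nlevels(gene)),
    dimnames = list(all_keys, levels(gene))
  )
  totals <- as.numeric(Matrix::rowSums(gene_counts))

  qr <- do.call(rbind, strsplit(all_keys, " ", fixed = TRUE))
  qv <- as.integer(qr[, 1])
  rv <- as.integer(qr[, 2])
  ctr_all <- hex_center(qv, rv, rad, x0, y0)

  bins <- tibble::tibble(
    bin = all_keys,
    q = qv,
    r = rv,
    x = ctr_all[, 1],
    y = ctr_all[, 2],
    total = totals
  )

  structure(
    list(
      bins = bins,
      gene_counts = gene_counts,
      circumradius = rad,
      area = area,
      origin = c(x = x0, y = y0)
    ),
    class = "hexbin_grid"
  )
}

#' @export
print.hexbin_grid <- function(x, ...) {
  cat(sprintf(
    "<hexbin_grid> %d bins, circumradius %.2f um, bin area %.1f um^2, %d transcripts\n",
    nrow(x$bins), x$circumradius, x$area, sum(x$bins$total)
  ))
  invisible(x)
}

#' @export
tidy.hexbin_grid <- function(x, ...) x$bins

#' @export
autoplot.hexbin_grid <- function(object, ...) {
  ggplot2::ggplot(object$bins, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$total), size = 3) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = "Hexbin transcript totals",
      x = "x (um)", y = "y (um)", colour = "transcripts"
    )
}

# ---------------------------------------------------------------------------
# Two-component Gaussian mixture over bin totals

#' Fit a two-component Gaussian mixture to hexbin transcript totals
#'
#' Separates low-count (background / extracellular) bins from high-count
#' (tissue) bins by an EM-fitted univariate two-component Gaussian mixture.
#' Each bin is hard-assigned to the component with the higher posterior
#' responsibility; the lower-mean component is designated background.
#'
#' Initialisation splits the bins at the median total and takes component
#' moments from each half, so the fit is deterministic; `seed` is accepted
#' for interface uniformity. Variances are floored at `1e-6 * var(totals)`.
#'
#' @param totals Numeric vector of per-bin transcript totals (length >= 4,
#'   positive variance).
#' @param seed Integer seed recorded with the fit (the default initialisation
#'   is deterministic).
#' @param init Optional list with elements `w`, `mu`, `sigma2` (each length
#'   2) overriding the default initialisation; used mainly for
#'   label-invariance checks.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return Object of class `background_gmm` with elements `w`, `mu`,
#'   `sigma2`, `responsibilities` (n x 2), `assignment` (1/2),
#'   `background_component`, `background_bins` (indices), `loglik`,
#'   `n_iter`, `converged`.
#' @export
fit_background_gmm <- function(totals, seed = 0L, init = NULL,
                               max_iter = 500L, tol = 1e-8) {
  totals <- as.numeric(totals)
  if (length(totals) < 4) {
    stop_invalid("need at least 4 bin totals to fit the background mixture.")
  }
  v <- var(totals)
  if (!is.finite(v) || v <= 0) {
    stop_invalid(
      "bin totals have zero variance; background cannot be separated - ",
      "disable the global background."
    )
  }
  n <- length(totals)
  var_floor <- 1e-6 * v

  if (is.null(init)) {
    med <- median(totals)
    lo <- totals[totals <= med]
    hi <- totals[totals > med]
    if (length(hi) == 0) { # heavy ties at the median
      hi <- totals[totals >= med]
      lo <- totals[totals < med]
    }
    mu <- c(mean(lo), mean(hi))
    sigma2 <- pmax(c(var(lo), var(hi)), var_floor, na.rm = TRUE)
    sigma2[is.na(sigma2)] <- var_floor
    w <- c(length(lo), length(hi)) / n
  } else {
    mu <- as.numeric(init$mu)
    sigma2 <- pmax(as.numeric(init$sigma2), var_floor)
    w <- as.numeric(init$w)
    w <- w / sum(w)
  }

  floored <- FALSE
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  resp <- matrix(0, n, 2)
  for (iter in seq_len(max_iter)) {
    lg <- cbind(
      log(w[1]) + dnorm(totals, mu[1], sqrt(sigma2[1]), log = TRUE),
      log(w[2]) + dnorm(totals, mu[2], sqrt(sigma2[2]), log = TRUE)
    )
    m <- pmax(lg[, 1], lg[, 2])
    lse <- m + log(exp(lg[, 1] - m) + exp(lg[, 2] - m))
    ll <- sum(lse)
    resp <- exp(lg - lse)

    nk <- colSums(resp)
    nk <- pmax(nk, 1e-12)
    w <- nk / n
    mu <- colSums(resp * totals) / nk
    sigma2_new <- colSums(resp * (outer(totals, mu, `-`))^2) / nk
    if (any(sigma2_new < var_floor)) floored <- TRUE
    sigma2 <- pmax(sigma2_new, var_floor)

    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (floored) {
    warn("background GMM variance collapsed; variance floor applied.")
  }

  assignment <- max.col(resp, ties.method = "first")
  background_component <- which.min(mu)
  background_bins <- which(assignment == background_component)

  structure(
    list(
      w = w[background_component],
      mu = mu,
      sigma2 = sigma2,
      mixing = w,
      responsibilities = resp,
      assignment = assignment,
      background_component = background_component,
      background_bins = background_bins,
      loglik = ll_old,
      n_iter = iter,
      converged = converged,
      seed = seed
    ),
    class = "background_gmm"
  )
}

#' @export
print.background_gmm <- function(x, ...) {
  bg <- x$background_component
  cat(sprintf(
    "<background_gmm> background: mu = %.2f (component %d, w = %.2f), signal: mu = %.2f; %d/%d bins background\n",
    x$mu[bg], bg, x$w, x$mu[-bg], length(x$background_bins), nrow(x$responsibilities)
  ))
  invisible(x)
}

#' @export
tidy.background_gmm <- function(x, ...) {
  tibble::tibble(
    component = 1:2,
    mixing = x$mixing,
    mu = x$mu,
    sigma2 = x$sigma2,
    is_background = 1:2 == x$background_component
  )
}

#' @export
glance.background_gmm <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik,
    n_iter = x$n_iter,
    converged = x$converged,
    n_background_bins = length(x$background_bins),
    background_weight = x$w
  )
}

#' @export
autoplot.background_gmm <- function(object, ...) {
  grid <- seq(
    min(object$mu) - 3 * sqrt(max(object$sigma2)),
    max(object$mu) + 3 * sqrt(max(object$sigma2)),
    length.out = 400
  )
  dens <- tibble::tibble(
    total = rep(grid, 2),
    component = factor(rep(1:2, each = length(grid))),
    density = c(
      object$mixing[1] * dnorm(grid, object$mu[1], sqrt(object$sigma2[1])),
      object$mixing[2] * dnorm(grid, object$mu[2], sqrt(object$sigma2[2]))
    )
  )
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$total, y = .data$density,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "Background GMM component densities",
                  x = "bin transcript total", y = "weighted density")
}

# ---------------------------------------------------------------------------

#' Compute the per-gene global ambient background profile
#'
#' Averages each gene's counts over the hexbins classified as background and
#' scales the result from the hexbin area to the area of a radius-`radius`
#' neighbourhood disc: \eqn{x_{jb} = (\pi d^2 / A) \cdot
#' \mathrm{mean}_{k \in B}(\mathrm{count}_{kj})}.
#'
#' @param grid A `hexbin_grid`.
#' @param gmm A `background_gmm` fitted to `grid$bins$total`.
#' @param radius Neighbourhood radius d in micrometres (the same radius used
#'   for the local context). Default 50.
#' @return Tibble with columns `gene`, `x_b` (expected ambient count within a
#'   radius-d disc), with the background bin indices in attribute
#'   `background_bins` and the scale factor in `scale_factor`.
#' @export
background_profile <- function(grid, gmm, radius = 50) {
  stopifnot(inherits(grid, "hexbin_grid"), inherits(gmm, "background_gmm"))
  bins <- gmm$background_bins
  if (length(bins) == 0) {
    stop_invalid(
      "no hexbins were assigned to the background component; ",
      "disable the global background."
    )
  }
  if (max(bins) > nrow(grid$gene_counts)) {
    stop_invalid("background GMM does not match the hexbin grid dimensions.")
  }
  scale_factor <- pi * radius^2 / grid$area
  mean_bg <- Matrix::colMeans(grid$gene_counts[bins, , drop = FALSE])
  out <- tibble::tibble(
    gene = colnames(grid$gene_counts),
    x_b = scale_factor * as.numeric(mean_bg)
  )
  attr(out, "background_bins") <- bins
  attr(out, "scale_factor") <- scale_factor
  attr(out, "radius") <- radius
  out
}

#' Assemble the per-(cell, gene) contamination offset matrix
#'
#' The offset \eqn{x^+_{ij}} is the sum of the local context (gene j's counts
#' summed over the neighbours of cell i) and the global ambient background
#' \eqn{x_{jb}}. It enters the mixture model as the baseline contamination
#' context against which a cell's own counts are judged.
#'
#' @param counts Cells x genes count matrix (dense or sparse; rows must align
#'   with the cells used to build `nbrs`).
#' @param nbrs An `nbr_index` built over the same cells, in the same order.
#' @param background Optional background profile tibble from
#'   [background_profile()]; genes are matched by name against
#'   `colnames(counts)`. When `NULL` the global term is zero and a warning is
#'   issued.
#' @return Dense numeric matrix of offsets, same dimnames as `counts`.
#' @export
compute_offsets <- function(counts, nbrs, background = NULL) {
  stopifnot(inherits(nbrs, "nbr_index"))
  counts <- check_count_matrix(counts, allow_real = TRUE)
  n <- length(nbrs$cell_id)
  if (nrow(counts) != n) {
    stop_invalid(sprintf(
      "`counts` has %d rows but the neighbourhood index covers %d cells.",
      nrow(counts), n
    ))
  }
  if (!is.null(rownames(counts)) &&
      !identical(unname(rownames(counts)), unname(nbrs$cell_id))) {
    stop_invalid("row names of `counts` do not match the neighbourhood index cell ids.")
  }

  local <- as.matrix(nbrs$adjacency %*% counts)

  if (is.null(background)) {
    warn("no background profile supplied; global ambient offset set to 0.")
    xb <- numeric(ncol(counts))
  } else {
    idx <- match(colnames(counts), background$gene)
    xb <- ifelse(is.na(idx), 0, background$x_b[idx])
    if (all(is.na(idx))) {
      warn("no gene names shared between `counts` and the background profile; global offset is 0.")
    }
  }
  out <- sweep(local, 2, xb, `+`)
  dimnames(out) <- dimnames(counts)
  out
}
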