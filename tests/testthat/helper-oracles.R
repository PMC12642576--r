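# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: closed-form EM updates, exhaustive
# enumeration, brute-force loops and grid searches.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Textbook two-component Poisson mixture EM (no offsets, closed-form
# M-step). Shares only the starting parameters with the package fit.
textbook_poisson_em <- function(x, pi0, lambda_e0, lambda_c0,
                                max_iter = 200, tol = 1e-6) {
  p <- pi0
  le <- lambda_e0
  lc <- lambda_c0
  ll <- ll_old <- -Inf
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    a <- log(p) + dpois(x, max(le, 1e-6), log = TRUE)
    b <- log(1 - p) + dpois(x, max(lc, 1e-6), log = TRUE)
    m <- pmax(a, b)
    lse <- m + log(exp(a - m) + exp(b - m))
    ll <- sum(lse)
    alpha <- exp(a - lse)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) {
      conv <- TRUE
      break
    }
    ll_old <- ll
    p <- min(max(mean(alpha), 1e-4), 1 - 1e-4)
    le <- max(sum(alpha * x) / max(sum(alpha), 1e-12), 1e-6)
    lc <- max(sum((1 - alpha) * x) / max(sum(1 - alpha), 1e-12), 1e-6)
    if (le < lc) {
      tmp <- le; le <- lc; lc <- tmp
      p <- min(max(1 - p, 1e-4), 1 - 1e-4)
    }
  }
  list(pi = p, lambda_e = le, lambda_c = lc, loglik = ll, converged = conv)
}

# Best-of-restarts wrapper around the textbook EM, started from the same
# initial parameter rule as the package.
textbook_poisson_em_restarts <- function(x, pi0_values) {
  fits <- lapply(pi0_values, function(p0) {
    init <- istclean::init_cell_params(x, rep(0, length(x)), p0)
    textbook_poisson_em(x, init$pi, init$lambda_e, init$lambda_c)
  })
  fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
}

# Exhaustive two-partition maximum-likelihood clustering of a small vector:
# every non-trivial bipartition scored by its Gaussian classification
# likelihood (component moments from the partition members).
exhaustive_gmm_partition <- function(totals) {
  n <- length(totals)
  stopifnot(n <= 16)
  floor_v <- 1e-6 * var(totals)
  best <- NULL
  best_ll <- -Inf
  for (mask in 1:(2^n - 2)) {
    grp <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    for (g in list(grp)) {
      a <- totals[g]
      b <- totals[!g]
      if (length(a) < 1 || length(b) < 1) next
      va <- max(if (length(a) > 1) var(a) else floor_v, floor_v)
      vb <- max(if (length(b) > 1) var(b) else floor_v, floor_v)
      wa <- length(a) / n
      ll <- sum(dnorm(a, mean(a), sqrt(va), log = TRUE)) +
        sum(dnorm(b, mean(b), sqrt(vb), log = TRUE)) +
        length(a) * log(wa) + length(b) * log(1 - wa)
      if (ll > best_ll) {
        best_ll <- ll
        best <- g
      }
    }
  }
  # return the lower-mean side as the background set
  if (mean(totals[best]) <= mean(totals[!best])) which(best) else which(!best)
}

# Dense triple-loop offset computation.
brute_force_offsets <- function(counts, cells, radius, x_b = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  g <- ncol(counts)
  if (is.null(x_b)) x_b <- numeric(g)
  out <- matrix(0, n, g, dimnames = dimnames(counts))
  for (i in seq_len(n)) {
    for (t in seq_len(n)) {
      if (t == i) next
      d <- sqrt((cells$x[t] - cells$x[i])^2 + (cells$y[t] - cells$y[i])^2)
      if (d <= radius) out[i, ] <- out[i, ] + counts[t, ]
    }
    out[i, ] <- out[i, ] + x_b
  }
  out
}

# Expected complete-data log-likelihood in one rate parameter (additive
# offsets), for grid-search checks of the M-step.
q_lambda <- function(lambda, x, xplus, w) {
  sum(w * (x * log(xplus + lambda) - (xplus + lambda)))
}

# Mixture log-likelihood via direct probabilities (no log-sum-exp).
naive_mixture_loglik <- function(x, xplus, p, le, lc) {
  sum(log(p * dpois(x, xplus + le) + (1 - p) * dpois(x, xplus + lc)))
}

# A small deterministic cell table for reuse.
toy_cells <- function(n, seed = 1, extent = 500) {
  withr::with_seed(seed, tibble::tibble(
    cell_id = sprintf("c%03d", seq_len(n)),
    x = runif(n, 0, extent),
    y = runif(n, 0, extent)
  ))
}
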