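# Per-cell two-component Poisson mixture with contamination offsets.
#
# For cell i with gene counts x_j and offsets xplus_j, the model is
#   x_j ~ Poisson(mu_e(xplus_j, lambda_e))   if Z_j = 1  (endogenous)
#   x_j ~ Poisson(mu_c(xplus_j, lambda_c))   if Z_j = 0  (contaminated)
#   Z_j ~ Bernoulli(pi)
# with additive component means mu = xplus + lambda by default, or
# multiplicative mu = xplus * lambda when offset_mode = "multiplicative".

LAMBDA_FLOOR <- 1e-6
PI_CLAMP <- 1e-4

component_mean <- function(xplus, lambda, offset_mode) {
  if (offset_mode == "additive") {
    pmax(xplus + lambda, LAMBDA_FLOOR)
  } else {
    pmax(xplus * lambda, LAMBDA_FLOOR)
  }
}

check_mixture_args <- function(x, xplus, pi, lambda_e, lambda_c) {
  if (length(x) != length(xplus)) {
    stop_invalid("`x` and `xplus` must have equal length.")
  }
  if (any(xplus < 0) || any(!is.finite(xplus))) {
    abort("offsets must be finite and non-negative.")
  }
  if (!is.finite(pi) || pi <= 0 || pi >= 1) {
    abort("`pi` must lie strictly inside (0, 1).")
  }
  if (!is.finite(lambda_e) || !is.finite(lambda_c) ||
      lambda_e < LAMBDA_FLOOR || lambda_c < LAMBDA_FLOOR) {
    abort("lambda parameters must be finite and >= the lambda floor (1e-6).")
  }
  invisible(NULL)
}

#' Per-cell mixture log-likelihood
#'
#' Log-likelihood of one cell's gene counts under the two-component Poisson
#' mixture with offset component means, computed with log-sum-exp
#' stabilisation.
#'
#' @param x Non-negative integer gene-count vector of one cell.
#' @param xplus Offset vector (same length): local neighbourhood sum plus
#'   global ambient term.
#' @param pi Mixing proportion of the endogenous component, in (0, 1).
#' @param lambda_e,lambda_c Endogenous and contamination rate parameters
#'   (both >= 1e-6).
#' @param offset_mode `"additive"` (component mean `xplus + lambda`, the
#'   default) or `"multiplicative"` (`xplus * lambda`).
#' @return A single finite number: the summed mixture log-likelihood.
#' @export
cell_loglik <- function(x, xplus, pi, lambda_e, lambda_c,
                        offset_mode = c("additive", "multiplicative")) {
  offset_mode <- match.arg(offset_mode)
  check_mixture_args(x, xplus, pi, lambda_e, lambda_c)
  le <- log(pi) + dpois(x, component_mean(xplus, lambda_e, offset_mode), log = TRUE)
  lc <- log1p(-pi) + dpois(x, component_mean(xplus, lambda_c, offset_mode), log = TRUE)
  m <- pmax(le, lc)
  sum(m + log(exp(le - m) + exp(lc - m)))
}

#' E-step: posterior probability of endogenous expression
#'
#' Computes, for each gene, the posterior probability
#' \eqn{\alpha_j = P(Z_j = 1 \mid x_j)} that the observed count is
#' endogenous rather than contamination, together with the current
#' log-likelihood.
#'
#' @inheritParams cell_loglik
#' @return List with `alpha` (vector in \[0, 1\]) and `loglik`.
#' @export
e_step <- function(x, xplus, pi, lambda_e, lambda_c,
                   offset_mode = c("additive", "multiplicative")) {
  offset_mode <- match.arg(offset_mode)
  check_mixture_args(x, xplus, pi, lambda_e, lambda_c)
  le <- log(pi) + dpois(x, component_mean(xplus, lambda_e, offset_mode), log = TRUE)
  lc <- log1p(-pi) + dpois(x, component_mean(xplus, lambda_c, offset_mode), log = TRUE)
  m <- pmax(le, lc)
  lse <- m + log(exp(le - m) + exp(lc - m))
  list(alpha = exp(le - lse), loglik = sum(lse))
}

# Weighted rate update: solves sum_j w_j * (x_j / (xplus_j + lambda) - 1) = 0
# for lambda in [LAMBDA_FLOOR, max(x) + 1]; the score is strictly decreasing.
solve_lambda_additive <- function(x, xplus, w) {
  sw <- sum(w)
  if (sw <= 1e-12) {
    return(list(lambda = LAMBDA_FLOOR, degenerate = TRUE))
  }
  score <- function(l) sum(w * (x / (xplus + l) - 1))
  if (score(LAMBDA_FLOOR) <= 0) {
    return(list(lambda = LAMBDA_FLOOR, degenerate = FALSE))
  }
  upper <- max(x) + 1
  if (score(upper) >= 0) { # cannot happen for x <= max(x); defensive
    return(list(lambda = upper, degenerate = FALSE))
  }
  root <- uniroot(score, c(LAMBDA_FLOOR, upper), tol = 1e-10)$root
  list(lambda = root, degenerate = FALSE)
}

solve_lambda_multiplicative <- function(x, xplus, w) {
  sw <- sum(w * xplus)
  if (sw <= 1e-12 || sum(w) <= 1e-12) {
    return(list(lambda = LAMBDA_FLOOR, degenerate = TRUE))
  }
  list(lambda = max(sum(w * x) / sw, LAMBDA_FLOOR), degenerate = FALSE)
}

#' M-step: maximise the expected complete-data log-likelihood
#'
#' Given posterior responsibilities `alpha`, updates `pi` to the clamped mean
#' responsibility and each rate parameter to the root of its weighted score
#' equation. Components are re-ordered so that `lambda_e >= lambda_c`; when a
#' swap happens the responsibilities (and hence `pi`) are flipped with them.
#'
#' @inheritParams cell_loglik
#' @param alpha Posterior responsibilities in \[0, 1\] (from [e_step()]).
#' @return List with `pi`, `lambda_e`, `lambda_c`, `flipped` (whether the
#'   component labels were swapped to enforce the ordering).
#' @export
m_step <- function(x, xplus, alpha,
                   offset_mode = c("additive", "multiplicative")) {
  offset_mode <- match.arg(offset_mode)
  if (length(alpha) != length(x) || any(alpha < 0 | alpha > 1)) {
    abort("`alpha` must be a vector in [0, 1] matching `x`.")
  }
  solver <- if (offset_mode == "additive") {
    solve_lambda_additive
  } else {
    solve_lambda_multiplicative
  }
  se <- solver(x, xplus, alpha)
  sc <- solver(x, xplus, 1 - alpha)
  if (se$degenerate || sc$degenerate) {
    warn("all responsibility mass on one component; rate set to the floor.")
  }
  pi <- min(max(mean(alpha), PI_CLAMP), 1 - PI_CLAMP)
  lambda_e <- se$lambda
  lambda_c <- sc$lambda
  flipped <- lambda_e < lambda_c
  if (flipped) {
    tmp <- lambda_e
    lambda_e <- lambda_c
    lambda_c <- tmp
    pi <- min(max(1 - pi, PI_CLAMP), 1 - PI_CLAMP)
  }
  list(pi = pi, lambda_e = lambda_e, lambda_c = lambda_c, flipped = flipped)
}

#' Initial rate parameters from an initial mixing proportion
#'
#' Ranks genes by the residual `x - xplus`; the top `ceiling(pi0 * G)` genes
#' seed the endogenous rate (mean residual of that set, at least 1) and the
#' remainder seed the contamination rate (mean residual, at least the floor).
#'
#' @inheritParams cell_loglik
#' @param pi0 Initial mixing proportion in (0, 1).
#' @return List with `pi`, `lambda_e`, `lambda_c`.
#' @export
init_cell_params <- function(x, xplus, pi0) {
  g <- length(x)
  resid <- x - xplus
  ord <- order(resid, decreasing = TRUE)
  k <- min(max(ceiling(pi0 * g), 1L), g - 1L)
  top <- ord[seq_len(k)]
  rest <- ord[-seq_len(k)]
  list(
    pi = min(max(pi0, PI_CLAMP), 1 - PI_CLAMP),
    lambda_e = max(mean(resid[top]), 1),
    lambda_c = max(mean(resid[rest]), LAMBDA_FLOOR)
  )
}

derive_cell_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 65536 * 32749 + as.double(index) * 7919 + 1) %% 2147483647)
}

#' Fit the per-cell Poisson mixture by EM with random restarts
#'
#' Runs EM from `n_restarts` initial mixing proportions drawn uniformly from
#' (0, 0.5) and keeps the restart with the highest final log-likelihood.
#' Within each restart the log-likelihood is non-decreasing. The fit is
#' deterministic given `seed` (all randomness is the restart draws).
#'
#' @inheritParams cell_loglik
#' @param n_restarts Number of EM restarts. Default 10.
#' @param seed Integer seed for the restart draws. Ignored when `pi0` is
#'   supplied.
#' @param pi0 Optional numeric vector of initial mixing proportions,
#'   overriding the random draws.
#' @param max_iter Iteration cap per restart (default 200).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param trace Keep the per-iteration log-likelihood trace of every restart.
#' @return Object of class `cell_fit`: list with `pi`, `lambda_e`,
#'   `lambda_c`, `loglik`, `n_iter`, `converged`, `restart_index`, `alpha`
#'   (posterior vector of the best restart), `restarts` (per-restart summary
#'   tibble) and, if `trace`, `traces` (list of log-likelihood vectors).
#' @export
fit_cell_mixture <- function(x, xplus, n_restarts = 10, seed = 0L, pi0 = NULL,
                             offset_mode = c("additive", "multiplicative"),
                             max_iter = 200L, tol = 1e-6, trace = FALSE) {
  offset_mode <- match.arg(offset_mode)
  if (length(x) != length(xplus)) {
    stop_invalid("`x` and `xplus` must have equal length.")
  }
  if (any(x < 0) || any(x != round(x))) {
    stop_invalid("`x` must contain non-negative integers.")
  }
  if (any(xplus < 0) || any(!is.finite(xplus))) {
    stop_invalid("`xplus` must be finite and non-negative.")
  }
  if (is.null(pi0)) {
    if (n_restarts < 1) stop_invalid("`n_restarts` must be >= 1.")
    pi0 <- withr::with_seed(seed, runif(n_restarts, 0, 0.5))
  }
  inits <- lapply(pi0, function(p) init_cell_params(x, xplus, p))

  fit <- fit_cell_em_cpp(
    as.numeric(x), as.numeric(xplus),
    pi0 = vapply(inits, `[[`, numeric(1), "pi"),
    lambda_e0 = vapply(inits, `[[`, numeric(1), "lambda_e"),
    lambda_c0 = vapply(inits, `[[`, numeric(1), "lambda_c"),
    multiplicative = offset_mode == "multiplicative",
    max_iter = as.integer(max_iter), tol = tol,
    lambda_floor = LAMBDA_FLOOR, pi_clamp = PI_CLAMP,
    keep_trace = isTRUE(trace)
  )

  if (!fit$converged) {
    warn("per-cell EM did not converge in any restart; best fit returned.")
  }
  restarts <- tibble::tibble(
    restart = seq_along(pi0),
    pi0 = as.numeric(pi0),
    pi = fit$all_pi,
    lambda_e = fit$all_lambda_e,
    lambda_c = fit$all_lambda_c,
    loglik = fit$all_loglik,
    n_iter = fit$all_n_iter,
    converged = fit$all_converged
  )
  out <- list(
    pi = fit$pi,
    lambda_e = fit$lambda_e,
    lambda_c = fit$lambda_c,
    loglik = fit$loglik,
    n_iter = fit$n_iter,
    converged = fit$converged,
    restart_index = fit$restart_index,
    alpha = fit$alpha,
    restarts = restarts,
    offset_mode = offset_mode
  )
  if (isTRUE(trace)) out$traces <- fit$traces
  structure(out, class = "cell_fit")
}

#' @export
print.cell_fit <- function(x, ...) {
  cat(sprintf(
    "<cell_fit> pi = %.3f, lambda_e = %.3f, lambda_c = %.4f, loglik = %.3f (%s, restart %d, %d iters)\n",
    x$pi, x$lambda_e, x$lambda_c, x$loglik,
    if (x$converged) "converged" else "NOT converged",
    x$restart_index, x$n_iter
  ))
  invisible(x)
}

#' @export
tidy.cell_fit <- function(x, ...) x$restarts

#' @export
glance.cell_fit <- function(x, ...) {
  tibble::tibble(
    pi = x$pi, lambda_e = x$lambda_e, lambda_c = x$lambda_c,
    loglik = x$loglik, n_iter = x$n_iter, converged = x$converged,
    restart_index = x$restart_index
  )
}

#' Zero out genes classified as contamination
#'
#' A gene's count is set to 0 when its posterior probability of endogenous
#' expression is at or below the cutoff (the boundary is filtered); otherwise
#' the original integer count is kept whole.
#'
#' @param x Integer gene-count vector.
#' @param alpha Posterior probabilities from the mixture fit.
#' @param cutoff Filtering threshold in \[0, 1\]. Default 0.75.
#' @return Adjusted integer count vector, elementwise either 0 or `x`.
#' @export
filter_counts <- function(x, alpha, cutoff = 0.75) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0 || cutoff > 1) {
    stop_invalid("`cutoff` must be a single number in [0, 1].")
  }
  if (length(alpha) != length(x)) {
    stop_invalid("`alpha` must match `x` in length.")
  }
  ifelse(alpha <= cutoff, 0, x)
}
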