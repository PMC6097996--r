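#' Ability estimates from a scored response pattern
#'
#' Three estimators of the latent ability under the constrained 2-AFC
#' response model:
#'
#' * `estimate_bayes_modal()` — mode of the posterior under a Gaussian
#'   prior (default mean 0, SD 1); the interim estimator of the adaptive
#'   session. With an empty pattern it returns the prior mode. Its
#'   standard error includes the prior's information contribution,
#'   `1 / sqrt(I(theta) + 1 / prior_sd^2)`.
#' * `estimate_weighted_likelihood()` — Warm's bias-corrected maximum
#'   likelihood estimate, the final scoring rule; finite even for
#'   all-correct or all-incorrect patterns. SE is `1 / sqrt(I(theta))`.
#' * `estimate_eap()` — posterior mean by fixed-node quadrature; SE is
#'   the posterior standard deviation.
#'
#' All estimators search the ability interval `[-6, 6]`, wide enough to
#' cover a standard-normal population and the standard bank's difficulty
#' range with margin.
#'
#' @param responses Binary vector (1 = correct) aligned with
#'   `difficulties`.
#' @param difficulties Difficulties of the administered items.
#' @param params A [response_model_params()] object.
#' @param prior_mean,prior_sd Gaussian prior for the Bayes modal and EAP
#'   estimators.
#' @param n_quadrature Number of quadrature nodes for EAP (`>= 15`).
#' @param bounds Search interval for the ability.
#' @return An object of class `"ability_estimate"`: a list with elements
#'   `theta`, `se`, `method`, `converged`, `n_items`.
#' @examples
#' est <- estimate_weighted_likelihood(c(1, 1, 0), c(-1, 0, 1))
#' est$theta
#' @name ability-estimates
NULL

new_estimate <- function(theta, se, method, converged, n_items) {
  structure(list(theta = theta, se = se, method = method,
                 converged = converged, n_items = n_items),
            class = "ability_estimate")
}

#' @export
print.ability_estimate <- function(x, ...) {
  cat(sprintf("Ability estimate (%s): theta = %.4f, SE = %.4f, %d item%s%s\n",
              x$method, x$theta, x$se, x$n_items,
              if (x$n_items == 1) "" else "s",
              if (x$converged) "" else " [non-converged]"))
  invisible(x)
}

#' @rdname ability-estimates
#' @export
estimate_bayes_modal <- function(responses, difficulties,
                                 params = response_model_params(),
                                 prior_mean = 0, prior_sd = 1,
                                 bounds = c(-6, 6)) {
  responses <- as.integer(responses)
  if (length(responses) != length(difficulties))
    stop("`responses` and `difficulties` must have equal length",
         call. = FALSE)
  if (length(responses) == 0L) {
    return(new_estimate(prior_mean, prior_sd, "bayes_modal", TRUE, 0L))
  }
  logpost <- function(th)
    loglik_pattern(th, difficulties, responses, params) +
      stats::dnorm(th, prior_mean, prior_sd, log = TRUE)
  ## coarse scan guards against local optima of the non-concave likelihood
  grid <- seq(bounds[1], bounds[2], length.out = 121L)
  gv <- vapply(grid, logpost, numeric(1))
  if (any(!is.finite(gv)))
    stop("non-finite posterior encountered", call. = FALSE)
  k <- which.max(gv)
  lo <- grid[max(1L, k - 1L)]; hi <- grid[min(length(grid), k + 1L)]
  opt <- stats::optimize(logpost, c(lo, hi), maximum = TRUE, tol = 1e-6)
  th <- opt$maximum
  info <- test_information(th, difficulties, params) + 1 / prior_sd^2
  new_estimate(th, 1 / sqrt(info), "bayes_modal", TRUE,
               length(responses))
}

## Warm's corrected score: S(theta) + J(theta) / (2 I(theta))
wl_corrected_score <- function(theta, difficulties, responses, params) {
  a <- params$discrimination
  cc <- params$guessing
  p <- prob_correct_4pl(theta, a, difficulties, cc, params$inattention)
  dp <- prob_deriv1(p, a, cc)
  d2p <- prob_deriv2(p, a, cc)
  s <- sum((responses / p - (1 - responses) / (1 - p)) * dp)
  info <- sum(dp^2 / (p * (1 - p)))
  j <- sum(dp * d2p / (p * (1 - p)))
  s + j / (2 * info)
}

#' @rdname ability-estimates
#' @export
estimate_weighted_likelihood <- function(responses, difficulties,
                                         params = response_model_params(),
                                         bounds = c(-6, 6)) {
  responses <- as.integer(responses)
  if (length(responses) == 0L)
    stop("weighted likelihood estimation needs at least one response",
         call. = FALSE)
  if (length(responses) != length(difficulties))
    stop("`responses` and `difficulties` must have equal length",
         call. = FALSE)
  f <- function(th) wl_corrected_score(th, difficulties, responses, params)
  lo <- f(bounds[1]); hi <- f(bounds[2])
  converged <- TRUE
  if (is.finite(lo) && is.finite(hi) && lo > 0 && hi < 0) {
    th <- stats::uniroot(f, bounds, tol = 1e-6)$root
  } else if (lo <= 0 && hi <= 0) {
    ## corrected score negative throughout: maximum at the lower bound
    th <- bounds[1]; converged <- FALSE
  } else if (lo >= 0 && hi >= 0) {
    th <- bounds[2]; converged <- FALSE
  } else {
    ## non-monotone bracketing: grid scan for a sign change
    grid <- seq(bounds[1], bounds[2], length.out = 481L)
    vals <- vapply(grid, f, numeric(1))
    ix <- which(vals[-1] * vals[-length(vals)] <= 0)
    if (length(ix)) {
      th <- stats::uniroot(f, grid[c(ix[1L], ix[1L] + 1L)],
                           tol = 1e-6)$root
    } else {
      th <- grid[which.max(-abs(vals))]; converged <- FALSE
    }
  }
  info <- test_information(th, difficulties, params)
  new_estimate(th, 1 / sqrt(info), "weighted_likelihood", converged,
               length(responses))
}

#' @rdname ability-estimates
#' @export
estimate_eap <- function(responses, difficulties,
                         params = response_model_params(),
                         prior_mean = 0, prior_sd = 1,
                         n_quadrature = 61, bounds = c(-6, 6)) {
  responses <- as.integer(responses)
  if (n_quadrature < 15)
    stop("`n_quadrature` must be >= 15", call. = FALSE)
  if (length(responses) != length(difficulties))
    stop("`responses` and `difficulties` must have equal length",
         call. = FALSE)
  if (length(responses) == 0L)
    return(new_estimate(prior_mean, prior_sd, "eap", TRUE, 0L))
  gh <- gauss_hermite_normal(n_quadrature, prior_mean, prior_sd)
  ll <- loglik_pattern(gh$nodes, difficulties, responses, params)
  w <- gh$weights * exp(ll - max(ll))
  w <- w / sum(w)
  m <- sum(w * gh$nodes)
  v <- sum(w * (gh$nodes - m)^2)
  new_estimate(m, sqrt(v), "eap", TRUE, length(responses))
}

## Gauss-Hermite nodes/weights adapted to a N(mean, sd) weight function,
## via Golub-Welsch on the Hermite Jacobi matrix.
gauss_hermite_normal <- function(n, mean = 0, sd = 1) {
  n <- as.integer(n)
  if (n == 1L) return(list(nodes = mean, weights = 1))
  off <- sqrt(seq_len(n - 1L) / 2)
  jac <- matrix(0, n, n)
  jac[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  jac[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  e <- eigen(jac, symmetric = TRUE)
  x <- e$values
  w <- e$vectors[1L, ]^2   # weights sum to 1 for the normal density
  ord <- order(x)
  list(nodes = mean + sd * sqrt(2) * x[ord], weights = w[ord])
}
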