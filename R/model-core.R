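#' Response model parameters for the constrained 2-AFC item response model
#'
#' Bundles the item parameters that are shared across all items of a beat
#' alignment test: a common discrimination, a guessing floor fixed by the
#' response format (1/2 for two-alternative forced choice), and an
#' inattention ceiling (1 for short tests).
#'
#' @param discrimination Positive slope shared by all items, on the logit
#'   scale of the latent ability.
#' @param guessing Lower asymptote of the response function; the chance
#'   success rate, 0.5 for 2-AFC.
#' @param inattention Upper asymptote of the response function.
#' @return An object of class `"response_model_params"`.
#' @examples
#' response_model_params()                 # published defaults (a = 1.166)
#' response_model_params(discrimination = 1.616)
#' @export
response_model_params <- function(discrimination = 1.166,
                                  guessing = 0.5,
                                  inattention = 1) {
  stopifnot(is.numeric(discrimination), length(discrimination) == 1L,
            is.finite(discrimination),
            is.numeric(guessing), length(guessing) == 1L,
            is.numeric(inattention), length(inattention) == 1L)
  if (discrimination <= 0)
    stop("`discrimination` must be > 0", call. = FALSE)
  if (!(guessing >= 0 && guessing < inattention && inattention <= 1))
    stop("require 0 <= guessing < inattention <= 1", call. = FALSE)
  structure(list(discrimination = discrimination,
                 guessing = guessing,
                 inattention = inattention),
            class = "response_model_params")
}

#' @export
print.response_model_params <- function(x, ...) {
  cat("Constrained item response model parameters\n")
  cat(sprintf("  discrimination (a): %.4g\n", x$discrimination))
  cat(sprintf("  guessing floor (c): %.4g\n", x$guessing))
  cat(sprintf("  inattention ceiling (d): %.4g\n", x$inattention))
  invisible(x)
}

## logistic(x) without overflow for large |x|
stable_logistic <- function(x) {
  out <- numeric(length(x))
  dim(out) <- dim(x)
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  e <- exp(x[!pos])
  out[!pos] <- e / (1 + e)
  out[is.na(x)] <- NA_real_
  out
}

#' Four-parameter logistic response probability
#'
#' Probability of a correct response under the four-parameter logistic (4PL)
#' item response model: `c + (d - c) * logistic(a * (theta - b))`. The
#' constrained 2-AFC model used throughout the package is the special case
#' `c = 0.5`, `d = 1` with a shared `a` (see [prob_correct_2afc()]).
#'
#' @param theta Latent ability (vectorised).
#' @param a Discrimination, `> 0`.
#' @param b Difficulty, on the same scale as `theta`.
#' @param c Guessing parameter, lower asymptote.
#' @param d Inattention parameter, upper asymptote.
#' @return Probabilities in `[c, d]`; strictly increasing in `theta`.
#'   Evaluation is overflow-safe for arbitrarily large `|a * (theta - b)|`.
#' @examples
#' prob_correct_4pl(0, a = 1.166, b = 0, c = 0.5, d = 1)  # 0.75
#' @export
prob_correct_4pl <- function(theta, a, b, c = 0.5, d = 1) {
  if (any(a <= 0)) stop("`a` must be > 0", call. = FALSE)
  if (any(c < 0 | c >= d | d > 1))
    stop("require 0 <= c < d <= 1", call. = FALSE)
  c + (d - c) * stable_logistic(a * (theta - b))
}

#' Constrained 2-AFC response probability
#'
#' The response model of the adaptive beat alignment test:
#' `P(correct) = 0.5 + 0.5 * logistic(a * (theta - difficulty))`.
#' Identical to [prob_correct_4pl()] with guessing 0.5 and inattention 1.
#'
#' @param theta Latent ability (vectorised).
#' @param difficulty Item difficulty (vectorised, recycled against `theta`).
#' @param a Shared discrimination, `> 0`.
#' @return Probabilities in `(0.5, 1)` for finite arguments.
#' @examples
#' prob_correct_2afc(0, 0)              # 0.75 at matched difficulty
#' prob_correct_2afc(1, 0, a = 1.166)   # ~0.8816
#' @export
prob_correct_2afc <- function(theta, difficulty, a = 1.166) {
  if (any(a <= 0)) stop("`a` must be > 0", call. = FALSE)
  0.5 + 0.5 * stable_logistic(a * (theta - difficulty))
}

#' Fisher information of one item at an ability value
#'
#' Expected (Fisher) information of a constrained-4PL item,
#' `a^2 * ((1 - P) / P) * ((P - c) / (1 - c))^2` with
#' `P = prob_correct_4pl(theta, a, difficulty, c, 1)`. Summed over items this
#' gives the test information whose inverse square root is the standard
#' error of a maximum-likelihood ability estimate.
#'
#' @param theta Ability value(s).
#' @param difficulty Item difficulty value(s).
#' @param params A [response_model_params()] object.
#' @return Nonnegative information values; vanishes as `theta -> +-Inf`.
#' @examples
#' item_information(0, 0)  # a^2 / 12 at matched difficulty for c = 0.5
#' @export
item_information <- function(theta, difficulty,
                             params = response_model_params()) {
  a <- params$discrimination
  cc <- params$guessing
  p <- prob_correct_4pl(theta, a, difficulty, cc, params$inattention)
  a^2 * ((1 - p) / p) * ((p - cc) / (1 - cc))^2
}

#' Test information across a set of items
#'
#' @inheritParams item_information
#' @param difficulties Numeric vector of item difficulties.
#' @return Sum of [item_information()] over the items, at each `theta`.
#' @export
test_information <- function(theta, difficulties,
                             params = response_model_params()) {
  vapply(theta, function(th)
    sum(item_information(th, difficulties, params)), numeric(1))
}

#' Log-likelihood of a scored response pattern
#'
#' Sum over administered items of `log P` for correct responses and
#' `log(1 - P)` for incorrect ones, with `P` the constrained-4PL response
#' probability.
#'
#' @param theta Ability value (scalar or vector; evaluated at each value).
#' @param difficulties Numeric vector of the administered items'
#'   difficulties.
#' @param responses Binary vector (0/1 or logical), aligned with
#'   `difficulties`.
#' @param params A [response_model_params()] object.
#' @return Log-likelihood value(s), `<= 0`.
#' @export
loglik_pattern <- function(theta, difficulties, responses,
                           params = response_model_params()) {
  responses <- as.integer(responses)
  if (length(difficulties) != length(responses))
    stop("`difficulties` and `responses` must have equal length",
         call. = FALSE)
  if (length(responses) == 0L)
    stop("response pattern is empty", call. = FALSE)
  if (any(!responses %in% c(0L, 1L)))
    stop("`responses` must be binary", call. = FALSE)
  vapply(theta, function(th) {
    p <- prob_correct_4pl(th, params$discrimination, difficulties,
                          params$guessing, params$inattention)
    sum(ifelse(responses == 1L, log(p), log1p(-p)))
  }, numeric(1))
}

## First derivative of P wrt theta for the constrained 4PL (d = 1)
prob_deriv1 <- function(p, a, cc) a * (p - cc) * (1 - p) / (1 - cc)

## Second derivative of P wrt theta
prob_deriv2 <- function(p, a, cc) {
  prob_deriv1(p, a, cc) * a * (1 - 2 * p + cc) / (1 - cc)
}

## Score function (d loglik / d theta) of a response pattern
score_pattern <- function(theta, difficulties, responses, params) {
  a <- params$discrimination
  cc <- params$guessing
  p <- prob_correct_4pl(theta, a, difficulties, cc, params$inattention)
  dp <- prob_deriv1(p, a, cc)
  sum((responses / p - (1 - responses) / (1 - p)) * dp)
}
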