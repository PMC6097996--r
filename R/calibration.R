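#' Per-person marginal log-likelihood under the constrained model
#'
#' Integrates the response-pattern likelihood over a standard-normal
#' ability distribution by fixed-node quadrature:
#' `log integral prod_j P_j(theta)^x (1-P_j(theta))^(1-x) phi(theta) d theta`.
#' Exposed so that fitted marginal likelihoods can be checked against
#' dense-grid numerical integration.
#'
#' @param scores Persons-by-items matrix of 0/1/NA scores.
#' @param difficulties Item difficulties (one per column of `scores`).
#' @param a Shared discrimination.
#' @param quadrature Number of quadrature nodes.
#' @return Numeric vector: one log marginal likelihood per person.
#' @export
marginal_loglik <- function(scores, difficulties, a, quadrature = 61) {
  gh <- gauss_hermite_normal(quadrature)
  ll <- pattern_loglik_matrix(scores, gh$nodes, difficulties, a)
  apply(ll, 1L, function(v) {
    m <- max(v)
    m + log(sum(gh$weights * exp(v - m)))
  })
}

## N x Q matrix of log-likelihoods of each person's pattern at each node
pattern_loglik_matrix <- function(scores, nodes, difficulties, a,
                                  guessing = 0.5) {
  obs <- !is.na(scores)
  x1 <- ifelse(obs, scores, 0)         # observed correct indicator
  x0 <- ifelse(obs, 1 - scores, 0)     # observed incorrect indicator
  p <- pmin(pmax(prob_matrix(nodes, difficulties, a, guessing), 1e-300),
            1 - 1e-12)
  x1 %*% t(log(p)) + x0 %*% t(log1p(-p))
}

prob_matrix <- function(nodes, difficulties, a, guessing = 0.5) {
  eta <- a * outer(nodes, difficulties, `-`)
  guessing + (1 - guessing) * stable_logistic(eta)
}

## Marginal-ML fitting engine.
## Item difficulty is b = Z %*% gamma for a design matrix Z (J x p);
## Z = identity gives the constrained 3PL with free per-item difficulties.
fit_marginal <- function(scores, Z, quadrature = 61,
                         guessing = 0.5,
                         gamma_bounds = c(-8, 8),
                         start = NULL, reltol = 1e-8) {
  N <- nrow(scores); J <- ncol(scores); p <- ncol(Z)
  gh <- gauss_hermite_normal(quadrature)
  nodes <- gh$nodes; w <- gh$weights; Q <- length(nodes)
  obs <- !is.na(scores)
  x1 <- ifelse(obs, scores, 0)
  x0 <- ifelse(obs, 1 - scores, 0)
  cc <- guessing

  neg_ll <- function(par) {
    a <- exp(par[1L])
    b <- as.numeric(Z %*% par[-1L])
    pm <- pmin(prob_matrix(nodes, b, a, cc), 1 - 1e-12)
    ll <- x1 %*% t(log(pm)) + x0 %*% t(log1p(-pm))   # N x Q
    m <- apply(ll, 1L, max)
    -sum(m + log(exp(ll - m) %*% w))
  }
  neg_grad <- function(par) {
    a <- exp(par[1L])
    b <- as.numeric(Z %*% par[-1L])
    pm <- pmin(prob_matrix(nodes, b, a, cc), 1 - 1e-12)  # Q x J
    ll <- x1 %*% t(log(pm)) + x0 %*% t(log1p(-pm))
    m <- apply(ll, 1L, max)
    fw <- exp(ll - m) * rep(w, each = N)              # N x Q, scaled
    W <- fw / rowSums(fw)                             # posterior weights
    C1 <- t(W) %*% x1                                 # Q x J
    C2 <- t(W) %*% obs
    resid <- C1 - pm * C2                             # sum_p W (x - P), obs only
    dp_deta <- (pm - cc) * (1 - pm) / (1 - cc)        # dP/d eta
    common <- resid * dp_deta / (pm * (1 - pm))
    eta_term <- outer(nodes, b, `-`)                  # (theta - b)
    g_loga <- sum(common * eta_term) * a
    g_b <- -a * colSums(common)                       # d/d b_j
    -c(g_loga, as.numeric(t(Z) %*% g_b))
  }

  if (is.null(start)) {
    pbar <- colMeans(scores, na.rm = TRUE)
    pbar[!is.finite(pbar)] <- mean(scores, na.rm = TRUE)  # unanswered items
    pbar <- pmin(pmax(pbar, cc + 0.02), 0.98)
    b0 <- -stats::qlogis((pbar - cc) / (1 - cc))
    gamma0 <- if (p == J && all(Z == diag(J))) b0
              else stats::coef(stats::lm.fit(Z, b0))
    start <- c(0, pmin(pmax(gamma0, gamma_bounds[1]), gamma_bounds[2]))
  }
  degenerate <- which(colMeans(scores, na.rm = TRUE) %in% c(0, 1))

  fit <- stats::optim(start, neg_ll, neg_grad, method = "L-BFGS-B",
                      lower = c(log(0.05), rep(gamma_bounds[1], p)),
                      upper = c(log(10), rep(gamma_bounds[2], p)),
                      control = list(maxit = 500, factr = reltol / 1e-15))
  hess <- stats::optimHess(fit$par, neg_ll, neg_grad)
  vcov <- tryCatch(solve(hess), error = function(e) {
    warning("observed information is singular; standard errors ",
            "unavailable", call. = FALSE)
    matrix(NA_real_, length(fit$par), length(fit$par))
  })
  grad_norm <- sqrt(sum(neg_grad(fit$par)^2))
  list(log_a = fit$par[1L], gamma = fit$par[-1L], vcov = vcov,
       loglik = -fit$value, convergence = fit$convergence,
       grad_norm = grad_norm, degenerate_items = degenerate,
       message = fit$message, quadrature = quadrature)
}

#' Calibrate the constrained 3PL model on a response matrix
#'
#' Marginal maximum likelihood over a standard-normal ability
#' distribution (fixed-node quadrature): guessing fixed at 1/2,
#' inattention at 1, one discrimination shared by all items, one free
#' difficulty per item. Standard errors come from the observed
#' information at the optimum. Items answered all-correct or
#' all-incorrect cannot be located on the ability scale; they are
#' flagged and their difficulties pushed to the search bounds with a
#' warning.
#'
#' @param matrix A [response_matrix()] (or plain persons-by-items score
#'   matrix).
#' @param quadrature Number of quadrature nodes (default 61).
#' @return An object of class `"irt_calibration"` with elements
#'   `discrimination` (+ `discrimination_se`), `difficulties` (named,
#'   + `difficulty_se`), `log_likelihood`, `convergence`,
#'   `flagged_items`, `n_persons`, `n_items`.
#' @examples
#' \donttest{
#' sim <- make_response_matrix(200, standard_bank()[1:20, ], seed = 1)
#' fit <- fit_constrained_3pl(sim$matrix)
#' coef(fit)
#' }
#' @export
fit_constrained_3pl <- function(matrix, quadrature = 61) {
  scores <- score_matrix(matrix)
  J <- ncol(scores)
  if (J < 2L) stop("need at least 2 items", call. = FALSE)
  res <- fit_marginal(scores, diag(J), quadrature)
  if (length(res$degenerate_items))
    warning("items with degenerate (all-correct or all-incorrect) ",
            "columns reported at the search bounds: ",
            paste(colnames(scores)[res$degenerate_items],
                  collapse = ", "), call. = FALSE)
  se <- sqrt(diag(res$vcov))
  a <- exp(res$log_a)
  out <- list(mode = "3pl",
              discrimination = a,
              discrimination_se = a * se[1L],     # delta method from log a
              difficulties = stats::setNames(res$gamma, colnames(scores)),
              difficulty_se = stats::setNames(se[-1L], colnames(scores)),
              log_likelihood = res$loglik,
              convergence = res$convergence == 0L,
              grad_norm = res$grad_norm,
              flagged_items = colnames(scores)[res$degenerate_items],
              n_persons = nrow(scores), n_items = J,
              quadrature = quadrature)
  class(out) <- "irt_calibration"
  out
}

#' Calibrate the explanatory item response model directly
#'
#' One-stage marginal maximum likelihood of the constrained 2-AFC model
#' with item difficulty replaced by the linear predictor in the item
#' features (intercept, beep-track accuracy, behind-the-beat indicator).
#' Equivalent to a logistic mixed model with a Gaussian person
#' intercept; effects are reported both on the raw logit scale
#' (`B = -a * c`) and on the difficulty scale, with delta-method
#' standard errors.
#'
#' @param matrix A [response_matrix()] whose `items` annotation carries
#'   `accuracy` and `direction`, or a plain score matrix with
#'   `item_features` supplied.
#' @param item_features Optional data frame with columns `accuracy` and
#'   `direction` (one row per item) overriding the matrix annotation.
#' @param quadrature Number of quadrature nodes.
#' @return An `"irt_calibration"` object with `coefficients` (a
#'   [difficulty_coefficients()] object), `coefficient_se`,
#'   `raw_effects`, `raw_effect_se`, `log_likelihood`, convergence
#'   diagnostics.
#' @export
fit_explanatory_model <- function(matrix, item_features = NULL,
                                  quadrature = 61) {
  scores <- score_matrix(matrix)
  if (is.null(item_features)) {
    if (inherits(matrix, "response_matrix") && !is.null(matrix$items))
      item_features <- matrix$items
    else stop("item features (accuracy, direction) are required",
              call. = FALSE)
  }
  if (!all(c("accuracy", "direction") %in% names(item_features)))
    stop("item features must include `accuracy` and `direction`",
         call. = FALSE)
  if (nrow(item_features) != ncol(scores))
    stop("one feature row per item is required", call. = FALSE)
  Z <- cbind(intercept = 1,
             accuracy = item_features$accuracy,
             direction_behind =
               as.numeric(item_features$direction == "behind"))
  res <- fit_marginal(scores, Z, quadrature)
  if (res$convergence != 0L)
    warning(sprintf("optimizer did not report convergence (gradient norm %.2e): %s",
                    res$grad_norm, res$message), call. = FALSE)
  se <- sqrt(diag(res$vcov))
  a <- exp(res$log_a)
  gamma <- stats::setNames(res$gamma, colnames(Z))
  gamma_se <- stats::setNames(se[-1L], colnames(Z))
  ## raw logit-scale effects B = -a * c; delta method with cov(log a, c)
  raw <- -a * gamma
  raw_se <- vapply(seq_along(gamma), function(k) {
    grad <- numeric(length(res$gamma) + 1L)
    grad[1L] <- -a * gamma[k]        # d(-exp(la) c)/d la
    grad[k + 1L] <- -a
    v <- as.numeric(t(grad) %*% res$vcov %*% grad)
    sqrt(max(v, 0))
  }, numeric(1))
  out <- list(mode = "explanatory",
              discrimination = a,
              discrimination_se = a * se[1L],
              coefficients = difficulty_coefficients(
                intercept = gamma[["intercept"]],
                accuracy_effect = gamma[["accuracy"]],
                direction_effect = gamma[["direction_behind"]],
                discrimination = a,
                track_random_effects = NULL),
              coefficient_se = gamma_se,
              raw_effects = stats::setNames(raw, colnames(Z)),
              raw_effect_se = stats::setNames(raw_se, colnames(Z)),
              log_likelihood = res$loglik,
              convergence = res$convergence == 0L,
              grad_norm = res$grad_norm,
              n_persons = nrow(scores), n_items = ncol(scores),
              quadrature = quadrature)
  class(out) <- "irt_calibration"
  out
}

score_matrix <- function(matrix) {
  sc <- if (inherits(matrix, "response_matrix")) matrix$scores
        else as.matrix(matrix)
  if (is.null(colnames(sc)))
    colnames(sc) <- sprintf("item%03d", seq_len(ncol(sc)))
  sc
}

#' @export
print.irt_calibration <- function(x, ...) {
  cat(sprintf("Constrained 2-AFC calibration (%s mode)\n", x$mode))
  cat(sprintf("  %d persons, %d items, log-likelihood %.2f\n",
              x$n_persons, x$n_items, x$log_likelihood))
  cat(sprintf("  discrimination a = %.3f (SE %.3f)\n",
              x$discrimination, x$discrimination_se))
  if (x$mode == "explanatory") {
    cf <- coef(x$coefficients)
    cat("  difficulty-scale effects:\n")
    for (k in seq_along(cf))
      cat(sprintf("    %-17s %8.3f (SE %.3f)\n", names(cf)[k], cf[k],
                  x$coefficient_se[k]))
  } else {
    cat(sprintf("  difficulty range: [%.2f, %.2f]\n",
                min(x$difficulties), max(x$difficulties)))
    if (length(x$flagged_items))
      cat("  flagged degenerate items:",
          paste(x$flagged_items, collapse = ", "), "\n")
  }
  if (!x$convergence) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
coef.irt_calibration <- function(object, ...) {
  if (object$mode == "explanatory")
    c(discrimination = object$discrimination, coef(object$coefficients))
  else c(discrimination = object$discrimination, object$difficulties)
}

#' @export
logLik.irt_calibration <- function(object, ...) {
  val <- object$log_likelihood
  attr(val, "df") <- if (object$mode == "explanatory") 4L
                     else object$n_items + 1L
  attr(val, "nobs") <- object$n_persons
  class(val) <- "logLik"
  val
}

#' @export
summary.irt_calibration <- function(object, ...) {
  print(object)
  if (object$mode == "3pl")
    invisible(data.frame(item_id = names(object$difficulties),
                         difficulty = unname(object$difficulties),
                         se = unname(object$difficulty_se)))
  else invisible(object)
}

#' Regress item difficulties on item features
#'
#' Ordinary least squares of calibrated item difficulties on a feature
#' data frame (the second stage of two-stage explanatory calibration).
#' Reports unstandardised and fully standardised coefficients with
#' standard errors, adjusted R-squared and the overall F test.
#'
#' @param difficulties Numeric vector of item difficulties.
#' @param features Data frame of item features (numeric columns and/or
#'   factors), or a numeric vector.
#' @return An object of class `"difficulty_regression"` wrapping the
#'   underlying `lm` fit, with elements `coefficients`, `se`,
#'   `standardized`, `standardized_se`, `adj_r_squared`, `f_statistic`
#'   (value, df1, df2, p).
#' @export
regress_difficulty_on_features <- function(difficulties, features) {
  if (is.atomic(features)) features <- data.frame(feature = features)
  # constant feature columns are absorbed by the intercept
  constant <- vapply(features, function(col)
    length(unique(col)) == 1L, logical(1))
  features <- features[, !constant, drop = FALSE]
  df <- data.frame(difficulty = difficulties, features)
  fit <- stats::lm(difficulty ~ ., data = df)
  if (any(is.na(stats::coef(fit))))
    stop("feature matrix is rank deficient", call. = FALSE)
  sm <- summary(fit)
  cf <- sm$coefficients
  mm <- stats::model.matrix(fit)
  sd_y <- stats::sd(difficulties)
  std <- std_se <- rep(NA_real_, nrow(cf))
  for (k in seq_len(nrow(cf))[-1]) {
    sd_x <- stats::sd(mm[, k])
    std[k] <- cf[k, 1] * sd_x / sd_y
    std_se[k] <- cf[k, 2] * sd_x / sd_y
  }
  fstat <- if (is.null(sm$fstatistic)) {
    c(value = NA_real_, df1 = NA_real_, df2 = NA_real_, p = NA_real_)
  } else {
    c(value = unname(sm$fstatistic[1L]),
      df1 = unname(sm$fstatistic[2L]),
      df2 = unname(sm$fstatistic[3L]),
      p = unname(stats::pf(sm$fstatistic[1L], sm$fstatistic[2L],
                           sm$fstatistic[3L], lower.tail = FALSE)))
  }
  structure(list(coefficients = cf[, 1L], se = cf[, 2L],
                 standardized = stats::setNames(std, rownames(cf)),
                 standardized_se = stats::setNames(std_se, rownames(cf)),
                 adj_r_squared = sm$adj.r.squared,
                 f_statistic = fstat, lm = fit),
            class = "difficulty_regression")
}

#' @export
print.difficulty_regression <- function(x, ...) {
  cat("Difficulty-on-features regression (OLS)\n")
  tab <- data.frame(estimate = x$coefficients, se = x$se,
                    std = x$standardized, std_se = x$standardized_se)
  print(round(tab, 4))
  cat(sprintf("  Adj. R-squared %.3f; F(%g, %g) = %.2f, p = %.3g\n",
              x$adj_r_squared, x$f_statistic["df1"],
              x$f_statistic["df2"], x$f_statistic["value"],
              x$f_statistic["p"]))
  invisible(x)
}

#' @export
coef.difficulty_regression <- function(object, ...) object$coefficients
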