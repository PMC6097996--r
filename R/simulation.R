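#' Simulated responder for virtual-participant experiments
#'
#' Returns a responder function suitable for [run_session()]: presented
#' with an item of difficulty `b`, it answers correctly with probability
#' `prob_correct_2afc(true_theta, b, a)`, with Bernoulli draws from a
#' private seeded stream.
#'
#' @param true_theta The virtual participant's true ability.
#' @param coefficients A [difficulty_coefficients()] object (supplies the
#'   discrimination).
#' @param seed Integer seed for the responder's private stream.
#' @return A function `function(item) -> 0/1`.
#' @export
simulate_responder <- function(true_theta,
                               coefficients = difficulty_coefficients(),
                               seed = 1L) {
  rng <- local_rng(seed)
  a <- coefficients$discrimination
  function(item) {
    p <- prob_correct_2afc(true_theta, item$difficulty, a)
    rng$bern(p)
  }
}

#' Replicate a set of abilities into a virtual cohort
#'
#' Each ability is replicated `factor` times, emulating the construction
#' of a large virtual participant group from a small set of observed
#' ability estimates.
#'
#' @param abilities Numeric vector of true abilities.
#' @param factor Replication factor, `>= 1`.
#' @param seed Seed recorded in the cohort's provenance.
#' @return An object of class `"virtual_cohort"` (numeric vector of
#'   abilities with provenance attributes).
#' @examples
#' length(upsample_cohort(rnorm(52), 250))  # 13000
#' @export
upsample_cohort <- function(abilities, factor = 250, seed = NA_integer_) {
  stopifnot(length(abilities) >= 1, all(is.finite(abilities)),
            factor >= 1)
  structure(rep(abilities, each = as.integer(factor)),
            provenance = list(source = "up-sampled",
                              factor = as.integer(factor), seed = seed),
            class = "virtual_cohort")
}

#' Draw a virtual cohort from the standard-normal ability population
#'
#' @param n Cohort size.
#' @param seed Integer seed.
#' @return A `"virtual_cohort"` object.
#' @export
sample_cohort <- function(n, seed = 1L) {
  structure(local_rng(seed)$norm(n),
            provenance = list(source = "N(0,1)", seed = seed),
            class = "virtual_cohort")
}

#' @export
print.virtual_cohort <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("Virtual cohort: %d participants (%s)\n", length(x),
              prov$source))
  invisible(x)
}

#' Standard-error and test-retest reliability curves by simulation
#'
#' Runs `n_sessions` independent adaptive sessions for every cohort
#' member and, for each test length `k`, rescores each session's first
#' `k` responses by weighted likelihood. Aggregates the mean standard
#' error across participants (sessions pooled) and, when
#' `n_sessions >= 2`, the Pearson correlation between the first two
#' sessions' length-`k` scores — the simulated test-retest reliability.
#' Confidence bands are percentile bootstrap over participants.
#'
#' @param cohort A `"virtual_cohort"` (or numeric vector of abilities).
#' @param bank An `"item_bank"`.
#' @param config A [session_config()]; its seed acts as the master seed
#'   from which all per-participant streams are derived.
#' @param n_sessions Sessions per participant (default 2).
#' @param lengths Test lengths at which to evaluate the curve (default
#'   every length `1:test_length`).
#' @param n_boot Bootstrap resamples for the confidence bands (0 skips
#'   bands).
#' @return An object of class `"reliability_curve"`: a data frame with
#'   columns `k`, `mean_se`, `se_lo`, `se_hi`, `retest_r`, `r_lo`,
#'   `r_hi`, with the per-participant score matrices in attributes.
#'   `retest_r` is `NA` (flagged by a warning) when the cohort has zero
#'   ability variance.
#' @examples
#' \donttest{
#' curve <- reliability_experiment(sample_cohort(50, 1), standard_bank(),
#'                                 session_config(seed = 1),
#'                                 lengths = c(5, 15, 25), n_boot = 200)
#' curve
#' }
#' @export
reliability_experiment <- function(cohort, bank,
                                   config = session_config(),
                                   n_sessions = 2,
                                   lengths = seq_len(config$test_length),
                                   n_boot = 1000) {
  abilities <- as.numeric(cohort)
  n <- length(abilities)
  stopifnot(n >= 1, n_sessions >= 1,
            all(lengths >= 1 & lengths <= config$test_length))
  all_seeds <- derive_seeds(config$seed, 2L * n * n_sessions + 1L)
  boot_seed <- all_seeds[length(all_seeds)]
  seeds <- matrix(all_seeds[-length(all_seeds)], nrow = 2L)
  theta_arr <- array(NA_real_, c(n, n_sessions, length(lengths)))
  se_arr <- array(NA_real_, c(n, n_sessions, length(lengths)))
  idx <- 0L
  for (i in seq_len(n)) {
    for (s in seq_len(n_sessions)) {
      idx <- idx + 1L
      resp <- simulate_responder(abilities[i], attr(bank, "coefficients"),
                                 seed = seeds[1L, idx])
      cfg <- config
      cfg$seed <- seeds[2L, idx]
      sess <- run_session(bank, resp, cfg)
      for (j in seq_along(lengths)) {
        est <- rescore_at_length(sess, lengths[j])
        theta_arr[i, s, j] <- est$theta
        se_arr[i, s, j] <- est$se
      }
    }
  }
  boot_idx <- if (n_boot > 0)
    matrix(ceiling(local_rng(boot_seed)$unif(n * n_boot) * n),
           nrow = n_boot) else NULL
  rows <- lapply(seq_along(lengths), function(j) {
    se_k <- se_arr[, , j, drop = FALSE]
    mean_se <- mean(se_k)
    r <- r_lo <- r_hi <- se_lo <- se_hi <- NA_real_
    if (n_sessions >= 2) {
      t1 <- theta_arr[, 1L, j]; t2 <- theta_arr[, 2L, j]
      if (isTRUE(stats::var(t1) > 0) && isTRUE(stats::var(t2) > 0)) {
        r <- stats::cor(t1, t2)
      } else {
        warning("zero score variance: test-retest r undefined",
                call. = FALSE)
      }
    }
    if (!is.null(boot_idx)) {
      bs <- apply(boot_idx, 1L, function(ix) {
        rb <- if (n_sessions >= 2 &&
                  isTRUE(stats::var(theta_arr[ix, 1L, j]) > 0) &&
                  isTRUE(stats::var(theta_arr[ix, 2L, j]) > 0))
          stats::cor(theta_arr[ix, 1L, j], theta_arr[ix, 2L, j])
        else NA_real_
        c(mean(se_arr[ix, , j]), rb)
      })
      se_lo <- stats::quantile(bs[1L, ], 0.025, names = FALSE)
      se_hi <- stats::quantile(bs[1L, ], 0.975, names = FALSE)
      if (!all(is.na(bs[2L, ]))) {
        r_lo <- stats::quantile(bs[2L, ], 0.025, names = FALSE,
                                na.rm = TRUE)
        r_hi <- stats::quantile(bs[2L, ], 0.975, names = FALSE,
                                na.rm = TRUE)
      }
    }
    data.frame(k = lengths[j], mean_se = mean_se, se_lo = se_lo,
               se_hi = se_hi, retest_r = r, r_lo = r_lo, r_hi = r_hi)
  })
  out <- do.call(rbind, rows)
  structure(out, abilities = abilities, theta = theta_arr, se = se_arr,
            class = c("reliability_curve", "data.frame"))
}

#' @export
print.reliability_curve <- function(x, ...) {
  cat("Simulated reliability curve\n")
  df <- as.data.frame(x)
  df[] <- lapply(df, function(col) round(col, 3))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Plot a reliability curve
#'
#' Mean weighted-likelihood standard error (left axis, solid) and
#' test-retest correlation (right axis, dashed) as functions of test
#' length, with bootstrap confidence bands.
#'
#' @param x A `"reliability_curve"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.reliability_curve <- function(x, ...) {
  df <- as.data.frame(x)
  graphics::plot(df$k, df$mean_se, type = "b", pch = 16,
                 xlab = "test length (items)", ylab = "mean SE",
                 ylim = range(df$se_lo, df$se_hi, df$mean_se,
                              na.rm = TRUE), ...)
  if (!all(is.na(df$se_lo)))
    graphics::polygon(c(df$k, rev(df$k)), c(df$se_lo, rev(df$se_hi)),
                      border = NA, col = grDevices::adjustcolor("grey", 0.5))
  if (!all(is.na(df$retest_r))) {
    graphics::par(new = TRUE)
    graphics::plot(df$k, df$retest_r, type = "b", pch = 1, lty = 2,
                   axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
    graphics::axis(4)
    graphics::mtext("test-retest r", side = 4, line = 2)
  }
  invisible(x)
}

#' Write a reliability curve as CSV
#'
#' Columns `k, mean_se, se_lo, se_hi, retest_r, r_lo, r_hi`.
#'
#' @param curve A `"reliability_curve"` object.
#' @param path File path.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
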