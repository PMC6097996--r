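test_that("marginal likelihood matches dense-grid numerical integration", {
  set.seed(4)
  b <- runif(6, -2, 2)
  x <- matrix(rbinom(5 * 6, 1, 0.7), 5, 6)
  x[1, 3] <- NA  # missing responses are ignorable
  got <- marginal_loglik(x, b, a = 1.4)
  grid <- seq(-6, 6, length.out = 10001)
  dg <- apply(x, 1, function(xi) {
    ok <- !is.na(xi)
    lik <- vapply(grid, function(t)
      exp(sum(xi[ok] * log(oracle_prob(t, b[ok], 1.4)) +
                (1 - xi[ok]) * log(1 - oracle_prob(t, b[ok], 1.4)))),
      numeric(1))
    log(sum(lik * dnorm(grid)) * (grid[2] - grid[1]))
  })
  expect_equal(got, dg, tolerance = 1e-6)
})

test_that("constrained 3PL recovers generating parameters", {
  b_true <- seq(-2, 2, length.out = 27)
  items <- data.frame(item_id = sprintf("i%02d", 1:27),
                      difficulty = b_true)
  sim <- make_response_matrix(
    500, items, difficulty_coefficients(discrimination = 1.6),
    seed = 42)
  fit <- fit_constrained_3pl(sim$matrix)
  expect_true(fit$convergence)
  expect_lt(mean(abs(fit$difficulties - b_true)), 0.25)
  expect_lt(abs(fit$discrimination - 1.6) / 1.6, 0.15)
  expect_true(all(fit$difficulty_se > 0))
  expect_gt(fit$discrimination_se, 0)
})

test_that("identical response columns get identical difficulty estimates", {
  set.seed(8)
  x <- matrix(rbinom(150 * 9, 1, 0.75), 150, 9)
  x <- cbind(x, x[, 2])  # item 10 duplicates item 2
  fit <- fit_constrained_3pl(x)
  expect_equal(unname(fit$difficulties[10]),
               unname(fit$difficulties[2]), tolerance = 1e-6)
})

test_that("the optimum beats random parameter vectors", {
  set.seed(12)
  b_true <- runif(8, -1.5, 1.5)
  items <- data.frame(item_id = sprintf("i%d", 1:8),
                      difficulty = b_true)
  sim <- make_response_matrix(120, items, seed = 3)
  fit <- fit_constrained_3pl(sim$matrix)
  best <- sum(marginal_loglik(sim$matrix$scores, fit$difficulties,
                              fit$discrimination))
  expect_equal(best, fit$log_likelihood, tolerance = 1e-6)
  for (r in 1:100) {
    ll_r <- sum(marginal_loglik(sim$matrix$scores, runif(8, -4, 4),
                                runif(1, 0.2, 4)))
    expect_lte(ll_r, best + 1e-8)
  }
})

test_that("degenerate all-correct columns are flagged at the bounds", {
  set.seed(5)
  x <- matrix(rbinom(60 * 3, 1, 0.8), 60, 3)
  x <- cbind(x, 1L)  # an item everyone answers correctly
  expect_warning(fit <- fit_constrained_3pl(x), "degenerate")
  expect_length(fit$flagged_items, 1)
  expect_lte(fit$difficulties[4], -7.9)
})

test_that("difficulty estimates shift with a constant shift of the truth", {
  base <- seq(-1, 1, length.out = 10)
  est <- lapply(c(0, 0.7), function(shift) {
    items <- data.frame(item_id = sprintf("i%d", 1:10),
                        difficulty = base + shift)
    sim <- make_response_matrix(800, items, seed = 99)
    fit_constrained_3pl(sim$matrix)$difficulties
  })
  # the estimated profiles differ by about the planted shift
  expect_equal(mean(est[[2]] - est[[1]]), 0.7, tolerance = 0.15)
})

test_that("explanatory calibration recovers the published coefficients", {
  bank <- build_bank(sprintf("t%02d", 1:27), accuracy_grid(27, 0.5, 1),
                     seed = 1)
  sim <- make_response_matrix(300, bank, design = "balanced", seed = 7)
  fit <- fit_explanatory_model(sim$matrix)
  expect_true(fit$convergence)
  truth <- c(intercept = -5.393, accuracy = 7.247,
             direction_behind = -0.576)
  est <- coef(fit$coefficients)
  for (k in names(truth)) {
    tol <- max(0.2 * abs(truth[[k]]), 2 * fit$coefficient_se[[k]])
    expect_lt(abs(est[[k]] - truth[[k]]), tol)
  }
  expect_lt(abs(fit$discrimination - 1.166), 0.2 * 1.166 + 1e-9)
  # raw effects are minus discrimination times difficulty effects
  expect_equal(unname(fit$raw_effects),
               unname(-fit$discrimination * est), tolerance = 1e-9)
  # sign structure: accuracy raises difficulty, behind lowers it
  expect_gt(est[["accuracy"]], 0)
  expect_lt(est[["direction_behind"]], 0)
})

test_that("a null direction effect is estimated near zero", {
  coefs <- difficulty_coefficients(direction_effect = 0)
  bank <- build_bank(sprintf("t%02d", 1:12), accuracy_grid(12, 0.5, 1),
                     coefficients = coefs)
  hits <- vapply(1:40, function(s) {
    sim <- make_response_matrix(120, bank, coefficients = coefs,
                                design = "balanced", seed = 500 + s)
    fit <- fit_explanatory_model(sim$matrix, quadrature = 31)
    abs(coef(fit$coefficients)[["direction_behind"]]) <=
      2 * fit$coefficient_se[["direction_behind"]]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("one-stage and two-stage calibration agree on a balanced design", {
  # complete factorial data: per-item 3PL difficulties then OLS on
  # features should agree with the direct explanatory fit
  bank <- build_bank(sprintf("t%02d", 1:4), accuracy_grid(5, 0.55, 0.95))
  sim <- make_response_matrix(600, bank, seed = 17)
  one <- fit_explanatory_model(sim$matrix)
  two_a <- fit_constrained_3pl(sim$matrix)
  reg <- regress_difficulty_on_features(
    two_a$difficulties,
    data.frame(accuracy = sim$matrix$items$accuracy,
               behind = as.numeric(sim$matrix$items$direction ==
                                     "behind")))
  cf1 <- coef(one$coefficients)
  cf2 <- coef(reg)
  joint_se <- sqrt(one$coefficient_se^2 + reg$se^2)
  for (k in 1:3)
    expect_lt(abs(cf1[[k]] - cf2[[k]]), 3 * joint_se[[k]] + 0.05)
})

test_that("difficulty regression reports OLS, standardised effects and fit", {
  acc <- seq(0.55, 0.95, length.out = 16)
  # exactly linear difficulties: perfect fit, zero residuals
  d_exact <- -8.388 + 10.025 * acc
  # summary.lm warns about the perfect fit; that is the point here
  reg <- suppressWarnings(regress_difficulty_on_features(d_exact, acc))
  expect_equal(unname(coef(reg)), c(-8.388, 10.025), tolerance = 1e-9)
  expect_equal(reg$adj_r_squared, 1, tolerance = 1e-9)
  expect_equal(unname(residuals(reg$lm)), rep(0, 16), tolerance = 1e-9)

  # slope recovery under noise: within 2 SE of the generating slope
  hits <- vapply(1:20, function(s) {
    set.seed(400 + s)
    d <- -8.388 + 10.025 * acc + rnorm(16, sd = 0.5)
    r <- regress_difficulty_on_features(d, acc)
    abs(coef(r)[["feature"]] - 10.025) <= 2 * r$se[["feature"]]
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # intercept-only (constant feature) returns the mean difficulty
  r0 <- regress_difficulty_on_features(d_exact,
                                       data.frame(z = rep(1, 16)))
  expect_equal(unname(coef(r0)[1]), mean(d_exact), tolerance = 1e-9)
  expect_error(regress_difficulty_on_features(1:4,
                 data.frame(a = c(1, 1, 2, 2), b = c(2, 2, 4, 4))),
               "rank deficient")
})

test_that("direct marginal ML agrees with a mixed-model cross-check", {
  # independent route: lme4::glmer with a custom 2-AFC link
  bank <- build_bank(sprintf("t%02d", 1:12), accuracy_grid(12, 0.5, 1))
  sim <- make_response_matrix(150, bank, design = "balanced", seed = 31)
  fit <- fit_explanatory_model(sim$matrix)

  sc <- sim$matrix$scores
  long <- data.frame(
    person = rep(rownames(sc), ncol(sc)),
    y = as.vector(sc),
    accuracy = rep(sim$matrix$items$accuracy, each = nrow(sc)),
    behind = rep(as.numeric(sim$matrix$items$direction == "behind"),
                 each = nrow(sc)))
  long <- long[!is.na(long$y), ]
  two_afc_link <- structure(list(
    linkfun = function(mu) qlogis(pmax((mu - 0.5) / 0.5, 1e-10)),
    linkinv = function(eta) 0.5 + 0.5 * plogis(eta),
    mu.eta = function(eta) 0.5 * dlogis(eta),
    valideta = function(eta) TRUE,
    name = "2afc-logit"), class = "link-glm")
  gm <- suppressWarnings(
    lme4::glmer(y ~ accuracy + behind + (1 | person), data = long,
                family = binomial(two_afc_link), nAGQ = 10))
  raw_glmer <- lme4::fixef(gm)
  sd_glmer <- sqrt(unname(lme4::VarCorr(gm)$person[1]))
  # discrimination equals the person-intercept SD; raw effects match
  expect_lt(abs(fit$discrimination - sd_glmer), 0.05)
  expect_lt(max(abs(fit$raw_effects - raw_glmer)), 0.05)
})
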