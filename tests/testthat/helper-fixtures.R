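# Shared fixtures and independent oracle implementations. Oracles here
# deliberately avoid the package's own code paths: probabilities are
# rebuilt from plain formulas and derivatives taken numerically.

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_bank <- function(n_tracks = 9, n_acc = 9, seed = 1L) {
  build_bank(sprintf("trk%02d", seq_len(n_tracks)),
             accuracy_grid(n_acc, 0.5, 1), seed = seed)
}

# plain-formula response probability (independent of the package)
oracle_prob <- function(theta, b, a = 1.166, cc = 0.5) {
  cc + (1 - cc) * plogis(a * (theta - b))
}

oracle_loglik <- function(theta, b, x, a = 1.166) {
  p <- oracle_prob(theta, b, a)
  sum(x * log(p) + (1 - x) * log(1 - p))
}

# dense grid maximizer of an objective on [-6, 6]; two-stage to reach
# `step` resolution quickly
grid_argmax <- function(f, step = 1e-4, bounds = c(-6, 6)) {
  coarse <- seq(bounds[1], bounds[2], by = 0.01)
  v <- vapply(coarse, f, numeric(1))
  c0 <- coarse[which.max(v)]
  fine <- seq(max(bounds[1], c0 - 0.02), min(bounds[2], c0 + 0.02),
              by = step)
  fine[which.max(vapply(fine, f, numeric(1)))]
}

# Warm's corrected score built from numerical derivatives of the plain
# formulas (independent route to the weighted-likelihood root)
oracle_wl_score <- function(theta, b, x, a = 1.166, h = 1e-5) {
  s <- (oracle_loglik(theta + h, b, x, a) -
          oracle_loglik(theta - h, b, x, a)) / (2 * h)
  p <- oracle_prob(theta, b, a)
  dp <- (oracle_prob(theta + h, b, a) - oracle_prob(theta - h, b, a)) /
    (2 * h)
  d2p <- (oracle_prob(theta + h, b, a) - 2 * p +
            oracle_prob(theta - h, b, a)) / h^2
  info <- sum(dp^2 / (p * (1 - p)))
  s + sum(dp * d2p / (p * (1 - p))) / (2 * info)
}

oracle_wl_root <- function(b, x, a = 1.166, step = 1e-4) {
  g <- seq(-6, 6, by = 0.01)
  v <- vapply(g, function(t) oracle_wl_score(t, b, x, a), numeric(1))
  ix <- which(v[-1] * v[-length(v)] <= 0)
  if (!length(ix)) return(g[which.min(abs(v))])
  lo <- g[ix[1]]; hi <- g[ix[1] + 1]
  fine <- seq(lo, hi, by = step)
  fv <- vapply(fine, function(t) oracle_wl_score(t, b, x, a), numeric(1))
  fine[which.min(abs(fv))]
}

# vectorised grid oracles (plain formulas, matrix algebra over a theta
# grid) for checking the estimators on many patterns quickly
oracle_grid_loglik <- function(grid, b, x, a = 1.166) {
  p <- 0.5 + 0.5 * plogis(a * outer(grid, b, `-`))
  as.numeric(log(p) %*% x + log(1 - p) %*% (1 - x))
}

oracle_bm_grid <- function(b, x, a = 1.166) {
  grid <- seq(-6, 6, by = 0.01)
  post <- oracle_grid_loglik(grid, b, x, a) + dnorm(grid, log = TRUE)
  c0 <- grid[which.max(post)]
  fine <- seq(max(-6, c0 - 0.02), min(6, c0 + 0.02), by = 1e-4)
  postf <- oracle_grid_loglik(fine, b, x, a) + dnorm(fine, log = TRUE)
  fine[which.max(postf)]
}

oracle_eap_grid <- function(b, x, a = 1.166) {
  grid <- seq(-6, 6, length.out = 10001)
  w <- exp(oracle_grid_loglik(grid, b, x, a)) * dnorm(grid)
  w <- w / sum(w)
  m <- sum(w * grid)
  c(mean = m, sd = sqrt(sum(w * (grid - m)^2)))
}

oracle_wl_grid <- function(b, x, a = 1.166, h = 1e-5) {
  corrected <- function(grid) {
    s <- (oracle_grid_loglik(grid + h, b, x, a) -
            oracle_grid_loglik(grid - h, b, x, a)) / (2 * h)
    pp <- function(g) 0.5 + 0.5 * plogis(a * outer(g, b, `-`))
    p <- pp(grid)
    dp <- (pp(grid + h) - pp(grid - h)) / (2 * h)
    d2p <- (pp(grid + h) - 2 * p + pp(grid - h)) / h^2
    info <- rowSums(dp^2 / (p * (1 - p)))
    s + rowSums(dp * d2p / (p * (1 - p))) / (2 * info)
  }
  grid <- seq(-6, 6, by = 0.01)
  v <- corrected(grid)
  ix <- which(v[-1] * v[-length(v)] <= 0)
  if (!length(ix)) return(grid[which.min(abs(v))])
  fine <- seq(grid[ix[1]], grid[ix[1] + 1], by = 1e-4)
  fv <- corrected(fine)
  fine[which.min(abs(fv))]
}

random_pattern <- function(n_items, theta, seed) {
  set.seed(seed)
  b <- runif(n_items, -2.4, 1.9)
  p <- oracle_prob(theta, b)
  list(b = b, x = as.integer(runif(n_items) < p))
}
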