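test_that("the first item sits at the configured difficulty target", {
  bank <- standard_bank()
  it <- select_first_item(bank, session_config(seed = 3))
  # the published-coefficient bank has an item within 0.05 of ability 0
  expect_lt(abs(it$difficulty - 0), 0.05)
  # brute-force: no bank item is closer to the target
  expect_equal(abs(it$difficulty - (-0.01)),
               min(abs(bank$difficulty - (-0.01))), tolerance = 1e-12)
  # single-item bank returns that item
  one <- build_bank("t1", 0.8, "ahead", "target_first")
  expect_equal(select_first_item(one, session_config(seed = 1))$item_id,
               one$item_id)
  expect_error(select_first_item(one[0, ], session_config()), "empty")
})

test_that("equidistant first-item candidates are drawn with the seeded generator", {
  # two items exactly equidistant from the target: both must occur
  bank <- build_bank(c("t1", "t2"), 0.7)
  cfg <- session_config(first_item_difficulty =
                          mean(bank$difficulty[1:2]))
  target <- cfg$first_item_difficulty
  d <- abs(bank$difficulty - target)
  ties <- which(d <= min(d) + 1e-12)
  expect_gte(length(ties), 2)
  picks <- vapply(1:40, function(s) {
    cfg$seed <- s
    select_first_item(bank, cfg, local_rng(s))$item_id
  }, character(1))
  expect_gt(length(unique(picks)), 1)
  # deterministic under a fixed seed
  expect_identical(select_first_item(bank, cfg, local_rng(9))$item_id,
                   select_first_item(bank, cfg, local_rng(9))$item_id)
})

test_that("nearest-difficulty selection matches an exhaustive scan under track exclusion", {
  bank <- tiny_bank(n_tracks = 12, n_acc = 12)
  cfg <- session_config(test_length = 5)
  used <- c("trk01", "trk05")
  for (s in 1:200) {
    theta <- runif(1, -3, 3)
    it <- select_next_item(bank, theta, used, cfg, local_rng(s))
    eligible <- bank[!(bank$track_id %in% used), ]
    expect_false(it$track_id %in% used)
    expect_equal(abs(it$difficulty - theta),
                 min(abs(eligible$difficulty - theta)),
                 tolerance = 1e-12)
  }
})

test_that("selection clamps to the bank boundary for extreme estimates", {
  bank <- tiny_bank()
  hi <- select_next_item(bank, 50, character(0), session_config(),
                         local_rng(1))
  expect_equal(hi$difficulty, max(bank$difficulty))
  lo <- select_next_item(bank, -50, character(0), session_config(),
                         local_rng(1))
  expect_equal(lo$difficulty, min(bank$difficulty))
  all_used <- unique(bank$track_id)
  expect_error(select_next_item(bank, 0, all_used, session_config(),
                                local_rng(1)), "exhausted")
})

test_that("sessions respect length, track exclusion and determinism", {
  bank <- standard_bank()
  cfg <- session_config(test_length = 25, seed = 11)
  s1 <- run_session(bank, simulate_responder(0.3, seed = 21), cfg)
  expect_length(s1$responses, 25)
  expect_equal(anyDuplicated(s1$items$track_id), 0L)
  expect_length(s1$trajectory, 25)
  expect_equal(s1$final$method, "weighted_likelihood")
  # identical (bank, seed, responder) reproduces the whole session
  s2 <- run_session(bank, simulate_responder(0.3, seed = 21), cfg)
  expect_identical(s1$items$item_id, s2$items$item_id)
  expect_identical(s1$responses, s2$responses)
  expect_equal(s1$final$theta, s2$final$theta, tolerance = 1e-12)
  # test length cannot exceed the number of tracks
  expect_error(run_session(tiny_bank(n_tracks = 5), function(i) 1L,
                           session_config(test_length = 6)),
               "distinct tracks")
})

test_that("an always-correct responder climbs to the bank ceiling", {
  bank <- standard_bank()
  s <- run_session(bank, function(item) 1L,
                   session_config(test_length = 20, seed = 2))
  th <- vapply(s$trajectory, `[[`, numeric(1), "theta")
  expect_true(all(diff(th) > -1e-9))
  # difficulties rise until they saturate at the ceiling
  d <- s$items$difficulty
  expect_gt(d[10], d[1])
  expect_equal(max(d), max(bank$difficulty), tolerance = 0.1)
})

test_that("an always-incorrect responder sinks to the bank floor", {
  bank <- standard_bank()
  s <- run_session(bank, function(item) 0L,
                   session_config(test_length = 20, seed = 2))
  th <- vapply(s$trajectory, `[[`, numeric(1), "theta")
  expect_true(all(diff(th) < 1e-9))
  expect_equal(min(s$items$difficulty), min(bank$difficulty),
               tolerance = 0.1)
})

test_that("replaying a logged session reproduces its trajectory", {
  bank <- standard_bank()
  s <- run_session(bank, simulate_responder(-0.7, seed = 5),
                   session_config(seed = 5))
  for (k in c(3, 12, 25)) {
    est <- estimate_bayes_modal(s$responses[1:k],
                                s$items$difficulty[1:k], s$params)
    expect_equal(est$theta, s$trajectory[[k]]$theta, tolerance = 1e-9)
    expect_equal(est$se, s$trajectory[[k]]$se, tolerance = 1e-9)
  }
  refinal <- estimate_weighted_likelihood(s$responses,
                                          s$items$difficulty, s$params)
  expect_equal(refinal$theta, s$final$theta, tolerance = 1e-9)
  # rescoring at full length equals the final estimate
  expect_equal(rescore_at_length(s, 25)$theta, s$final$theta,
               tolerance = 1e-12)
})

test_that("session logs round-trip through JSON lines", {
  bank <- tiny_bank()
  s <- run_session(bank, simulate_responder(0, seed = 3),
                   session_config(test_length = 6, seed = 3))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_session_log(s, path)
  log <- read_session_log(path)
  expect_equal(nrow(log$items), 6)
  expect_equal(log$items$item_id, s$items$item_id)
  expect_equal(log$items$response, s$responses)
  expect_equal(log$items$theta_interim,
               vapply(s$trajectory, `[[`, numeric(1), "theta"),
               tolerance = 1e-12)
  expect_equal(log$final$theta, s$final$theta, tolerance = 1e-12)
})

test_that("a failing responder aborts with the partial log preserved", {
  bank <- tiny_bank()
  n_answered <- 0
  responder <- function(item) {
    n_answered <<- n_answered + 1
    if (n_answered == 4) stop("headphones unplugged")
    1L
  }
  err <- tryCatch(
    run_session(bank, responder, session_config(test_length = 6)),
    error = identity)
  expect_match(conditionMessage(err), "item 4")
  expect_s3_class(err$data, "cat_session")
  expect_length(err$data$responses, 3)
})

test_that("administered difficulties track the true ability", {
  bank <- standard_bank()
  run_dev <- function(theta, seed) {
    s <- run_session(bank, simulate_responder(theta, seed = seed),
                     session_config(seed = seed + 1000))
    mean(abs(s$items$difficulty[16:25] - theta))
  }
  # bank density: every late item sits essentially on the interim
  # estimate that selected it (grid resolution, under track exclusion)
  for (theta in c(-0.8, 0, 0.8)) {
    s <- run_session(bank, simulate_responder(theta, seed = 50),
                     session_config(seed = 51))
    sel_target <- vapply(s$trajectory[15:24], `[[`, numeric(1), "theta")
    expect_true(all(abs(s$items$difficulty[16:25] - sel_target) < 0.05))
  }
  # averaged over a cohort at the population centre, late items stay
  # close to the true ability
  centre_dev <- mean(vapply(1:12, function(s)
    run_dev(0, 300 + s), numeric(1)))
  expect_lt(centre_dev, 0.8)
  late_mean <- vapply(seq(-2, 2, by = 1), function(theta) {
    s <- run_session(bank, simulate_responder(theta, seed = 40),
                     session_config(seed = 41))
    mean(s$items$difficulty[16:25])
  }, numeric(1))
  expect_true(all(diff(late_mean) > 0))
})
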