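iso_take <- function(drummer, take, n = 12, period = 0.5, shift = 0,
                     latency = 0) {
  tap_take(drummer, take, seq_len(n) * period + shift + latency,
           latency_correction = latency)
}

test_that("identical takes reproduce themselves with zero phase difference", {
  takes <- list(iso_take("d1", "t1"), iso_take("d1", "t2"))
  ann <- consensus_beats(takes)
  expect_equal(ann$beat_times, seq_len(12) * 0.5, tolerance = 1e-12)
  expect_equal(ann$mean_period, 0.5, tolerance = 1e-12)
  expect_equal(unname(ann$screening$within_phase), 0)
  expect_false(ann$screening$flagged)
})

test_that("latency correction is applied before averaging", {
  takes <- list(iso_take("d1", "t1", latency = 0.02),
                iso_take("d1", "t2", latency = 0.02))
  ann <- consensus_beats(takes)
  expect_equal(ann$beat_times, seq_len(12) * 0.5, tolerance = 1e-12)
})

test_that("constant offsets convert to the documented phase thresholds", {
  # 30 ms at a 500 ms period: 2*pi*0.06 ~ 0.377 rad, not flagged
  takes <- list(iso_take("d1", "t1"), iso_take("d1", "t2", shift = 0.03))
  ann <- consensus_beats(takes)
  expect_equal(unname(ann$screening$within_phase), 2 * pi * 0.06,
               tolerance = 1e-9)
  expect_false(ann$screening$flagged)
  # 9.5% of a beat sits at the 0.6 rad within-drummer threshold
  t95 <- list(iso_take("d1", "t1"),
              iso_take("d1", "t2", shift = 0.095 * 0.5))
  ph <- consensus_beats(t95)$screening$within_phase
  expect_equal(round(unname(ph), 1), 0.6)
  # 11.1% of a beat sits at the 0.7 rad between-drummer threshold
  t111 <- list(iso_take("d1", "t1"), iso_take("d1", "t2"),
               iso_take("d2", "t3", shift = 0.111 * 0.5),
               iso_take("d2", "t4", shift = 0.111 * 0.5))
  bp <- consensus_beats(t111)$screening$between_phase
  expect_equal(round(unname(bp), 1), 0.7)
})

test_that("take selection picks the pair with closest inter-tap intervals", {
  # a third take with a stretched period must be ignored
  stretched <- tap_take("d1", "slow", seq_len(12) * 0.56)
  takes <- list(iso_take("d1", "t1"), stretched,
                iso_take("d1", "t2", shift = 0.01))
  ann <- consensus_beats(takes)
  expect_setequal(ann$screening$selected_takes, c("t1", "t2"))
  expect_equal(ann$mean_period, 0.5, tolerance = 0.01)
  expect_error(consensus_beats(list(iso_take("d1", "t1"))),
               "at least two")
})

test_that("consensus is invariant to take order and equivariant to time shifts", {
  takes <- list(iso_take("d1", "t1"), iso_take("d1", "t2", shift = 0.01),
                iso_take("d2", "t3", shift = -0.02),
                iso_take("d2", "t4", shift = 0.015))
  ann1 <- consensus_beats(takes)
  ann2 <- consensus_beats(rev(takes))
  expect_equal(sort(ann1$beat_times), sort(ann2$beat_times),
               tolerance = 1e-12)
  shifted <- lapply(takes, function(t) {
    t$onsets <- t$onsets + 1.3; t
  })
  ann3 <- consensus_beats(shifted)
  expect_equal(ann3$beat_times, ann1$beat_times + 1.3,
               tolerance = 1e-12)
})

test_that("beep schedules implement the displacement geometry", {
  beats <- seq(0.5, 5, by = 0.5)
  target <- beep_schedule(beats, "target")
  expect_equal(target$onsets, beats)
  # isochronous beats at 0.5 s, P = 0.1 behind: every onset +0.05 s
  behind <- beep_schedule(beats, "lure", offset = 0.1,
                          direction = "behind")
  expect_equal(behind$onsets, beats + 0.05, tolerance = 1e-12)
  ahead <- beep_schedule(beats, "lure", offset = 0.1,
                         direction = "ahead")
  expect_equal(ahead$onsets, beats - 0.05, tolerance = 1e-12)
  # offset round trip to 1e-9
  for (p in c(0.05, 0.17, 0.5)) {
    lure <- beep_schedule(beats, "lure", offset = p,
                          direction = "behind")
    implied <- (lure$onsets - beats[seq_along(lure$onsets)]) / 0.5
    expect_equal(implied, rep(p, length(implied)), tolerance = 1e-9)
  }
  # P -> 0 limit approaches the target schedule
  near0 <- beep_schedule(beats, "lure", offset = 1e-9,
                         direction = "ahead")
  expect_equal(near0$onsets, beats, tolerance = 1e-8)
  # half-period displacement: ahead and behind coincide except at the
  # sequence boundaries
  h_ahead <- beep_schedule(beats, "lure", offset = 0.5,
                           direction = "ahead")
  h_behind <- beep_schedule(beats, "lure", offset = 0.5,
                            direction = "behind")
  common <- intersect(round(h_ahead$onsets, 9),
                      round(h_behind$onsets, 9))
  expect_gte(length(common), length(beats) - 2)
  expect_error(beep_schedule(beats, "lure", offset = 0.7,
                             direction = "ahead"), "0, 0.5")
})

test_that("lure displacement uses the local inter-beat interval", {
  beats <- c(0.5, 1.0, 1.6, 2.4)  # accelerating periods 0.5, 0.6, 0.8
  lure <- beep_schedule(beats, "lure", offset = 0.25,
                        direction = "behind", duration = 4)
  expect_equal(lure$onsets,
               beats + 0.25 * c(0.5, 0.6, 0.8, 0.8),
               tolerance = 1e-12)
})

test_that("rendered beeps have the documented shape and recoverable onsets", {
  # schedule whose onsets all fall outside the excerpt renders silence
  silent <- render_beep_track(beep_schedule(c(1, 2), "target",
                                            duration = 0.5))
  expect_true(all(silent$samples == 0))
  expect_length(detect_onsets(silent), 0)
  beats <- c(0.5, 1.2, 2.0)
  wave <- render_beep_track(beep_schedule(beats, "target",
                                          duration = 2.5))
  expect_equal(wave$sample_rate, 44100)
  expect_lte(max(abs(wave$samples)), 1)
  # a single beep spans 882 samples at 44.1 kHz, fading over the last 441
  one <- render_beep_track(beep_schedule(1, "target", duration = 2))
  region <- one$samples[(round(1 * 44100) + 1):(round(1 * 44100) + 882)]
  expect_gt(max(abs(region)), 0.9)
  expect_true(all(one$samples[seq_len(44100)] == 0))
  expect_true(all(abs(one$samples[(44100 + 883):88200]) == 0))
  # the fade ramp scales the final 441 samples towards zero
  fade <- abs(region[442:882])
  raw <- abs(sin(2 * pi * 1000 * ((441:881) / 44100)))
  scale <- fade / pmax(raw, 1e-9)
  expect_true(all(diff(tapply(scale, (0:440) %/% 44, max)) < 0.05))
  # onsets recovered within one sample
  got <- detect_onsets(wave)
  expect_length(got, 3)
  expect_true(all(abs(got - beats) <= 1 / 44100 + 1e-12))
})

test_that("trials assemble to the documented duration", {
  five_s <- beep_schedule(seq(0.5, 4.5, by = 0.5), "target",
                          duration = 5)
  a <- render_beep_track(five_s)
  b <- render_beep_track(five_s)
  trial <- assemble_trial(a, b, gap = 2)
  expect_equal(length(trial$samples) / trial$sample_rate, 12,
               tolerance = 1e-6)
  # zero gap is plain concatenation
  cat0 <- assemble_trial(a, b, gap = 0)
  expect_equal(length(cat0$samples),
               length(a$samples) + length(b$samples))
  bad <- structure(list(samples = numeric(10), sample_rate = 22050),
                   class = "waveform")
  expect_error(assemble_trial(a, bad), "sample rates")
})

test_that("silence regions are exactly zero and peaks bounded everywhere", {
  beats <- seq(0.5, 3, by = 0.5)
  tr <- assemble_trial(
    render_beep_track(beep_schedule(beats, "target", duration = 3.5)),
    render_beep_track(beep_schedule(beats, "lure", offset = 0.2,
                                    direction = "ahead",
                                    duration = 3.5)))
  sr <- tr$sample_rate
  gap_region <- tr$samples[(3.5 * sr + 1):(5.5 * sr)]
  expect_true(all(gap_region == 0))
  expect_lte(max(abs(tr$samples)), 1)
})

test_that("WAV files round-trip in both encodings", {
  w <- render_beep_track(beep_schedule(c(0.3, 0.8), "target",
                                       duration = 1.2),
                         sample_rate = 8000)
  for (fmt in c("pcm16", "float32")) {
    path <- withr::local_tempfile(fileext = ".wav")
    write_wav(w, path, format = fmt)
    back <- read_wav(path)
    expect_equal(back$sample_rate, 8000)
    tol <- if (fmt == "pcm16") 1 / 32767 else 1e-7
    expect_equal(back$samples, w$samples, tolerance = tol)
  }
})

test_that("annotations and tap takes round-trip through JSON", {
  takes <- list(iso_take("d1", "t1"), iso_take("d1", "t2",
                                               shift = 0.01))
  path <- withr::local_tempfile(fileext = ".json")
  write_tap_takes(takes, path)
  back <- read_tap_takes(path)
  expect_equal(back[[1]]$onsets, takes[[1]]$onsets, tolerance = 1e-12)
  expect_equal(back[[2]]$drummer_id, "d1")

  ann <- consensus_beats(takes)
  apath <- withr::local_tempfile(fileext = ".json")
  write_annotation(ann, apath)
  ann2 <- read_annotation(apath)
  expect_equal(ann2$beat_times, ann$beat_times, tolerance = 1e-12)
  expect_equal(ann2$mean_period, ann$mean_period, tolerance = 1e-12)
})
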