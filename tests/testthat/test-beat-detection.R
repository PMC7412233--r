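test_that("noiseless synthetic record is recovered peak for peak", {
  sim <- simulate_ecg(clean_config(duration_s = 60, seed = 3))
  beats <- detect_beats(sim$record)
  expect_equal(nrow(beats), nrow(sim$truth))
  # every detected peak within 2 ms of its true position
  d <- beats$time_s * 1000
  r <- sim$truth$time_s * 1000
  expect_lt(max(abs(d - r)), 2)
})

test_that("degenerate inputs give empty annotations", {
  z <- numeric(2000)
  beats <- detect_r_peaks(z, z, 1000)
  expect_equal(nrow(beats), 0)
  beats <- detect_r_peaks(numeric(0), numeric(0), 1000)
  expect_equal(nrow(beats), 0)
})

test_that("the minimum-distance rule keeps the larger of two close peaks, earlier on ties", {
  x <- numeric(1000)
  x[200] <- 0.5
  x[230] <- 0.8   # 30 ms apart at 1000 Hz, both above height
  beats <- detect_r_peaks(x, x, 1000)
  expect_equal(beats$sample, 229)  # only the larger kept (0-based)

  x2 <- numeric(1000)
  x2[400] <- 0.6
  x2[430] <- 0.6  # exact tie: earlier wins
  beats2 <- detect_r_peaks(x2, x2, 1000)
  expect_equal(beats2$sample, 399)

  # separation of exactly the minimum distance is allowed
  x3 <- numeric(1000)
  x3[300] <- 0.6
  x3[350] <- 0.6
  beats3 <- detect_r_peaks(x3, x3, 1000)
  expect_equal(nrow(beats3), 2)
})

test_that("detected peaks are strictly increasing with enforced separation", {
  sim <- simulate_ecg(sim_config(duration_s = 30, seed = 17,
                                 noise = noise_spec(0.05, 0.4, 0.15, 0.05),
                                 artifacts = artifact_spec(2)))
  beats <- detect_beats(sim$record)
  expect_true(all(diff(beats$sample) > 0))
  expect_true(all(diff(beats$sample) >= 50))  # 50 ms at 1000 Hz
})

test_that("heart rate is peak count over recording time", {
  b <- beat_annotations(seq(0, 11999) * 100, 1000)
  expect_equal(heart_rate(b, 1200), 600)
  expect_equal(heart_rate(beat_annotations(numeric(0), 1000), 60), 0)
  expect_error(heart_rate(b, 0), "positive")
})

test_that("simulated heart rate and RR statistics are recovered through the pipeline", {
  sim <- simulate_ecg(clean_config(duration_s = 120, seed = 9))
  beats <- detect_beats(sim$record)
  hr <- heart_rate(beats, 120)
  expect_lt(abs(hr - 600), 1)      # 100 ms mean RR -> 600 bpm
  rr <- rr_intervals(beats)
  expect_lt(abs(mean(rr$rr_ms) - 100) / 100, 0.01)
  expect_lt(abs(sd(rr$rr_ms) - 3) / 3, 0.10)
})

test_that("RR intervals are successive peak differences in ms", {
  rr <- rr_intervals(beat_annotations(c(0, 100, 200), 1000))
  expect_equal(rr$rr_ms, c(100, 100))
  rr <- rr_intervals(beat_annotations(c(0, 90, 210), 1000))
  expect_equal(rr$rr_ms, c(90, 120))
  expect_equal(mean(rr$rr_ms), 105)
  expect_equal(rr$anchor_sample, c(90, 210))
  expect_warning(out <- rr_intervals(beat_annotations(42, 1000)), "fewer than 2")
  expect_equal(nrow(out), 0)
})

test_that("RR histogram uses 1 ms bins and the half-maximum width rule", {
  h <- rr_histogram(rep(100.3, 25))
  expect_equal(h$fwhm_ms, 1)       # single bin
  expect_equal(sum(h$counts), 25)

  # counts 1, 10, 9, 2 in consecutive bins: half-max 5 -> bins 2..3
  rr <- c(100.5, rep(101.5, 10), rep(102.5, 9), rep(103.5, 2))
  h <- rr_histogram(rr)
  expect_equal(h$counts, c(1, 10, 9, 2))
  expect_equal(h$half_max, 5)
  expect_equal(h$fwhm_ms, 2)
  expect_equal(sum(h$counts), length(rr))

  expect_error(rr_histogram(numeric(0)), "empty")
})

test_that("FWHM tracks the analytic Gaussian width and ignores outlier tails", {
  set.seed(50)
  rr <- rnorm(1e5, 100.5, 3)
  h <- rr_histogram(rr)
  expect_lt(abs(h$fwhm_ms - 2.355 * 3) / (2.355 * 3), 0.15)

  # a single far outlier (ectopic tail) leaves the FWHM untouched
  h2 <- rr_histogram(c(rr, 250))
  expect_equal(h2$fwhm_ms, h$fwhm_ms)
  expect_equal(sum(h2$counts), 1e5 + 1)
})

test_that("tidy and glance expose histogram bins and the summary row", {
  rr <- c(100.5, rep(101.5, 10), rep(102.5, 9), rep(103.5, 2))
  h <- rr_histogram(rr)
  td <- tidy(h)
  expect_equal(nrow(td), 4)
  expect_equal(td$count, h$counts)
  expect_equal(td$at_half_max, c(FALSE, TRUE, TRUE, FALSE))
  g <- glance(h)
  expect_equal(g$fwhm_ms, 2)
  expect_equal(g$n_intervals, 22)
  s <- beat_summary(beat_annotations(c(0, 100, 200, 300), 1000), 0.4)
  expect_equal(s$n_peaks, 4)
  expect_equal(s$hr_bpm, 600)
  expect_equal(s$mean_rr_ms, 100)
  expect_equal(s$fwhm_ms, 1)
})
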