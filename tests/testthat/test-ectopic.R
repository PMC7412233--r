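# direct O(n * w) re-computation of the centred, self-excluding moving
# average, used as the oracle for the vectorised implementation
brute_moving_average <- function(rr, window = 100) {
  n <- length(rr)
  half <- floor(window / 2)
  vapply(seq_len(n), function(i) {
    k <- min(half, i - 1, n - i)
    if (k >= 1) {
      mean(rr[c((i - k):(i - 1), (i + 1):(i + k))])
    } else if (i == 1) {
      mean(rr[2:(1 + min(half, n - 1))])
    } else {
      mean(rr[(n - min(half, n - 1)):(n - 1)])
    }
  }, numeric(1))
}

test_that("moving average is the windowed mean excluding the current interval", {
  expect_equal(moving_average_rr(rep(100, 120)), rep(100, 120))

  rr <- c(rep(100, 50), 60, rep(100, 50))
  ma <- moving_average_rr(rr, 100)
  expect_equal(ma[51], 100)  # the aberrant interval does not pollute itself

  expect_error(moving_average_rr(100), "at least 2")
})

test_that("moving average equals the brute-force oracle on random series", {
  set.seed(77)
  for (n in c(5, 37, 100, 211, 500)) {
    rr <- rnorm(n, 100, 5)
    expect_equal(moving_average_rr(rr, 100), brute_moving_average(rr, 100))
    expect_equal(moving_average_rr(rr, 10), brute_moving_average(rr, 10))
  }
})

test_that("deviation threshold separates ectopic from normal intervals", {
  rr <- c(rep(100, 60), 60, rep(100, 60))   # 40% deviation
  rois <- flag_ectopic(rr)
  expect_equal(nrow(rois), 1)
  expect_equal(rois$beat_index, 62L)        # beat terminating interval 61
  expect_equal(rois$interval_ms, 60)
  expect_gt(rois$deviation_fraction, 0.30)

  rr2 <- c(rep(100, 60), 75, rep(100, 60))  # 25% deviation: below threshold
  expect_equal(nrow(flag_ectopic(rr2)), 0)

  # near-unity threshold never fires on constant data
  cfg <- ectopic_config(deviation_threshold = 0.999)
  expect_equal(nrow(flag_ectopic(rep(100, 200), cfg)), 0)
})

test_that("premature beat and compensatory pause merge into one ROI", {
  rr <- c(rep(100, 60), 60, 140, rep(100, 60))
  rois <- flag_ectopic(rr)
  expect_equal(nrow(rois), 1)
  expect_equal(rois$n_intervals, 2L)
  # the member with the largest relative deviation is reported: the 140 ms
  # pause deviates slightly more than the 60 ms premature interval because
  # its own reference window contains the 60 ms interval
  expect_equal(rois$interval_ms, 140)
  expect_equal(rois$beat_index, 62L)
})

test_that("flags are invariant under a time shift of the recording", {
  rr <- tibble::tibble(rr_ms = c(rep(100, 60), 60, 140, rep(100, 60)))
  rr$anchor_time_s <- cumsum(rr$rr_ms) / 1000
  shifted <- rr
  shifted$anchor_time_s <- rr$anchor_time_s + 3600
  a <- flag_ectopic(rr)
  b <- flag_ectopic(shifted)
  expect_equal(b$beat_index, a$beat_index)
  expect_equal(b$deviation_fraction, a$deviation_fraction)
  expect_equal(b$time_s, a$time_s + 3600)
})

test_that("every injected premature event is flagged through the full pipeline", {
  cfg <- clean_config(
    duration_s = 120, seed = 31,
    ectopic = list(ectopic_event("premature", at_s = c(20, 50, 80, 110),
                                 fraction = 0.6)))
  sim <- simulate_ecg(cfg)
  beats <- detect_beats(sim$record)
  rois <- flag_ectopic(rr_intervals(beats))
  expect_gte(nrow(rois), 4)
  true_t <- sim$truth$time_s[sim$truth$is_ectopic]
  for (t in true_t) {
    expect_true(any(abs(rois$time_s - t) < 0.15))  # within one beat
  }
})

test_that("ROI export writes the table always and panels only when flagged", {
  sim <- simulate_ecg(clean_config(
    duration_s = 60, seed = 13,
    ectopic = list(ectopic_event("premature", at_s = c(15, 30, 45),
                                 fraction = 0.6))))
  pre <- preprocess_ecg(sim$record)
  beats <- detect_r_peaks(pre$detection, pre$bandpassed, 1000)
  rois <- flag_ectopic(rr_intervals(beats))
  expect_gte(nrow(rois), 3)

  out <- withr::local_tempdir()
  paths <- export_rois(pre$bandpassed, rois, beats, out)
  csv <- read.csv(file.path(out, "rois.csv"))
  expect_equal(nrow(csv), nrow(rois))
  expect_named(csv, c("beat_index", "time_s", "interval_ms", "moving_avg_ms",
                      "deviation_fraction"))
  expect_true(file.exists(file.path(out, "rois.pdf")))

  # empty ROI set: header-only CSV, no plot file
  out2 <- withr::local_tempdir()
  none <- flag_ectopic(rep(100, 150))
  export_rois(pre$bandpassed, none, beats, out2)
  csv2 <- read.csv(file.path(out2, "rois.csv"))
  expect_equal(nrow(csv2), 0)
  expect_false(file.exists(file.path(out2, "rois.pdf")))

  # ROI near the record start is clipped to the record bounds, not an error
  early <- flag_ectopic(c(60, 140, rep(100, 120)))
  expect_no_error(export_rois(pre$bandpassed, early, beats,
                              withr::local_tempdir()))
})
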