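# O(n^2) greedy matcher over all candidate pairs, the oracle for match_peaks
brute_match <- function(det_ms, ref_ms, tol) {
  pairs <- expand.grid(i = seq_along(det_ms), j = seq_along(ref_ms))
  pairs$dt <- abs(det_ms[pairs$i] - ref_ms[pairs$j])
  pairs <- pairs[pairs$dt <= tol, ]
  pairs <- pairs[order(pairs$dt, pairs$i), ]
  used_i <- logical(length(det_ms))
  used_j <- logical(length(ref_ms))
  tp <- 0
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (!used_i[i] && !used_j[j]) {
      used_i[i] <- TRUE; used_j[j] <- TRUE; tp <- tp + 1
    }
  }
  tp
}

test_that("perfect and near-perfect detectors produce the expected counts", {
  ref <- beat_annotations(seq(100, 100 * 100, by = 100), 1000,
                          source = "reference")
  m <- match_peaks(ref, ref, tolerance_ms = 10, total_samples = 1e6)
  expect_equal(unlist(m[c("tp", "fp", "fn", "tn")]),
               c(tp = 100, fp = 0, fn = 0, tn = 999900))
  expect_equal(m$sensitivity, 1)

  # miss two reference peaks, add one spurious detection
  det <- beat_annotations(sort(c(setdiff(ref$sample, c(300, 700)), 9050)),
                          1000)
  m2 <- match_peaks(det, ref, tolerance_ms = 10, total_samples = 1.2e6)
  expect_equal(unlist(m2[c("tp", "fn", "fp", "tn")]),
               c(tp = 98, fn = 2, fp = 1, tn = 1199899))
  # count conservation
  expect_equal(m2$tp + m2$tn + m2$fp + m2$fn, 1.2e6)
})

test_that("jittered peaks within tolerance all match; matching equals the brute-force oracle", {
  set.seed(99)
  for (rep in 1:5) {
    n <- sample(50:300, 1)
    ref_ms <- cumsum(rnorm(n, 100, 3))
    jit <- ref_ms + runif(n, -9, 9)
    det <- beat_annotations(sort(round(jit)), 1000)
    ref <- beat_annotations(round(ref_ms), 1000, source = "reference")
    m <- match_peaks(det, ref, tolerance_ms = 10, total_samples = 1e6)
    expect_equal(m$tp, brute_match(det$time_s * 1000, ref$time_s * 1000, 10))
    expect_equal(m$fp + m$fn, 2 * (n - m$tp))
  }
  # all-jitter-within-tolerance gives a perfect score
  ref_ms <- seq(100, 10000, by = 100)
  det <- beat_annotations(ref_ms + sample(-8:8, length(ref_ms), TRUE), 1000)
  ref <- beat_annotations(ref_ms, 1000, source = "reference")
  m <- match_peaks(det, ref, tolerance_ms = 10, total_samples = 1e5)
  expect_equal(c(m$fp, m$fn), c(0, 0))
})

test_that("swapping detected and reference swaps FP and FN, keeping TP", {
  set.seed(7)
  a <- beat_annotations(sort(sample(1:10000, 80)), 1000)
  b <- beat_annotations(sort(sample(1:10000, 95)), 1000, source = "reference")
  m_ab <- match_peaks(a, b, tolerance_ms = 10, total_samples = 1e5)
  m_ba <- match_peaks(b, a, tolerance_ms = 10, total_samples = 1e5)
  expect_equal(m_ab$tp, m_ba$tp)
  expect_equal(m_ab$fp, m_ba$fn)
  expect_equal(m_ab$fn, m_ba$fp)
})

test_that("metric ratios match published six-decimal values and handle zero denominators", {
  expect_equal(round(compute_metrics(11780, 1188216, 2, 2)$sensitivity, 6),
               0.999830)
  expect_equal(round(compute_metrics(12413, 1187556, 16, 15)$precision, 6),
               0.998713)
  expect_equal(compute_metrics(5, 0, 0, 5)$sensitivity, 0.5)
  und <- compute_metrics(0, 100, 0, 0)
  expect_true(is.na(und$sensitivity))   # undefined, not zero
  expect_true(is.na(und$precision))
  expect_equal(und$specificity, 1)
})

test_that("mean metrics average per-file rows", {
  counts <- rpeak_benchmark()
  custom <- counts[counts$method == "custom", ]
  ev <- evaluate_counts(custom[, c("method", "file", "tp", "tn", "fp", "fn")])
  expect_equal(round(ev$means$sensitivity, 6), 0.998566)
  one <- summarize_metrics(ev$per_file[3, ])
  expect_equal(one$sensitivity, ev$per_file$sensitivity[3])
  same <- summarize_metrics(ev$per_file[c(2, 2, 2), ])
  expect_equal(same$precision, ev$per_file$precision[2])
})

test_that("paired comparison matches a direct t-distribution computation", {
  set.seed(11)
  a <- 0.99 + rnorm(10, 0, 0.002)
  b <- a - 0.001 + rnorm(10, 0, 0.001)
  res <- paired_compare(a, b)
  d <- a - b
  t_stat <- mean(d) / (sd(d) / sqrt(length(d)))
  p_ref <- 2 * pt(-abs(t_stat), length(d) - 1)
  expect_equal(res$statistic, t_stat, tolerance = 1e-10)
  expect_equal(res$p_value, p_ref, tolerance = 1e-6)

  # identical lists: zero-variance differences are undefined, not p = 1
  expect_warning(res0 <- paired_compare(a, a), "zero variance")
  expect_true(is.na(res0$p_value))

  # Wilcoxon variant runs and returns a probability
  rw <- paired_compare(a, b, method = "wilcoxon")
  expect_true(rw$p_value > 0 && rw$p_value < 1)
})

test_that("evaluating the shipped benchmark counts reproduces every published metric", {
  counts <- rpeak_benchmark()
  ev <- evaluate_counts(counts[, c("method", "file", "tp", "tn", "fp", "fn")])
  expect_equal(round(ev$per_file$sensitivity, 6), counts$sensitivity)
  expect_equal(round(ev$per_file$precision, 6), counts$precision)
  expect_equal(round(ev$per_file$specificity, 6), counts$specificity)
  expect_s3_class(tidy(ev), "tbl_df")
  g <- glance(ev)
  expect_true(all(c("p_sensitivity", "p_precision", "p_specificity") %in%
                    names(g)))
})

test_that("run_evaluation assembles per-file reports with paired comparison", {
  set.seed(5)
  refs <- lapply(1:3, function(i) {
    beat_annotations(sort(sample(1:60000, 500)), 1000, source = "reference")
  })
  dets <- lapply(refs, identity)
  alt <- lapply(seq_along(refs), function(i) {
    kept <- refs[[i]]$sample[-seq(1, 5 + 3 * i)]
    spurious <- 59000 + 25 * seq_len(2 + 2 * i)
    # keep only spurious peaks clearly outside the matching tolerance
    near_ref <- vapply(spurious, function(s) {
      min(abs(refs[[i]]$sample - s)) <= 10
    }, logical(1))
    beat_annotations(sort(union(kept, spurious[!near_ref])), 1000)
  })
  ev <- run_evaluation(dets, refs, total_samples = 60000, detected_b = alt)
  expect_equal(nrow(ev$per_file), 6)
  expect_true(all(ev$per_file$sensitivity[1:3] == 1))
  expect_true(all(ev$per_file$sensitivity[4:6] < 1))
  expect_false(is.null(ev$comparison))
})
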