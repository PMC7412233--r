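#' Match detected peaks against reference annotations
#'
#' One-to-one nearest-neighbour matching: candidate pairs within the time
#' tolerance are taken greedily by increasing absolute time difference, each
#' peak matched at most once. Matched detections are true positives,
#' unmatched detections false positives, unmatched reference peaks false
#' negatives. True negatives are counted at the sample level — every
#' evaluated sample holding no peak — so `tp + tn + fp + fn = total_samples`.
#'
#' @param detected,reference `beat_tbl` annotation sets (each may have its
#'   own sampling rate; matching is done in time).
#' @param tolerance_ms Match tolerance in ms (default 10, about one murine
#'   QRS width).
#' @param total_samples Number of evaluated samples (defines the
#'   sample-level true-negative count); e.g. 1,200,000 for a 20-min
#'   fragment at 1000 Hz.
#' @return One-row tibble: `tp`, `tn`, `fp`, `fn`, `sensitivity`,
#'   `precision`, `specificity`.
#' @examples
#' ref <- beat_annotations(c(100, 200, 300), 1000, source = "reference")
#' det <- beat_annotations(c(101, 200, 299, 350), 1000)
#' match_peaks(det, ref, tolerance_ms = 10, total_samples = 1000)
#' @export
match_peaks <- function(detected, reference, tolerance_ms = 10,
                        total_samples) {
  if (tolerance_ms <= 0) abort("`tolerance_ms` must be positive")
  td <- detected$time_s * 1000
  tr <- reference$time_s * 1000
  nd <- length(td)
  nr <- length(tr)
  pairs <- NULL
  if (nd > 0 && nr > 0) {
    # candidate pairs: each detection against its bracketing references
    lo <- findInterval(td, tr)
    cand <- unique(rbind(
      cbind(seq_len(nd), pmax(lo, 1L)),
      cbind(seq_len(nd), pmin(lo + 1L, nr))
    ))
    dt <- abs(td[cand[, 1]] - tr[cand[, 2]])
    ok <- dt <= tolerance_ms
    cand <- cand[ok, , drop = FALSE]
    dt <- dt[ok]
    ord <- order(dt, cand[, 1])
    used_d <- logical(nd)
    used_r <- logical(nr)
    tp <- 0L
    for (k in ord) {
      i <- cand[k, 1]
      j <- cand[k, 2]
      if (!used_d[i] && !used_r[j]) {
        used_d[i] <- TRUE
        used_r[j] <- TRUE
        tp <- tp + 1L
      }
    }
  } else {
    tp <- 0L
  }
  fp <- nd - tp
  fn <- nr - tp
  tn <- total_samples - tp - fp - fn
  if (tn < 0) abort("`total_samples` smaller than the number of peaks")
  cbind(tibble(tp = tp, tn = tn, fp = fp, fn = fn),
        compute_metrics(tp, tn, fp, fn))
}

#' Sensitivity, precision and specificity from counts
#'
#' The three detector-evaluation ratios:
#' sensitivity `tp / (tp + fn)`, precision `tp / (tp + fp)`, specificity
#' `tn / (tn + fp)`. A zero denominator yields `NA` (undefined), never 0.
#' Vectorised over rows of counts.
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return Tibble with `sensitivity`, `precision`, `specificity`.
#' @examples
#' compute_metrics(11780, 1188216, 2, 2)
#' @export
compute_metrics <- function(tp, tn, fp, fn) {
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  tibble(
    sensitivity = ratio(tp, tp + fn),
    precision = ratio(tp, tp + fp),
    specificity = ratio(tn, tn + fp)
  )
}

#' Mean metrics over evaluated files
#'
#' Arithmetic mean of per-file sensitivity, precision and specificity.
#'
#' @param per_file A tibble with columns `sensitivity`, `precision`,
#'   `specificity` (one row per file).
#' @return One-row tibble of means.
#' @export
summarize_metrics <- function(per_file) {
  if (nrow(per_file) == 0) abort("no per-file metrics to summarise")
  tibble(
    sensitivity = mean(per_file$sensitivity),
    precision = mean(per_file$precision),
    specificity = mean(per_file$specificity)
  )
}

#' Paired comparison of two detectors
#'
#' Two-sided paired test on per-file metric values. The default is the
#' paired t-test; a Wilcoxon signed-rank alternative is available. With
#' zero variance of the differences the statistic is undefined and `NA` is
#' returned (with a warning) rather than a fabricated p-value.
#'
#' @param metrics_a,metrics_b Tibbles of per-file metrics (same files, same
#'   order, >= 2 rows) with columns `sensitivity`, `precision`,
#'   `specificity` — or plain numeric vectors for a single metric.
#' @param method `"t"` (default) or `"wilcoxon"`.
#' @return Tibble with `metric`, `statistic`, `p_value`.
#' @examples
#' a <- tibble::tibble(sensitivity = c(.99, .98, .97),
#'                     precision = c(.99, .99, .98),
#'                     specificity = c(1, 1, 1))
#' b <- a
#' b$sensitivity <- b$sensitivity - c(.002, .001, .003)
#' paired_compare(a, b)
#' @export
paired_compare <- function(metrics_a, metrics_b, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  if (is.numeric(metrics_a)) metrics_a <- tibble(value = metrics_a)
  if (is.numeric(metrics_b)) metrics_b <- tibble(value = metrics_b)
  cols <- intersect(c("sensitivity", "precision", "specificity", "value"),
                    intersect(names(metrics_a), names(metrics_b)))
  if (length(cols) == 0) abort("no shared metric columns to compare")
  if (nrow(metrics_a) != nrow(metrics_b)) {
    abort("paired comparison needs equal numbers of files")
  }
  if (nrow(metrics_a) < 2) abort("paired comparison needs >= 2 files")
  one <- function(metric) {
    a <- metrics_a[[metric]]
    b <- metrics_b[[metric]]
    d <- a - b
    if (sd(d) == 0) {
      warn(sprintf("zero variance of paired differences for %s", metric))
      return(tibble(metric = metric, statistic = NA_real_,
                    p_value = NA_real_))
    }
    ht <- if (method == "t") {
      t.test(a, b, paired = TRUE)
    } else {
      suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE))
    }
    tibble(metric = metric, statistic = unname(ht$statistic),
           p_value = ht$p.value)
  }
  dplyr::bind_rows(lapply(cols, one))
}

#' Evaluate a table of raw detection counts
#'
#' Computes the three metrics for each row of a per-file count table (for
#' example a published benchmark table), plus per-method means and — when
#' exactly two methods share the same files — a paired comparison per
#' metric.
#'
#' @param counts A data frame with columns `file`, `tp`, `tn`, `fp`, `fn`
#'   and optionally `method`.
#' @param method Passed to [paired_compare()].
#' @return An object of class `ecg_eval`: list with `per_file`, `means`
#'   (per method) and `comparison` (or `NULL`).
#' @export
evaluate_counts <- function(counts, method = c("t", "wilcoxon")) {
  counts <- as_tibble(counts)
  if (!"method" %in% names(counts)) counts$method <- "detector"
  per_file <- cbind(counts,
                    compute_metrics(counts$tp, counts$tn, counts$fp,
                                    counts$fn))
  per_file <- as_tibble(per_file)
  means <- dplyr::summarise(
    dplyr::group_by(per_file, .data$method),
    dplyr::across(c("sensitivity", "precision", "specificity"), mean),
    .groups = "drop"
  )
  comparison <- NULL
  methods <- unique(per_file$method)
  if (length(methods) == 2) {
    a <- per_file[per_file$method == methods[1], ]
    b <- per_file[per_file$method == methods[2], ]
    if (nrow(a) == nrow(b) && all(a$file == b$file)) {
      comparison <- paired_compare(a, b, method = method)
    }
  }
  structure(list(per_file = per_file, means = means,
                 comparison = comparison), class = "ecg_eval")
}

#' Evaluate detector annotation sets against references
#'
#' Runs [match_peaks()] per file and assembles the standard evaluation
#' report: per-file counts and metrics, the mean row, and — if a second
#' detector's annotations are given — a paired comparison.
#'
#' @param detected A list of `beat_tbl` (one per file).
#' @param reference A list of reference `beat_tbl`, same length and order.
#' @param total_samples Evaluated samples per file (scalar or vector).
#' @param tolerance_ms Match tolerance in ms.
#' @param detected_b Optional second detector's annotations for paired
#'   comparison.
#' @param files Optional file labels.
#' @return An `ecg_eval` object.
#' @export
run_evaluation <- function(detected, reference, total_samples,
                           tolerance_ms = 10, detected_b = NULL,
                           files = NULL) {
  n <- length(detected)
  if (length(reference) != n) abort("one reference set per detected set")
  total_samples <- rep_len(total_samples, n)
  files <- files %||% sprintf("%03d", seq_len(n))
  eval_one <- function(dets, label) {
    rows <- lapply(seq_len(n), function(i) {
      cbind(tibble(method = label, file = files[i]),
            match_peaks(dets[[i]], reference[[i]], tolerance_ms,
                        total_samples[i]))
    })
    as_tibble(dplyr::bind_rows(rows))
  }
  per_file <- eval_one(detected, "detector_a")
  if (!is.null(detected_b)) {
    per_file <- dplyr::bind_rows(per_file, eval_one(detected_b, "detector_b"))
  }
  evaluate_counts(per_file[, c("method", "file", "tp", "tn", "fp", "fn")])
}

#' @export
print.ecg_eval <- function(x, ...) {
  cat("# R-peak detector evaluation\n")
  print(x$per_file)
  cat("# Mean values\n")
  print(x$means)
  if (!is.null(x$comparison)) {
    cat("# Paired comparison (two-sided)\n")
    print(x$comparison)
  }
  invisible(x)
}

#' Tidy detector-evaluation results
#'
#' `tidy()` returns the per-file counts and metrics; `glance()` the
#' per-method mean metrics, with paired-comparison p-values appended when a
#' comparison was made.
#'
#' @param x An `ecg_eval` from [evaluate_counts()] or [run_evaluation()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ecg_eval <- function(x, ...) x$per_file

#' @rdname tidy.ecg_eval
#' @export
glance.ecg_eval <- function(x, ...) {
  out <- x$means
  if (!is.null(x$comparison)) {
    p <- x$comparison$p_value
    names(p) <- paste0("p_", x$comparison$metric)
    out <- cbind(out[1, setdiff(names(out), "method"), drop = FALSE],
                 as_tibble(as.list(p)))
    out <- as_tibble(out)
  }
  out
}

#' Sensitivity across sampling rates
#'
#' Re-runs the full pre-processing and detection chain on one record at
#' several working rates and evaluates each against the reference
#' annotations — the harness used to pick a down-sampling rate that
#' balances computational load against detection performance.
#'
#' @param record An `ecg_tbl` at the source rate (e.g. 2000 Hz).
#' @param reference Reference `beat_tbl` (any rate; matching is in time).
#' @param rates Working rates in Hz; each must divide the source rate.
#' @param lead Lead to analyse.
#' @param pre,config,tolerance_ms Chain parameters.
#' @return Tibble with one row per rate: `rate_hz`, `tp`, `fp`, `fn`,
#'   `sensitivity`, `precision`.
#' @export
sweep_sample_rates <- function(record, reference,
                               rates = c(2000, 1000, 500, 400, 250),
                               lead = "II", pre = preprocess_config(),
                               config = detection_config(),
                               tolerance_ms = 10) {
  rows <- lapply(rates, function(r) {
    p <- pre
    p$target_rate_hz <- r
    beats <- suppressWarnings(
      detect_beats(record, lead = lead, pre = p, config = config))
    m <- match_peaks(beats, reference, tolerance_ms,
                     total_samples = round(duration_s(record) * r))
    cbind(tibble(rate_hz = r), m[, c("tp", "fp", "fn", "sensitivity",
                                     "precision")])
  })
  as_tibble(dplyr::bind_rows(rows))
}
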