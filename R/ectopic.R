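#' Ectopic-detection configuration
#'
#' Beats are flagged when their RR interval deviates from a local moving
#' average by more than a threshold fraction. The 100-interval window and
#' 30% threshold defaults were chosen to trigger on genuine ectopy without
#' firing inside the normal range of sinus variability.
#'
#' @param window_intervals Sliding-window length in intervals (default 100,
#'   minimum 2), applied as 50 before + 50 after the index interval.
#' @param deviation_threshold Flagging threshold as a fraction of the
#'   moving average (default 0.30), in (0, 1).
#' @param roi_halfwidth_ms Half-width of the exported review window in ms
#'   (default 500).
#' @return A list of class `ectopic_config`.
#' @export
ectopic_config <- function(window_intervals = 100,
                           deviation_threshold = 0.30,
                           roi_halfwidth_ms = 500) {
  if (window_intervals < 2) abort("`window_intervals` must be >= 2")
  if (deviation_threshold <= 0 || deviation_threshold >= 1) {
    abort("`deviation_threshold` must lie in (0, 1)")
  }
  structure(list(window_intervals = window_intervals,
                 deviation_threshold = deviation_threshold,
                 roi_halfwidth_ms = roi_halfwidth_ms),
            class = "ectopic_config")
}

#' Moving average of RR intervals
#'
#' For interval `i` the reference is the mean of up to `window` intervals
#' centred on `i` and excluding `i` itself (half the window before, half
#' after), so an aberrant interval never pollutes its own reference. The
#' window shrinks symmetrically where it meets a series edge; at the two
#' endpoints, where no symmetric window exists, the available one-sided
#' neighbours (up to half a window) are used.
#'
#' @param rr Numeric RR intervals in ms, or the tibble from
#'   [rr_intervals()].
#' @param window Window length in intervals (default 100).
#' @return Numeric vector of local means, one per interval.
#' @examples
#' moving_average_rr(c(rep(100, 50), 60, rep(100, 50)))[51]  # 100: self excluded
#' @export
moving_average_rr <- function(rr, window = 100) {
  if (is.data.frame(rr)) rr <- rr$rr_ms
  n <- length(rr)
  if (n < 2) abort("RR series must contain at least 2 intervals")
  half <- floor(window / 2)
  cs <- c(0, cumsum(rr))
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- min(half, i - 1, n - i)
    if (k >= 1) {
      out[i] <- (cs[i + k + 1] - cs[i - k] - rr[i]) / (2 * k)
    } else {
      # endpoint: one-sided fallback over the nearest available neighbours
      if (i == 1) {
        m <- min(half, n - 1)
        out[i] <- mean(rr[2:(1 + m)])
      } else {
        m <- min(half, n - 1)
        out[i] <- mean(rr[(n - m):(n - 1)])
      }
    }
  }
  out
}

#' Flag ectopic beats from deviating RR intervals
#'
#' Every interval whose absolute deviation from its moving average exceeds
#' the threshold fraction yields a region of interest (ROI) anchored at the
#' terminating peak. A premature beat and its compensatory pause both
#' deviate and share a beat, so runs of consecutive flagged intervals are
#' merged into a single ROI (anchored at the first flagged beat of the run,
#' reporting the largest deviation) to avoid double-reporting one event.
#'
#' @param rr The tibble from [rr_intervals()] (columns `rr_ms`,
#'   `anchor_time_s`; `anchor_sample` if available), or a numeric vector of
#'   intervals in ms (anchor times then assume consecutive intervals from
#'   time 0).
#' @param config An [ectopic_config()].
#' @return A tibble of class `ectopic_roi`: `beat_index` (1-based beat
#'   ordinal of the anchoring peak, where beat `i + 1` terminates interval
#'   `i`), `time_s`, `interval_ms`, `moving_avg_ms`, `deviation_fraction`,
#'   `n_intervals` (merged run length), `window_start_s`, `window_end_s`.
#' @examples
#' rr <- c(rep(100, 60), 60, 140, rep(100, 60))
#' flag_ectopic(rr)
#' @export
flag_ectopic <- function(rr, config = ectopic_config()) {
  if (!is.data.frame(rr)) {
    rr <- tibble(rr_ms = as.numeric(rr),
                 anchor_time_s = cumsum(as.numeric(rr)) / 1000)
  }
  stopifnot(all(c("rr_ms", "anchor_time_s") %in% names(rr)))
  empty <- tibble(
    beat_index = integer(0), time_s = numeric(0), interval_ms = numeric(0),
    moving_avg_ms = numeric(0), deviation_fraction = numeric(0),
    n_intervals = integer(0), window_start_s = numeric(0),
    window_end_s = numeric(0)
  )
  class(empty) <- c("ectopic_roi", class(empty))
  if (nrow(rr) < 2) return(empty)
  ma <- moving_average_rr(rr$rr_ms, config$window_intervals)
  dev <- abs(rr$rr_ms - ma) / ma
  hit <- which(dev > config$deviation_threshold)
  if (length(hit) == 0) return(empty)
  run <- cumsum(c(1, diff(hit) > 1))
  half_s <- config$roi_halfwidth_ms / 1000
  rois <- lapply(split(hit, run), function(ix) {
    top <- ix[which.max(dev[ix])]
    anchor <- ix[1]
    tibble(
      beat_index = anchor + 1L,           # beat i + 1 terminates interval i
      time_s = rr$anchor_time_s[anchor],
      interval_ms = rr$rr_ms[top],
      moving_avg_ms = ma[top],
      deviation_fraction = dev[top],
      n_intervals = length(ix),
      window_start_s = min(rr$anchor_time_s[ix]) - half_s,
      window_end_s = max(rr$anchor_time_s[ix]) + half_s
    )
  })
  out <- dplyr::bind_rows(rois)
  out <- out[order(out$time_s), ]
  class(out) <- c("ectopic_roi", class(out))
  out
}

#' Export ectopic regions of interest for manual review
#'
#' Writes a machine-readable ROI table (`rois.csv`, always, with header
#' even when empty) and, when any ROI exists, a multi-page PDF
#' (`rois.pdf`) plotting the band-passed trace around each flagged beat
#' with detected peaks marked, for manual classification of the event
#' (PVC, PAC, blocked P, sinus arrest) on the original trace. Windows are
#' clipped to the record bounds.
#'
#' @param record The band-passed `ecg_tbl` to plot.
#' @param rois The tibble from [flag_ectopic()].
#' @param beats Detected `beat_tbl` (peak markers).
#' @param out_dir Output directory (created if needed).
#' @param lead Lead to plot.
#' @param pdf Write the PDF panel file (default `TRUE`).
#' @return Invisibly, the paths written.
#' @export
export_rois <- function(record, rois, beats, out_dir, lead = "II",
                        pdf = TRUE) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", out_dir))
  }
  csv_path <- file.path(out_dir, "rois.csv")
  out_cols <- c("beat_index", "time_s", "interval_ms", "moving_avg_ms",
                "deviation_fraction")
  write.csv(as.data.frame(rois)[, out_cols, drop = FALSE], csv_path,
            row.names = FALSE)
  paths <- csv_path
  if (nrow(rois) > 0 && pdf) {
    pdf_path <- file.path(out_dir, "rois.pdf")
    grDevices::pdf(pdf_path, width = 8, height = 3.5)
    on.exit(grDevices::dev.off(), add = TRUE)
    for (k in seq_len(nrow(rois))) {
      print(roi_panel(record, rois[k, ], beats, lead = lead))
    }
    paths <- c(paths, pdf_path)
  }
  invisible(paths)
}

roi_panel <- function(record, roi, beats, lead = "II") {
  t0 <- max(min(record$time_s), roi$window_start_s)
  t1 <- min(max(record$time_s), roi$window_end_s)
  seg <- record[record$time_s >= t0 & record$time_s <= t1, ]
  pk <- beats[beats$time_s >= t0 & beats$time_s <= t1, ]
  pk$amp <- seg[[lead]][findInterval(pk$time_s, seg$time_s)]
  ggplot(seg, aes(x = .data$time_s, y = .data[[lead]])) +
    geom_line(linewidth = 0.3) +
    geom_point(data = pk, aes(x = .data$time_s, y = .data$amp),
               colour = "blue", size = 1.2) +
    geom_vline(xintercept = roi$time_s, colour = "red",
               linetype = "dashed") +
    labs(
      title = sprintf(
        "ROI at %.2f s: RR %.1f ms vs local mean %.1f ms (%.0f%% deviation)",
        roi$time_s, roi$interval_ms, roi$moving_avg_ms,
        100 * roi$deviation_fraction),
      x = "time (s)", y = sprintf("lead %s (mV)", lead)) +
    theme_minimal()
}
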