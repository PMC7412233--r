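#' Plot an ECG trace with detected beats
#'
#' Line plot of one or more leads over an optional time window, with
#' detected R peaks overlaid as blue points.
#'
#' @param record An `ecg_tbl`.
#' @param beats Optional `beat_tbl` of peaks to mark.
#' @param leads Leads to draw (default: all).
#' @param from,to Optional time window in seconds.
#' @return A ggplot object.
#' @export
plot_ecg <- function(record, beats = NULL, leads = NULL, from = NULL,
                     to = NULL) {
  leads <- leads %||% lead_names(record)
  seg <- record
  if (!is.null(from)) seg <- seg[seg$time_s >= from, ]
  if (!is.null(to)) seg <- seg[seg$time_s <= to, ]
  long <- tidyr_longer(seg, leads)
  p <- ggplot(long, aes(x = .data$time_s, y = .data$amplitude_mv)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~lead, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = "amplitude (mV)") +
    theme_minimal()
  if (!is.null(beats) && nrow(beats) > 0) {
    pk <- beats
    if (!is.null(from)) pk <- pk[pk$time_s >= from, ]
    if (!is.null(to)) pk <- pk[pk$time_s <= to, ]
    if (nrow(pk) > 0) {
      marks <- dplyr::bind_rows(lapply(leads, function(ld) {
        tibble(time_s = pk$time_s, lead = ld,
               amplitude_mv = seg[[ld]][pmax(
                 1, findInterval(pk$time_s, seg$time_s))])
      }))
      p <- p + geom_point(data = marks, colour = "blue", size = 1)
    }
  }
  p
}

# minimal wide-to-long for lead columns (avoids a tidyr dependency)
tidyr_longer <- function(seg, leads) {
  dplyr::bind_rows(lapply(leads, function(ld) {
    tibble(time_s = seg$time_s, lead = factor(ld, levels = leads),
           amplitude_mv = seg[[ld]])
  }))
}

#' Plot an RR-interval histogram with its half-maximum level
#'
#' Mirrors the standard heart-rate-variability panel: 1 ms bins, a red line
#' at half the maximum count, and the mean RR and FWHM in the title.
#'
#' @param object An `rr_hist` from [rr_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rr_hist <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$bin_left_ms + 0.5, y = .data$count)) +
    geom_col(width = 1, fill = "grey40") +
    geom_hline(yintercept = object$half_max, colour = "red") +
    labs(
      title = sprintf("Mean RR %.1f ms, FWHM %g ms", object$mean_rr_ms,
                      object$fwhm_ms),
      x = "RR interval (ms)", y = "count") +
    theme_minimal()
}

#' @export
plot.rr_hist <- function(x, ...) print(autoplot.rr_hist(x, ...))
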