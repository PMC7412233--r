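#' Pre-processing configuration
#'
#' Defaults follow the murine QRS-isolation chain: a 2nd-order 5 Hz
#' zero-phase Butterworth high-pass (removes baseline wander and respiratory
#' drift), decimation to 1000 Hz, a hard FFT band-pass at 100-200 Hz (the
#' murine QRS frequency band at that rate), and a zero-phase derivative.
#'
#' @param hpf_cutoff_hz High-pass cut-off in Hz (default 5).
#' @param hpf_order Butterworth order (default 2).
#' @param target_rate_hz Working rate after decimation (default 1000); must
#'   divide the source rate.
#' @param bp_low_hz,bp_high_hz Band-pass corner frequencies in Hz (defaults
#'   100 and 200). Fixed in Hz, not rescaled with the sampling rate; if the
#'   upper corner exceeds Nyquist it is clipped with a warning.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(hpf_cutoff_hz = 5, hpf_order = 2,
                              target_rate_hz = 1000,
                              bp_low_hz = 100, bp_high_hz = 200) {
  if (!(hpf_cutoff_hz > 0 && hpf_cutoff_hz < bp_low_hz &&
        bp_low_hz < bp_high_hz)) {
    abort("need 0 < hpf_cutoff_hz < bp_low_hz < bp_high_hz")
  }
  structure(list(hpf_cutoff_hz = hpf_cutoff_hz, hpf_order = hpf_order,
                 target_rate_hz = target_rate_hz,
                 bp_low_hz = bp_low_hz, bp_high_hz = bp_high_hz),
            class = "preprocess_config")
}

# one IIR pass initialised at steady state for a constant input x0: past
# inputs are x0, past outputs the DC response to x0, so a step sees no
# start-up transient
apply_iir <- function(b, a, x, x0) {
  h1 <- sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x0, length(b) - 1),
                            init.y = rep(h1 * x0, length(a) - 1)))
}

# forward-backward IIR filtering with odd (point-reflected) edge padding of
# 3 x filter order and steady-state initialisation: zero phase, no
# start-up transient, output length = input length
zero_phase_filter <- function(b, a, x) {
  order <- max(length(a), length(b)) - 1
  padlen <- 3 * order
  n <- length(x)
  if (n <= padlen) {
    abort(sprintf("signal shorter than filter warm-up (%d samples)", padlen))
  }
  ext <- c(2 * x[1] - x[(padlen + 1):2], x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  y <- apply_iir(b, a, ext, ext[1])
  y <- rev(apply_iir(b, a, rev(y), y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}

#' Zero-phase Butterworth high-pass filter
#'
#' Forward-backward application of a Butterworth high-pass: the two passes
#' cancel the phase response, so waveform features (in particular R peaks)
#' keep their exact temporal position while DC and slow baseline components
#' are removed.
#'
#' @param x Numeric signal (mV).
#' @param rate Sampling rate in Hz; must exceed twice the cut-off.
#' @param cutoff_hz,order Filter cut-off (Hz) and order; defaults from
#'   [preprocess_config()].
#' @return Filtered signal, same length as `x`.
#' @examples
#' y <- highpass_zero_phase(rep(1, 1000) , rate = 1000)
#' max(abs(y)) < 1e-6   # DC fully rejected
#' @export
highpass_zero_phase <- function(x, rate, cutoff_hz = 5, order = 2) {
  if (rate <= 2 * cutoff_hz) abort("sampling rate must exceed 2 x cutoff")
  bf <- signal::butter(order, cutoff_hz / (rate / 2), type = "high")
  zero_phase_filter(bf$b, bf$a, x)
}

#' Decimate a signal by an integer factor
#'
#' Keeps every `rate / target_rate`-th sample (plain decimation). No
#' separate anti-aliasing filter is applied: in this chain the subsequent
#' hard band-pass bounds the aliased energy reaching detection.
#'
#' @param x Numeric signal.
#' @param rate Source sampling rate in Hz.
#' @param target_rate Target rate in Hz; must divide `rate` exactly.
#' @return A list with `x` (length `ceiling(n / factor)`) and `rate`.
#' @export
downsample_signal <- function(x, rate, target_rate) {
  factor <- rate / target_rate
  if (abs(factor - round(factor)) > 1e-9) {
    abort("`target_rate` must divide `rate` (integer decimation factor)")
  }
  factor <- as.integer(round(factor))
  list(x = x[seq(1, length(x), by = factor)], rate = target_rate)
}

#' Hard FFT band-pass filter
#'
#' Transforms to the frequency domain, zeroes every bin whose (folded)
#' frequency lies outside `[low, high]`, and transforms back. The brick-wall
#' mask makes the operation exactly idempotent. An upper corner above
#' Nyquist is clipped to Nyquist with a warning, so the same 100-200 Hz
#' corners remain usable at low sampling rates.
#'
#' @param x Numeric signal.
#' @param rate Sampling rate in Hz.
#' @param low,high Pass-band corners in Hz (`low < high`, `low` below
#'   Nyquist).
#' @param warn_clip Warn when `high` is clipped to Nyquist (default `TRUE`).
#' @return Filtered signal, same length.
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' x <- sin(2 * pi * 50 * t) + sin(2 * pi * 150 * t)
#' y <- fft_bandpass(x, 1000, 100, 200)   # keeps only the 150 Hz tone
#' @export
fft_bandpass <- function(x, rate, low, high, warn_clip = TRUE) {
  n <- length(x)
  if (n == 0) abort("empty signal")
  nyq <- rate / 2
  if (!(low < high)) abort("`low` must be below `high`")
  if (low >= nyq) abort("`low` must be below Nyquist")
  if (high > nyq) {
    if (warn_clip) {
      warn(sprintf("band-pass upper corner %g Hz above Nyquist %g Hz; clipped",
                   high, nyq))
    }
    high <- nyq
  }
  f <- (seq_len(n) - 1) * rate / n
  folded <- pmin(f, rate - f)
  keep <- folded >= low & folded <= high
  Re(fft(fft(x) * keep, inverse = TRUE)) / n
}

#' Zero-phase derivative filter
#'
#' Central difference `(x[i+1] - x[i-1]) * rate / 2` with replicated edges.
#' The symmetric kernel has exactly zero phase, so the derivative's features
#' stay aligned with the input; output units are mV/s.
#'
#' @param x Numeric signal (length >= 3).
#' @param rate Sampling rate in Hz.
#' @return Derivative signal, same length as `x`.
#' @export
derivative_zero_phase <- function(x, rate) {
  n <- length(x)
  if (n < 3) abort("signal must have at least 3 samples")
  d <- c(0, (x[3:n] - x[1:(n - 2)]) * rate / 2, 0)
  d[1] <- d[2]
  d[n] <- d[n - 1]
  d
}

#' Run the full pre-processing chain on a record
#'
#' Applies, per lead and in order: zero-phase high-pass (at the source
#' rate), decimation to the working rate, hard FFT band-pass, and the
#' zero-phase derivative. Returns both the band-passed record (for display
#' and for peak-position refinement) and the detection record fed to the
#' R-peak detector. The detection trace is the zero-phase half central
#' difference of the band-passed trace — the derivative rescaled to mV per
#' sample — so the peak-height threshold of [detection_config()] is stated
#' in plain mV regardless of the working rate.
#'
#' @param record An `ecg_tbl`.
#' @param config A [preprocess_config()].
#' @return A list with `bandpassed` and `detection`, both `ecg_tbl` at the
#'   working rate.
#' @examples
#' sim <- simulate_ecg(sim_config(duration_s = 5, seed = 2))
#' pre <- preprocess_ecg(sim$record)
#' pre$detection
#' @export
preprocess_ecg <- function(record, config = preprocess_config()) {
  stopifnot(inherits(record, "ecg_tbl"), inherits(config, "preprocess_config"))
  rate <- sample_rate(record)
  leads <- lead_names(record)
  bp <- list()
  det <- list()
  new_rate <- config$target_rate_hz
  for (ld in leads) {
    x <- highpass_zero_phase(record[[ld]], rate,
                             cutoff_hz = config$hpf_cutoff_hz,
                             order = config$hpf_order)
    ds <- if (rate == new_rate) list(x = x, rate = rate) else {
      downsample_signal(x, rate, new_rate)
    }
    b <- fft_bandpass(ds$x, ds$rate, config$bp_low_hz, config$bp_high_hz)
    bp[[ld]] <- b
    # detection trace: zero-phase half central difference (x[i+1] - x[i-1])/2,
    # i.e. the derivative rescaled to plain mV per sample, so the mV
    # peak-height threshold of detection_config() applies directly
    det[[ld]] <- derivative_zero_phase(b, ds$rate) / (2 * ds$rate)
  }
  start_s <- attr(record, "start_s") %||% 0
  list(
    bandpassed = ecg_record(bp, new_rate, start_s = start_s),
    detection = ecg_record(det, new_rate, start_s = start_s)
  )
}
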