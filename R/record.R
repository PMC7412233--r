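#' Construct a multi-lead ECG record
#'
#' An ECG record is a tibble with a `time_s` column and one numeric column
#' per lead (amplitudes in mV), carrying the sampling rate and fragment
#' metadata as attributes. All package stages consume and return this shape,
#' so records chain with the pipe.
#'
#' @param signals A named list or data frame of equal-length numeric vectors,
#'   one per lead, amplitudes in mV. Conventional murine limb leads are named
#'   `"I"`, `"II"`, `"III"`.
#' @param sample_rate Sampling rate in Hz (positive scalar).
#' @param lead_labels Optional character vector overriding `names(signals)`.
#' @param start_s Time offset of the first sample in seconds (default 0).
#' @param partial Logical flag marking an incomplete trailing fragment
#'   produced by [segment_ecg()].
#'
#' @return A tibble of class `ecg_tbl` with columns `time_s` and one column
#'   per lead; attributes `sample_rate`, `start_s`, `partial`.
#' @examples
#' rec <- ecg_record(list(I = rnorm(2000, sd = 0.05),
#'                        II = rnorm(2000, sd = 0.05)), sample_rate = 2000)
#' sample_rate(rec)
#' lead_names(rec)
#' @export
ecg_record <- function(signals, sample_rate, lead_labels = NULL,
                       start_s = 0, partial = FALSE) {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    abort("`sample_rate` must be a single positive number (Hz).")
  }
  signals <- as.list(signals)
  if (length(signals) == 0) abort("at least one lead is required")
  lens <- lengths(signals)
  if (length(unique(lens)) != 1) {
    abort("ragged channels: all leads must have equal length")
  }
  if (!all(vapply(signals, is.numeric, logical(1)))) {
    abort("all leads must be numeric (amplitude in mV)")
  }
  labels <- lead_labels %||% names(signals)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- paste0("V", seq_along(signals))
  }
  names(signals) <- labels
  n <- lens[[1]]
  out <- new_tibble(
    c(list(time_s = start_s + (seq_len(n) - 1) / sample_rate), signals),
    nrow = n,
    class = "ecg_tbl"
  )
  attr(out, "sample_rate") <- as.numeric(sample_rate)
  attr(out, "start_s") <- as.numeric(start_s)
  attr(out, "partial") <- isTRUE(partial)
  out
}

#' Record accessors
#'
#' Small helpers reading record metadata: sampling rate (Hz), lead names
#' (every column except `time_s`), and duration in seconds.
#'
#' @param x An `ecg_tbl` record (or, for `sample_rate()`, a beat-annotation
#'   tibble).
#' @return `sample_rate()` a number in Hz; `lead_names()` a character vector;
#'   `duration_s()` seconds spanned by the samples.
#' @export
sample_rate <- function(x) {
  r <- attr(x, "sample_rate")
  if (is.null(r)) abort("object carries no `sample_rate` attribute")
  r
}

#' @rdname sample_rate
#' @export
lead_names <- function(x) setdiff(names(x), "time_s")

#' @rdname sample_rate
#' @export
duration_s <- function(x) nrow(x) / sample_rate(x)

#' @export
print.ecg_tbl <- function(x, ...) {
  cat(sprintf("# ECG record: %d samples @ %g Hz (%.1f s), leads: %s%s\n",
              nrow(x), sample_rate(x), duration_s(x),
              paste(lead_names(x), collapse = ", "),
              if (isTRUE(attr(x, "partial"))) " [partial fragment]" else ""))
  NextMethod()
}

lead_matrix <- function(record) {
  as.matrix(record[lead_names(record)])
}

#' Beat annotations
#'
#' An ordered set of R-peak positions. Sample indices are 0-based (sample 0
#' is the first sample of the record), the convention also used in the
#' annotation text files, and must be strictly increasing.
#'
#' @param sample Integer vector of 0-based sample indices, strictly
#'   increasing.
#' @param sample_rate Sampling rate in Hz the indices refer to.
#' @param source `"detected"` or `"reference"`.
#' @return A tibble of class `beat_tbl` with columns `beat` (1-based ordinal),
#'   `sample` (0-based index) and `time_s`; attributes `sample_rate`,
#'   `source`.
#' @examples
#' beat_annotations(c(0, 200, 400), sample_rate = 2000)
#' @export
beat_annotations <- function(sample, sample_rate,
                             source = c("detected", "reference")) {
  source <- match.arg(source)
  sample <- as.numeric(sample)
  if (any(sample < 0)) abort("sample indices must be >= 0 (0-based)")
  if (length(sample) > 1 && any(diff(sample) <= 0)) {
    abort("peak sample indices must be strictly increasing")
  }
  out <- new_tibble(
    list(beat = seq_along(sample), sample = sample,
         time_s = sample / sample_rate),
    nrow = length(sample), class = "beat_tbl"
  )
  attr(out, "sample_rate") <- as.numeric(sample_rate)
  attr(out, "source") <- source
  out
}

# ---- delimited-text record I/O ----------------------------------------------
# Format: comment header lines `# key=value` (sample_rate_hz mandatory,
# leads / start_s optional), then whitespace-delimited numeric columns,
# one column per lead, amplitudes in mV.

parse_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$", h))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- trimws(m[3])
  }
  kv
}

#' Read and write delimited-text ECG records
#'
#' The on-disk format is plain text: `# key=value` header lines carrying at
#' least `sample_rate_hz` (plus optional `leads` and `start_s`), followed by
#' one whitespace-delimited numeric column per lead, amplitudes in mV.
#' Readers refuse files without a sample rate, with ragged columns, or with
#' non-numeric content; amplitudes in other units must be converted before
#' writing.
#'
#' @param path File path.
#' @param record An `ecg_tbl` record.
#' @return `read_ecg()` returns an `ecg_tbl`; `write_ecg()` returns `path`
#'   invisibly.
#' @examples
#' p <- tempfile(fileext = ".txt")
#' rec <- ecg_record(list(II = sin(2 * pi * 5 * seq(0, 1, by = 5e-4))), 2000)
#' write_ecg(rec, p)
#' rec2 <- read_ecg(p)
#' @export
read_ecg <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  kv <- parse_header(lines)
  if (is.null(kv$sample_rate_hz)) {
    abort("missing sample rate: header must contain `# sample_rate_hz=`")
  }
  rate <- suppressWarnings(as.numeric(kv$sample_rate_hz))
  if (is.na(rate) || rate <= 0) abort("invalid sample rate in header")
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) abort("record contains no samples")
  rows <- strsplit(trimws(body), "[\t ,]+")
  ncol <- lengths(rows)
  if (length(unique(ncol)) != 1) {
    abort("ragged channels: rows have differing numbers of columns")
  }
  vals <- suppressWarnings(as.numeric(unlist(rows, use.names = FALSE)))
  if (anyNA(vals)) abort("non-numeric content in record body")
  mat <- matrix(vals, ncol = ncol[[1]], byrow = TRUE)
  labels <- if (!is.null(kv$leads)) {
    trimws(strsplit(kv$leads, ",")[[1]])
  } else {
    paste0("V", seq_len(ncol(mat)))
  }
  if (length(labels) != ncol(mat)) {
    abort("header `leads=` does not match the number of columns")
  }
  start_s <- if (!is.null(kv$start_s)) as.numeric(kv$start_s) else 0
  sig <- lapply(seq_len(ncol(mat)), function(j) mat[, j])
  names(sig) <- labels
  ecg_record(sig, rate, start_s = start_s)
}

#' @rdname read_ecg
#' @export
write_ecg <- function(record, path) {
  stopifnot(inherits(record, "ecg_tbl"))
  leads <- lead_names(record)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sample_rate_hz=%.10g", sample_rate(record)),
    sprintf("# leads=%s", paste(leads, collapse = ",")),
    sprintf("# start_s=%.10g", attr(record, "start_s") %||% 0)
  ), con)
  mat <- lead_matrix(record)
  body <- apply(mat, 1, function(r) paste(sprintf("%.9g", r), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read and write beat-annotation files
#'
#' Annotations are a single column of 0-based sample indices preceded by
#' `# sample_rate_hz=` and `# source=` header lines.
#'
#' @param path File path.
#' @param beats A `beat_tbl` from [beat_annotations()] or [detect_r_peaks()].
#' @return `read_beats()` a `beat_tbl`; `write_beats()` the path, invisibly.
#' @export
read_beats <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  kv <- parse_header(lines)
  if (is.null(kv$sample_rate_hz)) {
    abort("missing sample rate: header must contain `# sample_rate_hz=`")
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  idx <- suppressWarnings(as.numeric(body))
  if (anyNA(idx)) abort("non-numeric annotation content")
  src <- kv$source %||% "reference"
  beat_annotations(idx, as.numeric(kv$sample_rate_hz), source = src)
}

#' @rdname read_beats
#' @export
write_beats <- function(beats, path) {
  stopifnot(inherits(beats, "beat_tbl"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sample_rate_hz=%.10g", sample_rate(beats)),
    sprintf("# source=%s", attr(beats, "source") %||% "detected"),
    format(beats$sample, scientific = FALSE, trim = TRUE)
  ), con)
  invisible(path)
}

#' Split a recording into consecutive fragments
#'
#' Long ambulatory recordings are analysed in fixed-length fragments
#' (20 minutes by default). Fragments are consecutive and non-overlapping; a
#' final partial fragment is retained and flagged rather than dropped, and
#' rate-normalised statistics downstream use its true duration.
#'
#' @param record An `ecg_tbl` record.
#' @param fragment_s Fragment length in seconds (default 1200 = 20 min).
#' @return A tibble with one row per fragment: `fragment`, `start_s`,
#'   `n_samples`, `duration_s`, `partial`, and a `record` list-column of
#'   `ecg_tbl` fragments.
#' @examples
#' rec <- ecg_record(list(II = rnorm(5000)), sample_rate = 1000)
#' segment_ecg(rec, fragment_s = 2)
#' @export
segment_ecg <- function(record, fragment_s = 1200) {
  stopifnot(inherits(record, "ecg_tbl"))
  if (!is.numeric(fragment_s) || fragment_s <= 0) {
    abort("`fragment_s` must be positive")
  }
  rate <- sample_rate(record)
  frag_n <- round(fragment_s * rate)
  n <- nrow(record)
  starts <- seq(1, n, by = frag_n)
  leads <- lead_names(record)
  base_start <- attr(record, "start_s") %||% 0
  frags <- lapply(seq_along(starts), function(k) {
    i0 <- starts[k]
    i1 <- min(i0 + frag_n - 1, n)
    sig <- lapply(record[leads], function(v) v[i0:i1])
    ecg_record(sig, rate, start_s = base_start + (i0 - 1) / rate,
               partial = (i1 - i0 + 1) < frag_n)
  })
  tibble(
    fragment = seq_along(frags),
    start_s = vapply(frags, function(f) attr(f, "start_s"), numeric(1)),
    n_samples = vapply(frags, nrow, integer(1)),
    duration_s = vapply(frags, duration_s, numeric(1)),
    partial = vapply(frags, function(f) isTRUE(attr(f, "partial")), logical(1)),
    record = frags
  )
}
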