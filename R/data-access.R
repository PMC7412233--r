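#' Published murine R-peak detection benchmark counts
#'
#' Per-fragment true/false positive/negative counts (and the published
#' six-decimal metrics) from a benchmark of automated R-peak detection on
#' ten 20-minute murine ECG fragments at 1000 Hz, comparing a custom
#' detector of this design against the PhysioZoo platform. True negatives
#' are counted at the sample level, so each custom-detector row sums to
#' 1,200,000 evaluated samples. Useful as a worked input for
#' [evaluate_counts()] and as a reference range for synthetic-data studies.
#'
#' @return A tibble with columns `method`, `file`, `tp`, `tn`, `fp`, `fn`
#'   and the published `sensitivity`, `precision`, `specificity`.
#' @examples
#' counts <- rpeak_benchmark()
#' ev <- evaluate_counts(counts[, c("method", "file", "tp", "tn", "fp", "fn")])
#' glance(ev)
#' @export
rpeak_benchmark <- function() {
  path <- system.file("extdata", "rpeak_benchmark_counts.csv",
                      package = "ambecg", mustWork = TRUE)
  as_tibble(read.csv(path, colClasses = c(
    method = "character", file = "character")))
}
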