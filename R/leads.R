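#' Einthoven and Goldberger lead algebra
#'
#' With two recorded bipolar limb leads the remaining standard leads follow
#' algebraically (clinical Einthoven polarity assumed): the third Einthoven
#' lead is `III = II - I`, and the Goldberger augmented unipolar leads are
#' `aVR = -(I + II)/2`, `aVL = I - II/2`, `aVF = II - I/2`. The augmented
#' leads always sum to zero.
#'
#' @param lead_i,lead_ii Numeric vectors of equal length, amplitudes in mV.
#' @return `derive_lead_iii()` a numeric vector; `derive_augmented_leads()` a
#'   tibble with columns `aVR`, `aVL`, `aVF`.
#' @examples
#' derive_lead_iii(0.2, 0.5)           # 0.3
#' derive_augmented_leads(0.2, 0.5)    # aVR -0.35, aVL -0.05, aVF 0.4
#' @export
derive_lead_iii <- function(lead_i, lead_ii) {
  if (length(lead_i) != length(lead_ii)) {
    abort("length mismatch between lead I and lead II")
  }
  lead_ii - lead_i
}

#' @rdname derive_lead_iii
#' @export
derive_augmented_leads <- function(lead_i, lead_ii) {
  if (length(lead_i) != length(lead_ii)) {
    abort("length mismatch between lead I and lead II")
  }
  tibble(
    aVR = -(lead_i + lead_ii) / 2,
    aVL = lead_i - lead_ii / 2,
    aVF = lead_ii - lead_i / 2
  )
}

#' Add derived leads to a record
#'
#' Convenience wrapper adding `III` (if absent) and the augmented leads
#' `aVR`, `aVL`, `aVF` as new columns, computed from recorded leads `I` and
#' `II`.
#'
#' @param record An `ecg_tbl` containing leads `"I"` and `"II"`.
#' @return The record with additional lead columns.
#' @export
with_derived_leads <- function(record) {
  stopifnot(inherits(record, "ecg_tbl"))
  if (!all(c("I", "II") %in% names(record))) {
    abort("record must contain leads \"I\" and \"II\"")
  }
  if (!"III" %in% names(record)) {
    record$III <- derive_lead_iii(record$I, record$II)
  }
  aug <- derive_augmented_leads(record$I, record$II)
  record$aVR <- aug$aVR
  record$aVL <- aug$aVL
  record$aVF <- aug$aVF
  record
}
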