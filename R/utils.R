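# Internal helpers shared across modules.

# Stage-tagged logging to stderr; every pipeline stage reports its counts
# through this single chokepoint so runs are auditable.
pv_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  invisible(NULL)
}

# Normalize free text for controlled-vocabulary matching: Unicode NFC,
# case fold, collapse internal whitespace, trim. Exact-string after
# normalization -- deliberately not substring matching.
normalize_term <- function(x) {
  x <- stringi::stri_trans_nfc(as.character(x))
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

check_proportions <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(sprintf("%s must be proportions in [0, 1]", what), call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("%s must sum to 1 (got %.12f)", what, sum(p)), call. = FALSE)
  }
  invisible(p)
}

#' Percentage of flagged reports
#'
#' Proportion of case-flagged reports among all analysis records,
#' expressed as a percentage and rounded the way summary tables print it.
#'
#' @param n_flagged number of case-flagged records.
#' @param n_total total number of analysis records.
#' @param digits decimal places of the printed percentage (default 3).
#' @return Numeric percentage, e.g. `0.067` for 1873 of 2,794,953.
#' @export
#' @examples
#' report_proportion(1873, 2794953)
report_proportion <- function(n_flagged, n_total, digits = 3) {
  stopifnot(n_total > 0, n_flagged >= 0, n_flagged <= n_total)
  round(100 * n_flagged / n_total, digits)
}
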