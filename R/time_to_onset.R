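# Time-to-onset construction: JADER date strings come in four digit
# dialects (4/6/8/12 digits); they are cleaned to calendar dates, the
# earliest administration and onset dates are selected per report, and
# the onset interval gets a +0.5-day continuity correction and a
# 0.5-365.5 day analysis window.

#' Clean a raw JADER date string
#'
#' Digit-only strings are handled by length: 12 digits are truncated to
#' the first eight (date + clock time), 8 digits parse as YYYYMMDD,
#' 6 digits (YYYYMM) are imputed to the 15th of the month, and 4 digits
#' (year only) are treated as missing. Anything else -- including
#' digit strings that are not real calendar dates (month 13, day 32,
#' Feb 29 in a non-leap year) -- is unparseable. Missing is a value,
#' never an error.
#'
#' @param raw character vector of raw date strings.
#' @return Data frame with one row per input: `date` (`Date`, `NA` when
#'   missing) and `provenance` (one of `"8-digit"`, `"truncated-12"`,
#'   `"imputed-6"`, `"missing-4"`, `"unparseable"`). `date` is
#'   non-missing exactly when provenance is one of the first three.
#' @export
#' @examples
#' clean_date(c("202304151230", "202304", "2023", "20230415"))
clean_date <- function(raw) {
  raw <- trimws(as.character(raw))
  n <- length(raw)
  date <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
  prov <- rep("unparseable", n)

  digits <- !is.na(raw) & grepl("^[0-9]+$", raw)
  len <- ifelse(digits, nchar(raw), -1L)

  eight <- raw
  eight[len == 12] <- substr(raw[len == 12], 1, 8)
  eight[len == 6] <- paste0(raw[len == 6], "15")

  parseable <- len %in% c(6, 8, 12)
  parsed <- as.Date(eight[parseable], format = "%Y%m%d")
  # as.Date(format=) accepts some impossible dates by rolling; require an
  # exact round trip so month 13 / day 32 are rejected
  ok <- !is.na(parsed) & format(parsed, "%Y%m%d") == eight[parseable]
  date[parseable][ok] <- parsed[ok]

  prov[parseable][ok] <- c(`6` = "imputed-6", `8` = "8-digit",
                           `12` = "truncated-12")[as.character(len[parseable][ok])]
  prov[len == 4] <- "missing-4"
  data.frame(date = date, provenance = prov, stringsAsFactors = FALSE)
}

#' Check dates against a validity window
#'
#' `TRUE` iff the date is present and inside the closed interval. The
#' default window, 1960-01-01 to 2025-02-28, is the plausibility window
#' applied to administration start dates (and, by assumption, onset
#' dates) in the reference analysis.
#'
#' @param dates `Date` vector (e.g. the `date` column of
#'   [clean_date()]).
#' @param window length-2 `Date` (or coercible) vector, start <= end.
#' @return Logical vector; missing dates are `FALSE`.
#' @export
validate_window <- function(dates,
                            window = as.Date(c("1960-01-01", "2025-02-28"))) {
  window <- as.Date(window)
  stopifnot(length(window) == 2, window[1] <= window[2])
  !is.na(dates) & dates >= window[1] & dates <= window[2]
}

#' Earliest valid date per key
#'
#' For rows carrying cleaned dates, returns the minimum date per key
#' (e.g. the first administration of a drug within a report, or the
#' first event onset for a patient). Rows with missing dates are
#' ignored; keys with no valid date are absent from the result.
#'
#' @param df data frame.
#' @param key character vector of key column names.
#' @param date_col name of the `Date` column (default `"date"`).
#' @return Data frame with the key columns and the minimum `date`.
#' @export
earliest_per_key <- function(df, key, date_col = "date") {
  stopifnot(all(c(key, date_col) %in% names(df)))
  df <- df[!is.na(df[[date_col]]), c(key, date_col), drop = FALSE]
  if (nrow(df) == 0) return(df)
  out <- aggregate(df[[date_col]], by = df[key], FUN = min)
  names(out) <- c(key, date_col)
  out[do.call(order, out[key]), , drop = FALSE]
}

#' Continuity-corrected time to onset
#'
#' Whole days from administration start to event onset plus 0.5 days as
#' a continuity correction, so a same-day onset contributes 0.5 days.
#' May be negative (plus 0.5) when onset precedes start; such values
#' fall outside the analysis window and are removed by
#' [window_filter()].
#'
#' @param start,onset `Date` vectors.
#' @return Numeric days; `t - 0.5` is a (possibly negative) integer.
#' @export
compute_tto <- function(start, onset) {
  as.numeric(as.Date(onset) - as.Date(start)) + 0.5
}

#' Restrict onset intervals to the analysis window
#'
#' Keeps exactly the values in the closed interval \[lower, upper\]
#' (defaults 0.5 and 365.5 days, both retained). Removal counts below
#' and above the window are logged and attached as attributes
#' `n_below` / `n_above`.
#'
#' @param values numeric days.
#' @param lower,upper closed window bounds.
#' @return The retained values.
#' @export
window_filter <- function(values, lower = 0.5, upper = 365.5) {
  stopifnot(lower < upper)
  keep <- !is.na(values) & values >= lower & values <= upper
  n_below <- sum(!is.na(values) & values < lower)
  n_above <- sum(!is.na(values) & values > upper)
  pv_log("window_filter", "kept %d of %d values (%d below %.1f, %d above %.1f)",
         sum(keep), length(values), n_below, lower, n_above, upper)
  out <- values[keep]
  attr(out, "n_below") <- n_below
  attr(out, "n_above") <- n_above
  out
}

#' Build the per-drug onset table
#'
#' For one drug, derives the windowed, continuity-corrected time to
#' onset per report: deduplicate, keep suspected rows only, clean the
#' drug's administration dates and the flagged events' onset dates,
#' take the earliest valid date of each per report (first dose, first
#' onset), difference + 0.5 days, then apply the onset analysis window.
#' Demographics are joined as optional enrichment.
#'
#' @param tables a `jader_tables` object (raw; cleaning is internal).
#' @param drug_name drug whose onset profile is wanted.
#' @param case_def the event [case_definition()].
#' @param date_window validity window for both date fields (see
#'   [validate_window()]).
#' @param tto_range closed analysis window in days (default
#'   `c(0.5, 365.5)`).
#' @param age_aliases passed to [convert_age()].
#' @return Data frame sorted by report_id: report_id, drug_name,
#'   t_days, gender, age_years. Empty (0 rows) when the drug or flagged
#'   events are absent.
#' @export
build_onset_table <- function(tables, drug_name,
                              case_def = case_definition(),
                              date_window = as.Date(c("1960-01-01",
                                                      "2025-02-28")),
                              tto_range = c(0.5, 365.5),
                              age_aliases = NULL) {
  stopifnot(inherits(tables, "jader_tables"))
  tables <- filter_suspected(deduplicate_tables(tables))

  empty <- data.frame(report_id = character(), drug_name = character(),
                      t_days = numeric(), gender = character(),
                      age_years = numeric(), stringsAsFactors = FALSE)

  dr <- tables$drug[tables$drug$drug_name == drug_name, , drop = FALSE]
  if (nrow(dr) == 0) return(empty)
  cd <- clean_date(dr$start_date)
  dr$date <- cd$date
  dr <- dr[validate_window(dr$date, date_window), , drop = FALSE]
  if (nrow(dr) == 0) return(empty)
  starts <- earliest_per_key(dr, "report_id")

  re <- tables$reaction
  re <- re[normalize_term(re$event_pt) %in% case_def$normalized_terms, ,
           drop = FALSE]
  if (nrow(re) == 0) return(empty)
  re$date <- clean_date(re$onset_date)$date
  re <- re[validate_window(re$date, date_window), , drop = FALSE]
  if (nrow(re) == 0) return(empty)
  onsets <- earliest_per_key(re, "report_id")

  names(starts)[2] <- "start"
  names(onsets)[2] <- "onset"
  both <- merge(starts, onsets, by = "report_id")
  if (nrow(both) == 0) return(empty)
  both$t_days <- compute_tto(both$start, both$onset)
  keep <- both$t_days >= tto_range[1] & both$t_days <= tto_range[2]
  pv_log("build_onset_table",
         "%s: %d report(s) with both dates, %d inside [%.1f, %.1f] days",
         drug_name, nrow(both), sum(keep), tto_range[1], tto_range[2])
  both <- both[keep, , drop = FALSE]
  if (nrow(both) == 0) return(empty)

  demo <- tables$demographic[!duplicated(tables$demographic$report_id), ,
                             drop = FALSE]
  out <- merge(both[, c("report_id", "t_days")],
               demo[, c("report_id", "gender", "age")],
               by = "report_id", all.x = TRUE)
  out$gender[is.na(out$gender)] <- "unknown"
  out$age_years <- convert_age(out$age, aliases = age_aliases)
  out$drug_name <- drug_name
  out <- out[order(out$report_id),
             c("report_id", "drug_name", "t_days", "gender", "age_years")]
  rownames(out) <- NULL
  out
}
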