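# Disproportionality screening: per-drug 2x2 contingency tables against
# the case flag, reporting odds ratio with Haldane-Anscombe correction,
# two-sided Fisher's exact test, and the three-part signal rule
# (ROR > 1, p < 0.05, >= min_reports reports).

#' Build the 2x2 contingency table for one drug
#'
#' Cell roles: `a` = with the drug and the event, `b` = with the drug
#' without the event, `c` = without the drug with the event, `d` =
#' neither. With `unit = "report"` (the pharmacovigilance convention) a
#' report counts once per cell: drug-positive if any of its suspected
#' drugs is `drug_name`, event-positive if any of its reactions is
#' flagged; the four cells partition the report set. With
#' `unit = "pair"` each analysis record (drug-event pair) is a counting
#' unit.
#'
#' @param records flagged analysis records (see [flag_events()]).
#' @param drug_name drug to tabulate; a drug absent from the data gives
#'   a zero drug margin.
#' @param unit `"report"` (default) or `"pair"`.
#' @return A list of class `contingency_2x2` with integer cells
#'   `a`, `b`, `c`, `d`.
#' @export
build_contingency <- function(records, drug_name,
                              unit = c("report", "pair")) {
  unit <- match.arg(unit)
  stopifnot(is.data.frame(records), "gbs_case" %in% names(records))
  if (nrow(records) == 0) stop("empty record set: no population to tabulate",
                               call. = FALSE)
  if (unit == "report") {
    drug_pos <- tapply(records$drug_name == drug_name, records$report_id, any)
    event_pos <- tapply(records$gbs_case, records$report_id, any)
    a <- sum(drug_pos & event_pos)
    b <- sum(drug_pos & !event_pos)
    c <- sum(!drug_pos & event_pos)
    d <- sum(!drug_pos & !event_pos)
  } else {
    dp <- records$drug_name == drug_name
    a <- sum(dp & records$gbs_case)
    b <- sum(dp & !records$gbs_case)
    c <- sum(!dp & records$gbs_case)
    d <- sum(!dp & !records$gbs_case)
  }
  structure(list(a = as.integer(a), b = as.integer(b),
                 c = as.integer(c), d = as.integer(d),
                 drug_name = drug_name, unit = unit),
            class = "contingency_2x2")
}

#' Haldane-Anscombe corrected reporting odds ratio
#'
#' Adds 1/2 to every cell before forming the odds ratio, so zero cells
#' never produce a division by zero:
#' ROR = ((a+1/2)(d+1/2)) / ((b+1/2)(c+1/2)). The 95% CI is Wald on the
#' log scale with the corrected cells:
#' exp(ln ROR +/- 1.96 sqrt(sum of 1/(cell+1/2))). The correction is
#' applied to the ROR and its CI only; Fisher's exact test
#' ([fisher_exact_2x2()]) uses the raw integer cells.
#'
#' @param table a `contingency_2x2` or a list/vector with `a,b,c,d`.
#' @param conf_level CI level (default 0.95).
#' @return List with `ror`, `ln_ror`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' ror_corrected(list(a = 10, b = 90, c = 1000, d = 9000))
ror_corrected <- function(table, conf_level = 0.95) {
  a <- table[["a"]] + 0.5; b <- table[["b"]] + 0.5
  c <- table[["c"]] + 0.5; d <- table[["d"]] + 0.5
  ror <- (a * d) / (b * c)
  ln_ror <- log(ror)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(ror = ror, ln_ror = ln_ror,
       ci_low = exp(ln_ror - z * se), ci_high = exp(ln_ror + z * se))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Sums, over all tables with the observed margins, the hypergeometric
#' probabilities not exceeding that of the observed table (the
#' minimum-likelihood two-sided convention of standard statistical
#' software); probabilities within a relative tolerance of 1e-7 of the
#' observed one count as tied and are included. Any zero margin gives
#' p = 1 by convention.
#'
#' @param a,b,c,d non-negative integer cells (raw, uncorrected). `a`
#'   may also be a `contingency_2x2`, in which case the other arguments
#'   are ignored.
#' @return Two-sided p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact_2x2(5, 0, 0, 5)  # 2/252
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (inherits(a, "contingency_2x2") || (is.list(a) && !is.null(a$a))) {
    b <- a[["b"]]; c <- a[["c"]]; d <- a[["d"]]; a <- a[["a"]]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("Fisher's exact test needs non-negative integer cells",
         call. = FALSE)
  }
  m <- a + b          # drug margin
  n <- c + d          # non-drug margin
  k <- a + c          # event margin
  if (m == 0 || n == 0 || k == 0 || b + d == 0) {
    return(1)         # degenerate margin: independence is untestable
  }
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Apply the three-part signal rule
#'
#' A drug shows a signal iff ROR > 1 (strict), two-sided Fisher p <
#' alpha (strict), and its report count is at least `min_reports`
#' (inclusive: n = 100 passes at the default threshold).
#'
#' @param ror corrected reporting odds ratio.
#' @param p_value two-sided Fisher p.
#' @param n_drug_reports reports carrying the drug (a + b).
#' @param min_reports report-count threshold (default 100).
#' @param alpha significance level (default 0.05).
#' @return Logical.
#' @export
classify_signal <- function(ror, p_value, n_drug_reports,
                            min_reports = 100, alpha = 0.05) {
  stopifnot(min_reports > 0, alpha > 0)
  (ror > 1) & (p_value < alpha) & (n_drug_reports >= min_reports)
}

#' Screen every drug in the analysis table
#'
#' Builds the per-drug 2x2 table, corrected ROR and CI, Fisher p, and
#' the signal verdict for each distinct drug name, plus volcano
#' coordinates (ln ROR, -log10 p). No multiple-testing adjustment is
#' applied; the number of tests equals the number of rows returned.
#'
#' @param records flagged analysis records (see [flag_events()]).
#' @param min_reports,alpha signal-rule thresholds (see
#'   [classify_signal()]).
#' @param unit counting unit, `"report"` or `"pair"` (see
#'   [build_contingency()]).
#' @return Data frame of class `signal_screen`, one row per drug,
#'   sorted by descending `neg_log10_p` with ties broken by drug name:
#'   drug, a, b, c, d, ror, ror_ci_low, ror_ci_high, ln_ror, p_value,
#'   neg_log10_p, n_reports, is_signal.
#' @export
screen_signals <- function(records, min_reports = 100, alpha = 0.05,
                           unit = c("report", "pair")) {
  unit <- match.arg(unit)
  stopifnot(is.data.frame(records), "gbs_case" %in% names(records))
  drugs <- sort(unique(records$drug_name))
  if (length(drugs) == 0 || nrow(records) == 0) {
    res <- data.frame(drug = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), ror = numeric(),
                      ror_ci_low = numeric(), ror_ci_high = numeric(),
                      ln_ror = numeric(), p_value = numeric(),
                      neg_log10_p = numeric(), n_reports = integer(),
                      is_signal = logical())
    class(res) <- c("signal_screen", class(res))
    return(res)
  }

  if (unit == "report") {
    event_by_report <- tapply(records$gbs_case, records$report_id, any)
    N <- length(event_by_report)
    E <- sum(event_by_report)
    pairs <- unique(records[, c("report_id", "drug_name")])
    pairs$event <- unname(event_by_report[pairs$report_id])
    n_g <- tapply(rep(1L, nrow(pairs)), pairs$drug_name, sum)
    a_g <- tapply(pairs$event, pairs$drug_name, sum)
  } else {
    N <- nrow(records)
    E <- sum(records$gbs_case)
    n_g <- tapply(rep(1L, nrow(records)), records$drug_name, sum)
    a_g <- tapply(records$gbs_case, records$drug_name, sum)
  }

  a <- as.integer(a_g[drugs])
  nb <- as.integer(n_g[drugs])
  b <- nb - a
  c <- as.integer(E) - a
  d <- as.integer(N) - nb - c

  ror <- ror_corrected(list(a = a, b = b, c = c, d = d))
  p <- vapply(seq_along(drugs),
              function(i) fisher_exact_2x2(a[i], b[i], c[i], d[i]),
              numeric(1))
  res <- data.frame(
    drug = drugs, a = a, b = b, c = c, d = d,
    ror = ror$ror, ror_ci_low = ror$ci_low, ror_ci_high = ror$ci_high,
    ln_ror = ror$ln_ror, p_value = p, neg_log10_p = -log10(p),
    n_reports = nb,
    is_signal = classify_signal(ror$ror, p, nb, min_reports, alpha),
    stringsAsFactors = FALSE
  )
  res <- res[order(-res$neg_log10_p, res$drug), , drop = FALSE]
  rownames(res) <- NULL
  pv_log("screen_signals",
         "screened %d drugs over %d %ss (%d events): %d signal(s); no multiplicity adjustment (%d tests)",
         nrow(res), N, unit, E, sum(res$is_signal), nrow(res))
  class(res) <- c("signal_screen", class(res))
  res
}

#' Volcano-plot coordinates for a screening result
#'
#' x = ln(ROR), y = -log10(p); the conventional significance reference
#' line sits at y = -log10(alpha) and is carried in the
#' `reference_line` attribute.
#'
#' @param results a [screen_signals()] result.
#' @param alpha significance level defining the reference line.
#' @return Data frame (drug, x, y, class_label) with attribute
#'   `reference_line`.
#' @export
volcano_coordinates <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results),
            all(c("drug", "ln_ror", "neg_log10_p") %in% names(results)))
  out <- data.frame(
    drug = results$drug,
    x = results$ln_ror,
    y = results$neg_log10_p,
    class_label = ifelse(results$is_signal, "signal", "no signal"),
    stringsAsFactors = FALSE
  )
  attr(out, "reference_line") <- -log10(alpha)
  out
}
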