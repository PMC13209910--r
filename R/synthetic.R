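# Seeded synthetic spontaneous-report generator in the JADER three-table
# schema. Every downstream stage can be validated against it because the
# generative truth -- per-drug event odds, Weibull onset profiles,
# injected duplicates, date dialects -- is known and attached as
# bookkeeping.

.decoy_pts <- c("Nausea", "Headache", "Pyrexia", "Rash", "Diarrhoea",
                "Vomiting", "Dizziness", "Fatigue", "Pruritus",
                "Hepatic function abnormal")

.default_age_mix <- c("under 10" = 0.05, "10s" = 0.07, "20s" = 0.08,
                      "30s" = 0.10, "40s" = 0.12, "50s" = 0.14,
                      "60s" = 0.14, "70s" = 0.14, "80s" = 0.10,
                      "90s" = 0.05, "100s" = 0.01)

#' Define a synthetic drug profile
#'
#' One simulated drug: how many reports list it as a suspected drug,
#' the odds of the flagged event in its reports relative to background,
#' the Weibull onset-time profile of its flagged events, and the mix of
#' involvement categories its rows carry.
#'
#' @param name drug label.
#' @param n_reports reports in which the drug is a suspected drug
#'   (>= 1).
#' @param gbs_odds_multiplier odds of the flagged event in this drug's
#'   reports relative to the background odds (> 0; 1 = null drug).
#' @param onset_scale_alpha,onset_shape_beta Weibull scale (days) and
#'   shape of the onset-time distribution for flagged events.
#' @param involvement_mix proportions over
#'   suspected/concomitant/interacting rows for this drug, summing
#'   to 1; the suspected share must be positive.
#' @return Object of class `drug_profile`.
#' @export
drug_profile <- function(name, n_reports, gbs_odds_multiplier = 1,
                         onset_scale_alpha = 20, onset_shape_beta = 1,
                         involvement_mix = c(suspected = 1, concomitant = 0,
                                             interacting = 0)) {
  stopifnot(is.character(name), nzchar(name),
            n_reports >= 1, n_reports == round(n_reports),
            gbs_odds_multiplier > 0,
            onset_scale_alpha > 0, onset_shape_beta > 0)
  involvement_mix <- involvement_mix[c("suspected", "concomitant",
                                       "interacting")]
  if (any(is.na(involvement_mix))) {
    stop("involvement_mix needs suspected, concomitant and interacting entries",
         call. = FALSE)
  }
  check_proportions(involvement_mix, "involvement_mix")
  if (involvement_mix[["suspected"]] <= 0) {
    stop("involvement_mix must give the suspected category positive mass",
         call. = FALSE)
  }
  structure(list(name = name, n_reports = as.integer(n_reports),
                 gbs_odds_multiplier = gbs_odds_multiplier,
                 onset_scale_alpha = onset_scale_alpha,
                 onset_shape_beta = onset_shape_beta,
                 involvement_mix = involvement_mix),
            class = "drug_profile")
}

#' Configure a synthetic JADER-schema dataset
#'
#' Defaults reflect the real database's gross features: a background
#' flagged-event rate of 0.067% of reports, an accrual window from
#' April 2004 to February 2025 (administration starts are sampled up to
#' 366 days before the window end so a year of follow-up fits inside
#' it), and a mostly-8-digit date dialect mix.
#'
#' @param profiles non-empty list of [drug_profile()]s.
#' @param background_event_rate probability that a background report
#'   carries the flagged event (in (0, 1)).
#' @param n_background_reports background reports to generate.
#' @param date_dialect_mix proportions over the `"4-digit"`,
#'   `"6-digit"`, `"8-digit"` and `"12-digit"` date renderings.
#' @param duplicate_row_rate fraction of rows injected again as exact
#'   duplicates in each table (in \[0, 1)).
#' @param gender_mix proportions over `male`/`female`/`unknown`.
#' @param age_decade_mix proportions over the decade codes.
#' @param study_window length-2 `Date` window for administration
#'   starts.
#' @param extra_drug_lambda Poisson mean of additional concomitant
#'   background drugs per report.
#' @param decoy_reaction_rate probability that an event report carries
#'   an additional non-flagged reaction row (non-event reports always
#'   carry one decoy reaction).
#' @param n_background_drugs size of the background drug vocabulary.
#' @param seed integer RNG seed; identical configs and seeds give
#'   byte-identical tables.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(profiles,
                             background_event_rate = 0.00067,
                             n_background_reports = 10000,
                             date_dialect_mix = c("4-digit" = 0.05,
                                                  "6-digit" = 0.05,
                                                  "8-digit" = 0.85,
                                                  "12-digit" = 0.05),
                             duplicate_row_rate = 0,
                             gender_mix = c(male = 0.48, female = 0.48,
                                            unknown = 0.04),
                             age_decade_mix = .default_age_mix,
                             study_window = as.Date(c("2004-04-01",
                                                      "2025-02-28")),
                             extra_drug_lambda = 0.3,
                             decoy_reaction_rate = 0.2,
                             n_background_drugs = 50,
                             seed = 1) {
  if (!is.list(profiles) || length(profiles) == 0) {
    stop("`profiles` must be a non-empty list of drug_profile objects",
         call. = FALSE)
  }
  if (!all(vapply(profiles, inherits, logical(1), "drug_profile"))) {
    stop("every element of `profiles` must be a drug_profile", call. = FALSE)
  }
  stopifnot(background_event_rate > 0, background_event_rate < 1,
            n_background_reports >= 1,
            duplicate_row_rate >= 0, duplicate_row_rate < 1,
            extra_drug_lambda >= 0,
            decoy_reaction_rate >= 0, decoy_reaction_rate <= 1,
            n_background_drugs >= 1)
  dialects <- c("4-digit", "6-digit", "8-digit", "12-digit")
  if (!setequal(names(date_dialect_mix), dialects)) {
    stop("date_dialect_mix needs exactly the 4/6/8/12-digit entries",
         call. = FALSE)
  }
  check_proportions(date_dialect_mix[dialects], "date_dialect_mix")
  check_proportions(gender_mix, "gender_mix")
  check_proportions(age_decade_mix, "age_decade_mix")
  study_window <- as.Date(study_window)
  stopifnot(length(study_window) == 2, study_window[1] < study_window[2])
  structure(list(
    profiles = profiles,
    background_event_rate = background_event_rate,
    n_background_reports = as.integer(n_background_reports),
    date_dialect_mix = date_dialect_mix[dialects],
    duplicate_row_rate = duplicate_row_rate,
    gender_mix = gender_mix,
    age_decade_mix = age_decade_mix,
    study_window = study_window,
    extra_drug_lambda = extra_drug_lambda,
    decoy_reaction_rate = decoy_reaction_rate,
    n_background_drugs = as.integer(n_background_drugs),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

render_dates <- function(dates, dialects) {
  out <- character(length(dates))
  out[dialects == "8-digit"] <- format(dates[dialects == "8-digit"], "%Y%m%d")
  i12 <- dialects == "12-digit"
  if (any(i12)) {
    out[i12] <- paste0(format(dates[i12], "%Y%m%d"),
                       sprintf("%02d%02d", sample(0:23, sum(i12), TRUE),
                               sample(0:59, sum(i12), TRUE)))
  }
  out[dialects == "6-digit"] <- format(dates[dialects == "6-digit"], "%Y%m")
  out[dialects == "4-digit"] <- format(dates[dialects == "4-digit"], "%Y")
  out
}

sample_dialects <- function(n, mix) {
  sample(names(mix), n, replace = TRUE, prob = mix)
}

inject_duplicates <- function(df, rate) {
  df <- df[!duplicated(df), , drop = FALSE]   # keep originals unique
  n_dup <- floor(rate * nrow(df))
  if (n_dup > 0) {
    df <- rbind(df, df[sample(nrow(df), n_dup, replace = FALSE), ,
                       drop = FALSE])
  }
  rownames(df) <- NULL
  list(table = df, n_injected = n_dup)
}

#' Generate a synthetic three-table dataset
#'
#' Draws one report per profile slot plus background reports. Each
#' report carries one suspected drug row (its primary drug), a Poisson
#' number of concomitant background drugs, at least one reaction row,
#' and one demographic row. Flagged events in profile-drug reports get
#' onset dates at `start + floor(Weibull(alpha, beta))` days, so the
#' pipeline's +0.5-day continuity correction reconstructs the interval
#' midpoints. Non-suspected involvement rows, decoy reaction terms,
#' date dialects and exact duplicate rows exercise the cleaning path.
#'
#' The `bookkeeping` attribute records per-report truth (primary drug,
#' event status, start date, floored onset day, the raw pre-floor
#' Weibull draw, the dialects used) plus per-table row and injected
#' duplicate counts.
#'
#' @param config a [synthetic_config()].
#' @return A `jader_tables` object (all-character tables) with
#'   attribute `bookkeeping`.
#' @export
generate_tables <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
  set.seed(config$seed)

  profiles <- config$profiles
  n_prof <- vapply(profiles, function(p) p$n_reports, integer(1))
  n_bg <- config$n_background_reports
  n_total <- sum(n_prof) + n_bg
  report_id <- sprintf("R%07d", seq_len(n_total))

  bg_drugs <- sprintf("background_drug_%02d", seq_len(config$n_background_drugs))
  primary <- c(rep(vapply(profiles, function(p) p$name, character(1)), n_prof),
               sample(bg_drugs, n_bg, replace = TRUE))
  is_profile <- c(rep(TRUE, sum(n_prof)), rep(FALSE, n_bg))

  p_bg <- config$background_event_rate
  o_bg <- p_bg / (1 - p_bg)
  p_event <- rep(p_bg, n_total)
  idx0 <- 0
  for (p in profiles) {
    o <- p$gbs_odds_multiplier * o_bg
    p_event[idx0 + seq_len(p$n_reports)] <- o / (1 + o)
    idx0 <- idx0 + p$n_reports
  }
  event <- rbinom(n_total, 1, p_event) == 1

  # administration starts: leave 366 days of follow-up inside the window
  span <- as.integer(config$study_window[2] - config$study_window[1]) - 366
  stopifnot(span >= 1)
  start <- config$study_window[1] + sample.int(span, n_total, replace = TRUE)

  onset_raw <- rep(NA_real_, n_total)
  onset_day <- rep(NA_integer_, n_total)
  idx0 <- 0
  for (p in profiles) {
    ii <- idx0 + seq_len(p$n_reports)
    ev <- ii[event[ii]]
    if (length(ev)) {
      onset_raw[ev] <- rweibull(length(ev), shape = p$onset_shape_beta,
                                scale = p$onset_scale_alpha)
      onset_day[ev] <- as.integer(floor(onset_raw[ev]))
    }
    idx0 <- idx0 + p$n_reports
  }
  bg_ev <- which(!is_profile & event)
  if (length(bg_ev)) {
    onset_day[bg_ev] <- as.integer(floor(rexp(length(bg_ev), rate = 1 / 30)))
  }

  start_dialect <- sample_dialects(n_total, config$date_dialect_mix)
  onset_dialect <- sample_dialects(n_total, config$date_dialect_mix)

  # ---- Drug table -----------------------------------------------------
  drug <- data.frame(report_id = report_id, involvement = "suspected",
                     drug_name = primary,
                     start_date = render_dates(start, start_dialect),
                     stringsAsFactors = FALSE)
  n_extra <- rpois(n_total, config$extra_drug_lambda)
  if (sum(n_extra) > 0) {
    rid <- rep(report_id, n_extra)
    extra <- data.frame(
      report_id = rid, involvement = "concomitant",
      drug_name = sample(bg_drugs, length(rid), replace = TRUE),
      start_date = render_dates(
        config$study_window[1] + sample.int(span, length(rid), TRUE),
        sample_dialects(length(rid), config$date_dialect_mix)),
      stringsAsFactors = FALSE)
    drug <- rbind(drug, extra)
  }
  # non-suspected rows for profile drugs per their involvement mix
  for (p in profiles) {
    mix <- p$involvement_mix
    other <- mix[["concomitant"]] + mix[["interacting"]]
    if (other <= 0) next
    n_other <- round(p$n_reports * other / mix[["suspected"]])
    if (n_other == 0) next
    inv <- sample(c("concomitant", "interacting"), n_other, replace = TRUE,
                  prob = c(mix[["concomitant"]], mix[["interacting"]]) / other)
    rid <- sample(report_id, n_other, replace = TRUE)
    drug <- rbind(drug, data.frame(
      report_id = rid, involvement = inv, drug_name = p$name,
      start_date = render_dates(
        config$study_window[1] + sample.int(span, n_other, TRUE),
        sample_dialects(n_other, config$date_dialect_mix)),
      stringsAsFactors = FALSE))
  }

  # ---- Reaction table -------------------------------------------------
  gbs_pts <- case_definition()$preferred_terms
  ev_idx <- which(event)
  reaction <- data.frame(report_id = character(), event_pt = character(),
                         onset_date = character(), stringsAsFactors = FALSE)
  if (length(ev_idx)) {
    reaction <- data.frame(
      report_id = report_id[ev_idx],
      event_pt = sample(gbs_pts, length(ev_idx), replace = TRUE),
      onset_date = render_dates(start[ev_idx] + onset_day[ev_idx],
                                onset_dialect[ev_idx]),
      stringsAsFactors = FALSE)
  }
  decoy_idx <- which(!event | runif(n_total) < config$decoy_reaction_rate)
  decoys <- data.frame(
    report_id = report_id[decoy_idx],
    event_pt = sample(.decoy_pts, length(decoy_idx), replace = TRUE),
    onset_date = render_dates(
      start[decoy_idx] + floor(runif(length(decoy_idx), 0, 90)),
      sample_dialects(length(decoy_idx), config$date_dialect_mix)),
    stringsAsFactors = FALSE)
  reaction <- rbind(reaction, decoys)

  # ---- Demographic table ----------------------------------------------
  weight <- ifelse(runif(n_total) < 0.7,
                   as.character(round(pmax(rnorm(n_total, 60, 15), 20))), "")
  demographic <- data.frame(
    report_id = report_id,
    gender = sample(names(config$gender_mix), n_total, replace = TRUE,
                    prob = config$gender_mix),
    age = sample(names(config$age_decade_mix), n_total, replace = TRUE,
                 prob = config$age_decade_mix),
    weight = weight,
    stringsAsFactors = FALSE)

  n_gbs_rows <- length(ev_idx)
  dup_d <- inject_duplicates(drug, config$duplicate_row_rate)
  dup_r <- inject_duplicates(reaction, config$duplicate_row_rate)
  dup_m <- inject_duplicates(demographic, config$duplicate_row_rate)

  tables <- structure(list(drug = dup_d$table, reaction = dup_r$table,
                           demographic = dup_m$table),
                      class = "jader_tables")
  attr(tables, "bookkeeping") <- list(
    n_rows = c(drug = nrow(dup_d$table), reaction = nrow(dup_r$table),
               demographic = nrow(dup_m$table)),
    n_duplicates_injected = c(drug = dup_d$n_injected,
                              reaction = dup_r$n_injected,
                              demographic = dup_m$n_injected),
    n_flagged_rows = n_gbs_rows,
    reports = data.frame(report_id = report_id, drug = primary,
                         is_profile = is_profile, event = event,
                         start_date = start, onset_day = onset_day,
                         onset_raw = onset_raw,
                         start_dialect = start_dialect,
                         onset_dialect = onset_dialect,
                         stringsAsFactors = FALSE)
  )
  tables
}

#' Ground truth implied by a synthetic configuration
#'
#' Deterministic, per profile drug: the configured odds multiplier and
#' Weibull onset parameters, and whether the drug is expected to be a
#' signal (odds multiplier > 1 and at least `min_reports` reports).
#'
#' @param config a [synthetic_config()].
#' @param min_reports screening report-count threshold (default 100).
#' @return Data frame: drug, odds_multiplier, alpha, beta,
#'   n_reports, expected_signal.
#' @export
ground_truth <- function(config, min_reports = 100) {
  stopifnot(inherits(config, "synthetic_config"), min_reports > 0)
  out <- do.call(rbind, lapply(config$profiles, function(p) {
    data.frame(drug = p$name, odds_multiplier = p$gbs_odds_multiplier,
               alpha = p$onset_scale_alpha, beta = p$onset_shape_beta,
               n_reports = p$n_reports,
               expected_signal = p$gbs_odds_multiplier > 1 &
                 p$n_reports >= min_reports,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write the three tables as CSV
#'
#' UTF-8, header row, comma separated, matching the [read_tables()]
#' default schema.
#'
#' @param tables a `jader_tables` object.
#' @param dir output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "jader_tables"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(drug = file.path(dir, "drug.csv"),
             reaction = file.path(dir, "reaction.csv"),
             demographic = file.path(dir, "demographic.csv"))
  for (nm in names(paths)) {
    write.csv(tables[[nm]], paths[[nm]], row.names = FALSE,
              fileEncoding = "UTF-8")
  }
  invisible(paths)
}
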