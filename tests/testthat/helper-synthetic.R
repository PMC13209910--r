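# Shared fixtures built in code: small synthetic configurations and a
# hand-rolled jader_tables constructor for micro-examples.

sm <- function(expr) suppressMessages(expr)

tiny_config <- function(seed = 1, ...) {
  synthetic_config(
    profiles = list(
      drug_profile("alpha_drug", 300, gbs_odds_multiplier = 8,
                   onset_scale_alpha = 15, onset_shape_beta = 0.8),
      drug_profile("beta_drug", 150, gbs_odds_multiplier = 1)
    ),
    background_event_rate = 0.005,
    n_background_reports = 1000,
    seed = seed,
    ...
  )
}

# Build a jader_tables object directly from row data (bypassing CSV IO)
make_tables <- function(drug, reaction, demographic = NULL) {
  if (is.null(demographic)) {
    demographic <- data.frame(report_id = character(), gender = character(),
                              age = character(), weight = character(),
                              stringsAsFactors = FALSE)
  }
  if (is.null(demographic$weight)) demographic$weight <- ""
  structure(list(drug = drug, reaction = reaction,
                 demographic = demographic),
            class = "jader_tables")
}

drug_rows <- function(report_id, involvement, drug_name, start_date) {
  data.frame(report_id = report_id, involvement = involvement,
             drug_name = drug_name, start_date = start_date,
             stringsAsFactors = FALSE)
}

reaction_rows <- function(report_id, event_pt, onset_date) {
  data.frame(report_id = report_id, event_pt = event_pt,
             onset_date = onset_date, stringsAsFactors = FALSE)
}

demo_rows <- function(report_id, gender, age, weight = "") {
  data.frame(report_id = report_id, gender = gender, age = age,
             weight = weight, stringsAsFactors = FALSE)
}

# Flagged analysis records built directly (unit tests for screening)
records_df <- function(report_id, drug_name, gbs_case,
                       event_pt = "Guillain-Barre syndrome") {
  data.frame(report_id = report_id, drug_name = drug_name,
             event_pt = ifelse(gbs_case, event_pt, "Nausea"),
             gender = "male", age_years = 55,
             start_date_raw = "20200101", onset_date_raw = "20200110",
             gbs_case = gbs_case, stringsAsFactors = FALSE)
}
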