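# Ingestion of the JADER three-table schema: Drug, Reaction and
# Demographic CSV tables keyed by a shared report identifier. All fields
# are read as text; date strings are cleaned later (see clean_date) and
# never parsed silently at read time.

.default_col_map <- list(
  drug        = c(report_id = "report_id", involvement = "involvement",
                  drug_name = "drug_name", start_date = "start_date"),
  reaction    = c(report_id = "report_id", event_pt = "event_pt",
                  onset_date = "onset_date"),
  demographic = c(report_id = "report_id", gender = "gender",
                  age = "age", weight = "weight")
)

.involvement_levels <- c("suspected", "concomitant", "interacting")

read_one_table <- function(path, map, table_name, optional_cols = character()) {
  if (!file.exists(path)) {
    stop(sprintf("%s table file not found: %s", table_name, path),
         call. = FALSE)
  }
  df <- read.csv(path, colClasses = "character", check.names = FALSE,
                 fileEncoding = "UTF-8")
  missing <- setdiff(setdiff(unname(map), optional_cols), names(df))
  if (length(missing)) {
    stop(sprintf("%s table is missing required column(s): %s",
                 table_name, paste(missing, collapse = ", ")), call. = FALSE)
  }
  # rename to canonical internal names; optional columns absent -> NA
  cols <- lapply(names(map), function(canon) {
    src <- map[[canon]]
    if (src %in% names(df)) df[[src]] else rep(NA_character_, nrow(df))
  })
  names(cols) <- names(map)
  out <- as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
  n_empty <- sum(!nzchar(trimws(out$report_id)))
  if (n_empty > 0) {
    warning(sprintf("%s table: dropped %d row(s) with empty report_id",
                    table_name, n_empty), call. = FALSE)
    out <- out[nzchar(trimws(out$report_id)), , drop = FALSE]
    rownames(out) <- NULL
  }
  pv_log("read_tables", "%s table: %d rows", table_name, nrow(out))
  out
}

#' Read the three JADER-schema tables
#'
#' Reads Drug, Reaction and Demographic CSV files with every field as
#' text. Column names can be remapped via `col_map` (a list with
#' entries `drug`, `reaction`, `demographic`, each a named character
#' vector canonical-name = file-column-name); the defaults match the
#' tables written by [write_tables()].
#'
#' @param drug,reaction,demographic paths to the three CSV files
#'   (UTF-8, header row).
#' @param col_map optional schema mapping overriding the defaults.
#' @return An object of class `jader_tables`: a list with character
#'   data frames `drug` (report_id, involvement, drug_name, start_date),
#'   `reaction` (report_id, event_pt, onset_date) and `demographic`
#'   (report_id, gender, age, weight).
#' @export
read_tables <- function(drug, reaction, demographic, col_map = NULL) {
  map <- .default_col_map
  if (!is.null(col_map)) {
    for (tb in names(col_map)) map[[tb]][names(col_map[[tb]])] <- col_map[[tb]]
  }
  tables <- list(
    drug        = read_one_table(drug, map$drug, "Drug"),
    reaction    = read_one_table(reaction, map$reaction, "Reaction"),
    demographic = read_one_table(demographic, map$demographic, "Demographic",
                                 optional_cols = map$demographic[["weight"]])
  )
  structure(tables, class = "jader_tables")
}

#' @export
print.jader_tables <- function(x, ...) {
  cat(sprintf("JADER-schema tables: Drug %d rows, Reaction %d rows, Demographic %d rows\n",
              nrow(x$drug), nrow(x$reaction), nrow(x$demographic)))
  invisible(x)
}

#' Remove exact duplicate rows within each table
#'
#' Rows equal on every field are reduced to their first occurrence,
#' independently in each of the three tables. This is the documented
#' deduplication rule of this pipeline (full-row identity); removed
#' counts are logged per table. Idempotent.
#'
#' @param tables a `jader_tables` object.
#' @return The deduplicated `jader_tables`.
#' @export
deduplicate_tables <- function(tables) {
  stopifnot(inherits(tables, "jader_tables"))
  for (nm in c("drug", "reaction", "demographic")) {
    before <- nrow(tables[[nm]])
    tables[[nm]] <- tables[[nm]][!duplicated(tables[[nm]]), , drop = FALSE]
    rownames(tables[[nm]]) <- NULL
    pv_log("deduplicate", "%s: removed %d duplicate row(s), %d remain",
           nm, before - nrow(tables[[nm]]), nrow(tables[[nm]]))
  }
  tables
}

#' Keep only suspected-drug rows
#'
#' Drops Drug-table rows whose involvement category is not
#' `"suspected"` (concomitant drugs and drug interactions are never
#' counted). Unrecognized involvement labels are dropped with a counted
#' warning. Reaction and Demographic tables pass through unchanged.
#'
#' @param tables a `jader_tables` object.
#' @return The filtered `jader_tables`.
#' @export
filter_suspected <- function(tables) {
  stopifnot(inherits(tables, "jader_tables"))
  inv <- tolower(trimws(tables$drug$involvement))
  unknown <- !(inv %in% .involvement_levels)
  if (any(unknown)) {
    warning(sprintf("dropped %d drug row(s) with unrecognized involvement",
                    sum(unknown)), call. = FALSE)
  }
  keep <- !unknown & inv == "suspected"
  pv_log("filter_suspected", "kept %d of %d drug rows (suspected only)",
         sum(keep), nrow(tables$drug))
  tables$drug <- tables$drug[keep, , drop = FALSE]
  rownames(tables$drug) <- NULL
  tables
}

.default_age_aliases <- c(
  "100s" = 105, "90s" = 95, "80s" = 85, "70s" = 75, "60s" = 65,
  "50s" = 55, "40s" = 45, "30s" = 35, "20s" = 25, "10s" = 15,
  "under 10" = 5, "under10" = 5, "0s" = 5
)

#' Convert decade-coded ages to midpoint years
#'
#' JADER reports age as a decade band; the analysis uses the band
#' midpoint as a continuous age: 100s -> 105, 90s -> 95, ..., 10s -> 15,
#' under 10 -> 5. Matching is case-insensitive after trimming;
#' unparseable codes give `NA` (missing is a value, not an error).
#' Additional label spellings (e.g. Japanese-language decade codes) can
#' be supplied through `aliases`.
#'
#' @param age_decade_code character vector of decade codes.
#' @param aliases named numeric vector mapping lower-cased codes to
#'   years; merged over the built-in English defaults.
#' @return Numeric vector of years with `NA` for unparseable codes; the
#'   image is a subset of \{5, 15, ..., 105\}.
#' @export
#' @examples
#' convert_age(c("100s", "under 10", "30s", ""))
convert_age <- function(age_decade_code, aliases = NULL) {
  map <- .default_age_aliases
  if (!is.null(aliases)) {
    stopifnot(is.numeric(aliases), !is.null(names(aliases)))
    map[tolower(names(aliases))] <- unname(aliases)
  }
  key <- tolower(trimws(as.character(age_decade_code)))
  unname(map[key])
}

#' Merge the three tables into the analysis table
#'
#' Expands each report into one record per (suspected-drug row x
#' reaction row) pair sharing the report identifier, then left-joins
#' demographics (reports without a demographic row keep gender and age
#' missing -- missing demographics never drop a record). Ages are
#' converted with [convert_age()]. Call after [deduplicate_tables()]
#' and [filter_suspected()].
#'
#' @param tables a deduplicated, suspected-filtered `jader_tables`.
#' @param age_aliases passed to [convert_age()].
#' @return Data frame of analysis records, sorted by report_id, drug
#'   and event term: report_id, drug_name, event_pt, gender, age_years,
#'   start_date_raw, onset_date_raw.
#' @export
merge_tables <- function(tables, age_aliases = NULL) {
  stopifnot(inherits(tables, "jader_tables"))
  drug <- tables$drug[, c("report_id", "drug_name", "start_date")]
  names(drug)[3] <- "start_date_raw"
  reac <- tables$reaction[, c("report_id", "event_pt", "onset_date")]
  names(reac)[3] <- "onset_date_raw"
  rec <- merge(drug, reac, by = "report_id", sort = FALSE)

  demo <- tables$demographic[, c("report_id", "gender", "age")]
  demo <- demo[!duplicated(demo$report_id), , drop = FALSE]
  rec <- merge(rec, demo, by = "report_id", all.x = TRUE, sort = FALSE)
  rec$gender[is.na(rec$gender)] <- "unknown"
  rec$age_years <- convert_age(rec$age, aliases = age_aliases)
  rec$age <- NULL

  rec <- rec[order(rec$report_id, rec$drug_name, rec$event_pt), ,
             drop = FALSE]
  rownames(rec) <- NULL
  rec <- rec[, c("report_id", "drug_name", "event_pt", "gender",
                 "age_years", "start_date_raw", "onset_date_raw")]
  pv_log("merge_tables", "analysis table: %d records from %d reports",
         nrow(rec), length(unique(rec$report_id)))
  rec
}
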