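# SMQ-style case definitions: a set of MedDRA preferred terms that
# defines the adverse event of interest. The shipped default is the
# narrow-scope Guillain-Barre syndrome SMQ (code 20000131), nine PTs.

#' Build a case definition
#'
#' A case definition is a non-empty set of MedDRA preferred terms (PTs);
#' a record is a case when its reported event term matches one of them
#' exactly after Unicode NFC normalization, case folding and whitespace
#' collapse. With no arguments the packaged narrow-scope
#' Guillain-Barre syndrome SMQ (nine PTs) is returned.
#'
#' @param preferred_terms character vector of PTs; `NULL` loads the
#'   packaged default list.
#' @param smq_code SMQ identifier kept as metadata (default `"20000131"`).
#' @param scope `"narrow"` or `"broad"`; metadata only, the terms
#'   themselves define the scope actually applied.
#' @return An object of class `case_definition`.
#' @seealso [read_case_definition()], [flag_events()]
#' @export
#' @examples
#' cd <- case_definition()
#' length(cd$preferred_terms)  # 9
case_definition <- function(preferred_terms = NULL, smq_code = "20000131",
                            scope = c("narrow", "broad")) {
  scope <- match.arg(scope)
  if (is.null(preferred_terms)) {
    path <- system.file("extdata", "gbs_smq_narrow_pts.txt",
                        package = "jaderpv", mustWork = TRUE)
    return(read_case_definition(path, smq_code = smq_code, scope = scope))
  }
  preferred_terms <- as.character(preferred_terms)
  preferred_terms <- preferred_terms[nzchar(trimws(preferred_terms))]
  if (length(preferred_terms) == 0) {
    stop("a case definition needs at least one preferred term", call. = FALSE)
  }
  norm <- normalize_term(preferred_terms)
  if (anyDuplicated(norm)) {
    stop("preferred terms must be unique after case-folding", call. = FALSE)
  }
  structure(
    list(smq_code = smq_code, scope = scope,
         preferred_terms = preferred_terms,
         normalized_terms = norm),
    class = "case_definition"
  )
}

#' Read a case definition from a plain-text file
#'
#' One preferred term per line; blank lines and `#` comments ignored.
#'
#' @inheritParams case_definition
#' @param path file to read.
#' @return An object of class `case_definition`.
#' @export
read_case_definition <- function(path, smq_code = "20000131",
                                 scope = c("narrow", "broad")) {
  scope <- match.arg(scope)
  if (!file.exists(path)) {
    stop(sprintf("case-definition file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  case_definition(lines[nzchar(lines)], smq_code = smq_code, scope = scope)
}

#' @export
print.case_definition <- function(x, ...) {
  cat(sprintf("Case definition: SMQ %s (%s scope), %d preferred terms\n",
              x$smq_code, x$scope, length(x$preferred_terms)))
  cat(paste0("  - ", x$preferred_terms, collapse = "\n"), "\n")
  invisible(x)
}

#' Flag analysis records matching a case definition
#'
#' Adds a logical `gbs_case` column: `TRUE` iff the record's `event_pt`
#' matches one of the definition's preferred terms after normalization.
#' No other column is touched; row order and count are preserved.
#'
#' @param records data frame of analysis records with an `event_pt`
#'   column (see [merge_tables()]).
#' @param case_def a [case_definition()].
#' @return `records` with a `gbs_case` logical column.
#' @export
flag_events <- function(records, case_def = case_definition()) {
  stopifnot(is.data.frame(records), "event_pt" %in% names(records))
  if (!inherits(case_def, "case_definition")) {
    stop("`case_def` must be a case_definition object", call. = FALSE)
  }
  records$gbs_case <- normalize_term(records$event_pt) %in%
    case_def$normalized_terms
  pv_log("flag_events", "%d of %d records match the case definition",
         sum(records$gbs_case), nrow(records))
  records
}
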