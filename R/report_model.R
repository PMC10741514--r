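# Report-level data model for spontaneous adverse event report databases.
#
# A report set is stored columnar, one row per individual case, with
# list-columns for the multi-valued fields (suspect drugs, concomitant
# drugs, reasons for use, reaction terms). This mirrors the on-disk CSV
# dialect and keeps per-drug counting vectorised over 10^5-report sets.

DRUG_ROLES <- c("SUSPECT", "CONCOMITANT")
SERIOUSNESS_LEVELS <- c("SERIOUS", "NON_SERIOUS")
SEX_LEVELS <- c("M", "F", "UNKNOWN")
REPORTER_TYPES <- c("CONSUMER", "HEALTHCARE_PROFESSIONAL", "UNKNOWN")

#' Normalize a drug name or reaction term
#'
#' Uppercases, trims surrounding whitespace and collapses internal runs of
#' whitespace to a single space. No salt/ingredient mapping is attempted:
#' names are kept at the granularity they were reported at (so
#' "Amlodipine Besylate" stays distinct from "Amlodipine").
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalize_name(c("  finasteride ", "Amlodipine   Besylate"))
normalize_name <- function(x) {
  x <- as.character(x)
  toupper(gsub("\\s+", " ", trimws(x)))
}

#' Construct a single adverse event report
#'
#' Builds a one-row report suitable for [report_set()]. Drug names and
#' reaction terms are normalized with [normalize_name()]; reasons for use are
#' aligned positionally with the suspect drugs (`NA` = reason unknown).
#'
#' @param report_id Unique case identifier.
#' @param suspect_drugs Character vector (length >= 1) of suspect product
#'   active ingredients.
#' @param reactions Character vector (length >= 1) of MedDRA preferred-term
#'   style reaction strings, e.g. "Infertility male".
#' @param concomitant_drugs Character vector (possibly empty) of co-medications
#'   not suspected of causing the event.
#' @param reasons_for_use Character vector parallel to `suspect_drugs` giving
#'   the indication for each suspect drug, or `NULL` (all unknown).
#' @param seriousness One of `"SERIOUS"`, `"NON_SERIOUS"`, or `NA`.
#' @param event_year Integer year of the event, or `NA`.
#' @param sex One of `"M"`, `"F"`, `"UNKNOWN"`, or `NA`.
#' @param age_years Patient age in years (0-130), or `NA`.
#' @param weight_kg Patient weight in kilograms, or `NA`.
#' @param reporter_type One of `"CONSUMER"`, `"HEALTHCARE_PROFESSIONAL"`,
#'   `"UNKNOWN"`.
#' @param country Reporting country code, or `NA`.
#' @param has_literature_ref Logical: does the report cite a literature
#'   reference?
#' @return A one-row [tibble::tibble()] in the report-set column layout.
#' @export
#' @examples
#' aer_report("R1", "Finasteride", "Infertility male",
#'            reasons_for_use = "alopecia", age_years = 34)
aer_report <- function(report_id,
                       suspect_drugs,
                       reactions,
                       concomitant_drugs = character(),
                       reasons_for_use = NULL,
                       seriousness = NA_character_,
                       event_year = NA_integer_,
                       sex = NA_character_,
                       age_years = NA_real_,
                       weight_kg = NA_real_,
                       reporter_type = "UNKNOWN",
                       country = NA_character_,
                       has_literature_ref = FALSE) {
  suspect_drugs <- normalize_name(suspect_drugs)
  concomitant_drugs <- normalize_name(as.character(concomitant_drugs))
  if (is.null(reasons_for_use)) {
    reasons_for_use <- rep(NA_character_, length(suspect_drugs))
  } else {
    reasons_for_use <- as.character(reasons_for_use)
    reasons_for_use[!is.na(reasons_for_use) & trimws(reasons_for_use) == ""] <-
      NA_character_
  }
  tibble::tibble(
    report_id = as.character(report_id),
    suspect_drugs = list(suspect_drugs),
    concomitant_drugs = list(concomitant_drugs),
    reasons_for_use = list(reasons_for_use),
    reactions = list(normalize_name(reactions)),
    seriousness = as.character(seriousness),
    event_year = as.integer(event_year),
    sex = as.character(sex),
    age_years = as.numeric(age_years),
    weight_kg = as.numeric(weight_kg),
    reporter_type = as.character(reporter_type),
    country = as.character(country),
    has_literature_ref = as.logical(has_literature_ref)
  )
}

#' Construct a validated report set
#'
#' @param reports A tibble in the layout produced by [aer_report()], or a list
#'   of such one-row tibbles, or `NULL` for an empty set.
#' @param provenance Free-text label recording where the data came from
#'   (source file, generation seed, ...).
#' @return An object of class `report_set`.
#' @seealso [read_reports()], [generate_reports()]
#' @export
report_set <- function(reports = NULL, provenance = NA_character_) {
  if (is.null(reports)) {
    reports <- empty_reports_tbl()
  } else if (is.list(reports) && !is.data.frame(reports)) {
    reports <- do.call(rbind, reports)
  }
  reports <- tibble::as_tibble(reports)
  rs <- structure(list(reports = reports, provenance = provenance),
                  class = "report_set")
  validate_report_set(rs)
  rs
}

empty_reports_tbl <- function() {
  aer_report("x", "x", "x")[0, ]
}

#' @export
print.report_set <- function(x, ...) {
  cat(sprintf("<report_set> %d report(s)", n_reports(x)))
  if (!is.na(x$provenance)) cat(sprintf("  [%s]", x$provenance))
  cat("\n")
  if (n_reports(x) > 0) print(utils::head(x$reports, 5))
  invisible(x)
}

#' Number of reports in a report set
#' @param rs A `report_set`.
#' @return Integer count of individual cases.
#' @export
n_reports <- function(rs) {
  stopifnot(inherits(rs, "report_set"))
  nrow(rs$reports)
}

#' Validate a report set against the data-model invariants
#'
#' Checks: unique report ids; at least one suspect drug and one non-empty
#' reaction term per report; reasons aligned one-to-one with suspect drugs;
#' enum fields within their vocabularies; ages within \[0, 130\].
#'
#' @param rs A `report_set`.
#' @return `rs`, invisibly; aborts with a per-row problem listing otherwise.
#' @export
validate_report_set <- function(rs) {
  stopifnot(inherits(rs, "report_set"))
  tbl <- rs$reports
  problems <- report_problems(tbl)
  dup <- unique(tbl$report_id[duplicated(tbl$report_id)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate report_id value(s): %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  if (nrow(problems) > 0) {
    msg <- paste(sprintf("row %d [%s]: %s", problems$row, problems$field,
                         problems$message), collapse = "\n  ")
    stop(sprintf("%d invalid report(s):\n  %s", length(unique(problems$row)),
                 msg), call. = FALSE)
  }
  invisible(rs)
}

# Row-level invariant check; returns a data.frame(row, field, message).
report_problems <- function(tbl) {
  probs <- list()
  add <- function(rows, field, message) {
    if (length(rows) > 0) {
      probs[[length(probs) + 1]] <<- data.frame(row = rows, field = field,
                                                message = message)
    }
  }
  n_susp <- vapply(tbl$suspect_drugs, function(d) sum(nzchar(d)), 0L)
  add(which(n_susp < 1L), "suspect_drugs", "no suspect drug")
  bad_susp <- vapply(tbl$suspect_drugs, function(d) any(!nzchar(d)), FALSE)
  add(which(bad_susp), "suspect_drugs", "empty drug name")
  bad_conc <- vapply(tbl$concomitant_drugs, function(d) any(!nzchar(d)), FALSE)
  add(which(bad_conc), "concomitant_drugs", "empty drug name")
  n_reac <- vapply(tbl$reactions, function(r) sum(nzchar(r)), 0L)
  add(which(n_reac < 1L |
              vapply(tbl$reactions, function(r) any(!nzchar(r)), FALSE)),
      "reactions", "missing or empty reaction term")
  mis_reason <- vapply(seq_len(nrow(tbl)), function(i) {
    length(tbl$reasons_for_use[[i]]) != length(tbl$suspect_drugs[[i]])
  }, FALSE)
  add(which(mis_reason), "reasons_for_use",
      "not aligned one-to-one with suspect_drugs")
  add(which(!nzchar(tbl$report_id) | is.na(tbl$report_id)), "report_id",
      "missing report_id")
  add(which(!is.na(tbl$age_years) &
              (tbl$age_years < 0 | tbl$age_years > 130)),
      "age_years", "outside [0, 130]")
  add(which(!is.na(tbl$weight_kg) & tbl$weight_kg < 0), "weight_kg",
      "negative")
  add(which(!is.na(tbl$seriousness) &
              !tbl$seriousness %in% SERIOUSNESS_LEVELS),
      "seriousness", "not SERIOUS/NON_SERIOUS")
  add(which(!is.na(tbl$sex) & !tbl$sex %in% SEX_LEVELS), "sex",
      "not M/F/UNKNOWN")
  add(which(is.na(tbl$reporter_type) |
              !tbl$reporter_type %in% REPORTER_TYPES),
      "reporter_type", "not CONSUMER/HEALTHCARE_PROFESSIONAL/UNKNOWN")
  add(which(is.na(tbl$has_literature_ref)), "has_literature_ref",
      "missing (must be TRUE/FALSE)")
  if (length(probs) == 0) {
    return(data.frame(row = integer(), field = character(),
                      message = character()))
  }
  out <- do.call(rbind, probs)
  out[order(out$row), , drop = FALSE]
}

#' Long view of every drug mention in a report set
#'
#' @param rs A `report_set`.
#' @return A tibble with one row per drug mention: `report_id`, `drug_name`,
#'   `role` (`"SUSPECT"` or `"CONCOMITANT"`), `reason_for_use` (`NA` for
#'   unknown and for all concomitant mentions).
#' @export
drug_mentions <- function(rs) {
  stopifnot(inherits(rs, "report_set"))
  tbl <- rs$reports
  ns <- lengths(tbl$suspect_drugs)
  nc <- lengths(tbl$concomitant_drugs)
  tibble::tibble(
    report_id = c(rep(tbl$report_id, ns), rep(tbl$report_id, nc)),
    drug_name = c(unlist(tbl$suspect_drugs), unlist(tbl$concomitant_drugs)),
    role = c(rep("SUSPECT", sum(ns)), rep("CONCOMITANT", sum(nc))),
    reason_for_use = c(unlist(tbl$reasons_for_use),
                       rep(NA_character_, sum(nc)))
  )
}

#' Exact-term reaction matching
#'
#' A report matches an index term iff the case/whitespace-normalized term
#' equals one of its normalized reaction terms. No substring or MedDRA
#' hierarchy matching is performed: a report coded only "Oligozoospermia"
#' does not match "Infertility male".
#'
#' @param rs A `report_set`.
#' @param term Non-empty reaction term (MedDRA preferred-term style).
#' @return Logical vector, one element per report.
#' @export
#' @examples
#' rs <- report_set(aer_report("R1", "D1", "Infertility male"))
#' matches_term(rs, "  infertility MALE ")
matches_term <- function(rs, term) {
  stopifnot(inherits(rs, "report_set"))
  term <- normalize_name(term)
  if (length(term) != 1 || !nzchar(term)) {
    stop("'term' must be a single non-empty string", call. = FALSE)
  }
  vapply(rs$reports$reactions, function(r) term %in% r, FALSE)
}

# logical vector: report lists the drug among its suspects
is_suspect_of <- function(rs, drug) {
  drug <- normalize_name(drug)
  vapply(rs$reports$suspect_drugs, function(d) drug %in% d, FALSE)
}

# logical vector: report lists >= 1 concomitant medication
has_concomitant <- function(rs) {
  lengths(rs$reports$concomitant_drugs) > 0
}

# subset a report_set by a logical/integer index, keeping provenance
subset_reports <- function(rs, idx, provenance = rs$provenance) {
  structure(list(reports = rs$reports[idx, , drop = FALSE],
                 provenance = provenance),
            class = "report_set")
}
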