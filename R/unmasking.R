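# Concomitant-medication "unmasking" re-analysis.
#
# Co-reported products can distort a drug's disproportionality (masking /
# competition bias). The secondary analysis repeats the primary PRR
# computation per index drug after removing, from that drug's dataset, every
# report that lists at least one concomitant medication. Which specific
# co-product drives the distortion is not identified; the exclusion is
# deliberately blanket.

#' Exclude an index drug's concomitant-bearing reports
#'
#' Removes every report that (i) names `drug` among its suspects AND (ii)
#' lists at least one concomitant-role medication, of any kind. Reports not
#' involving the index drug as a suspect are untouched, so complement cells
#' are recomputed on the same reduced set and the partition invariant holds.
#' Additional suspect co-drugs do not trigger exclusion: the rule is about
#' concomitant medications only.
#'
#' @param rs A `report_set`.
#' @param drug Index drug name.
#' @return The reduced `report_set`, with attribute `n_excluded` giving the
#'   number of reports removed.
#' @export
exclude_concomitant_reports <- function(rs, drug) {
  stopifnot(inherits(rs, "report_set"))
  drop <- is_suspect_of(rs, drug) & has_concomitant(rs)
  out <- subset_reports(rs, !drop)
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Run the unmasking re-analysis
#'
#' For each drug (by default every drug the primary analysis flagged
#' non-`"NONE"`), recomputes the contingency table, PRR, confidence interval
#' and tier on the report set reduced by [exclude_concomitant_reports()].
#' A drug whose reduced index-term count `a` falls to 0 keeps a point
#' estimate of 0 with an `NA` interval and tier `"UNDEFINED"` (with a
#' warning); a drug whose reduced set makes the PRR itself undefined is
#' likewise flagged rather than crashing.
#'
#' @param rs A `report_set`.
#' @param term Index reaction term.
#' @param criteria A [signal_criteria()] object.
#' @param drugs Character vector of drugs to unmask; `NULL` selects the
#'   primary-significant drugs.
#' @return A tibble, one row per drug: crude columns (`prr_crude`,
#'   `ci_low_crude`, `ci_high_crude`, `tier_crude`, `a_crude`), unmasked
#'   columns (same, `_unmasked`), and `n_excluded`.
#' @export
run_unmasking <- function(rs, term, criteria = signal_criteria(),
                          drugs = NULL) {
  stopifnot(inherits(rs, "report_set"))
  if (is.null(drugs)) {
    primary <- run_primary_analysis(rs, term, criteria)
    drugs <- primary$drug[primary$signal_tier != "NONE"]
  }
  drugs <- normalize_name(drugs)
  rows <- lapply(drugs, function(drug) {
    crude_t <- build_contingency(rs, drug, term)
    crude <- prr_row(crude_t, criteria)
    reduced <- exclude_concomitant_reports(rs, drug)
    red_t <- build_contingency(reduced, drug, term)
    unmasked <- prr_row(red_t, criteria)
    if (is.na(unmasked$tier) || unmasked$tier == "UNDEFINED") {
      warning(sprintf(
        "unmasked estimate undefined for %s (a=%d, a+b=%d, c=%d)",
        drug, red_t$a, red_t$a + red_t$b, red_t$c), call. = FALSE)
    }
    tibble::tibble(
      drug = drug,
      a_crude = crude_t$a, prr_crude = crude$prr,
      ci_low_crude = crude$ci_low, ci_high_crude = crude$ci_high,
      tier_crude = crude$tier,
      n_excluded = attr(reduced, "n_excluded"),
      a_unmasked = red_t$a, prr_unmasked = unmasked$prr,
      ci_low_unmasked = unmasked$ci_low, ci_high_unmasked = unmasked$ci_high,
      tier_unmasked = unmasked$tier,
      analysis_label = "UNMASKED")
  })
  out <- if (length(rows) == 0) {
    tibble::tibble(drug = character(), a_crude = integer(),
                   prr_crude = numeric(), ci_low_crude = numeric(),
                   ci_high_crude = numeric(), tier_crude = character(),
                   n_excluded = integer(), a_unmasked = integer(),
                   prr_unmasked = numeric(), ci_low_unmasked = numeric(),
                   ci_high_unmasked = numeric(), tier_unmasked = character(),
                   analysis_label = character())
  } else {
    do.call(rbind, rows)
  }
  structure(out, term = normalize_name(term), criteria = criteria)
}

# point estimate + CI + tier for one table, tolerating degenerate cells
prr_row <- function(t, criteria) {
  if (t$a + t$b == 0 || t$c == 0) {
    return(list(prr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                tier = "UNDEFINED"))
  }
  prr <- compute_prr(t)
  if (t$a == 0) {
    return(list(prr = prr, ci_low = NA_real_, ci_high = NA_real_,
                tier = "UNDEFINED"))
  }
  ci <- compute_prr_ci(t, criteria)
  list(prr = prr, ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
       tier = classify_signal(prr, ci[["ci_low"]], criteria))
}
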