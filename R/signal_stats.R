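# Disproportionality core: per-drug case counting, inclusion filter, 2x2
# contingency table, PRR with a log-normal Wald interval, tiered signal
# classification, and the assembled primary analysis.

#' Signal-detection thresholds
#'
#' Bundles every tunable threshold of the analysis. Defaults encode the
#' conventional screening rule: keep drugs with more than 10 index-term
#' cases (`min_reports = 11`), call a signal when the lower 95% confidence
#' bound of the PRR exceeds 1, and call it strong when additionally
#' PRR > 3.
#'
#' @param min_reports Minimum per-drug index-term case count for inclusion
#'   (a drug is kept when its count is `>= min_reports`).
#' @param prr_strong_cutoff PRR point-estimate cutoff for a strong signal.
#' @param prr_elevated_cutoff Lower-confidence-bound cutoff above which
#'   reporting is called disproportionate.
#' @param confidence_level Two-sided confidence level in (0, 1).
#' @return An object of class `signal_criteria`; `$z_value` holds the
#'   standard-normal quantile implied by `confidence_level`.
#' @export
#' @examples
#' signal_criteria()                   # screening defaults
#' signal_criteria(min_reports = 1)    # no inclusion filter
signal_criteria <- function(min_reports = 11L,
                            prr_strong_cutoff = 3,
                            prr_elevated_cutoff = 1,
                            confidence_level = 0.95) {
  stopifnot(length(min_reports) == 1, min_reports >= 1,
            prr_strong_cutoff > 0, prr_elevated_cutoff > 0,
            confidence_level > 0, confidence_level < 1)
  structure(
    list(min_reports = as.integer(min_reports),
         prr_strong_cutoff = prr_strong_cutoff,
         prr_elevated_cutoff = prr_elevated_cutoff,
         confidence_level = confidence_level,
         z_value = stats::qnorm(1 - (1 - confidence_level) / 2)),
    class = "signal_criteria")
}

#' @export
print.signal_criteria <- function(x, ...) {
  cat(sprintf(paste0("<signal_criteria> min_reports=%d, strong PRR>%g, ",
                     "signal lower CI>%g, confidence=%g%% (z=%.4f)\n"),
              x$min_reports, x$prr_strong_cutoff, x$prr_elevated_cutoff,
              100 * x$confidence_level, x$z_value))
  invisible(x)
}

#' Count index-term cases per suspect drug
#'
#' For every drug appearing as a suspect in at least one report matching
#' `term`, counts the number of distinct matching reports in which it is a
#' suspect. The counting unit is the individual case: a report with k
#' suspect drugs contributes one case to each of the k drugs, so counts may
#' sum to more than the number of distinct matching reports.
#'
#' @param rs A `report_set`.
#' @param term Index reaction term.
#' @return Named integer vector, sorted by decreasing count then name.
#' @export
count_term_cases <- function(rs, term) {
  hit <- matches_term(rs, term)
  drugs <- unlist(rs$reports$suspect_drugs[hit])
  if (length(drugs) == 0) {
    return(stats::setNames(integer(), character()))
  }
  # a drug mentioned twice as suspect in one report still counts once
  ids <- rep(rs$reports$report_id[hit],
             lengths(rs$reports$suspect_drugs[hit]))
  counts <- table(drugs[!duplicated(paste0(ids, "\r", drugs))])
  counts <- stats::setNames(as.integer(counts), names(counts))
  counts[order(-counts, names(counts))]
}

#' Apply the minimum-report inclusion filter
#'
#' @param counts Named integer vector from [count_term_cases()].
#' @param criteria A [signal_criteria()] object.
#' @return The entries with count `>= criteria$min_reports`, ordered by
#'   decreasing count then name.
#' @export
filter_min_reports <- function(counts, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  kept <- counts[counts >= criteria$min_reports]
  kept[order(-kept, names(kept))]
}

#' Build the 2x2 contingency table for one (drug, term) pair
#'
#' Cells partition the report set: `a` = cases with the index drug as a
#' suspect and the index term among the reactions; `b` = index-drug cases
#' with any other adverse event only; `c` = index-term cases not naming the
#' drug as a suspect; `d` = all remaining cases. Concomitant mentions of the
#' index drug do not count towards `a`/`b`.
#'
#' @param rs A `report_set`.
#' @param drug Index drug name (normalized internally).
#' @param term Index reaction term.
#' @return An object of class `contingency_table` with fields `a`, `b`, `c`,
#'   `d`, `drug`, `term`, `n_reports`.
#' @export
build_contingency <- function(rs, drug, term) {
  stopifnot(nzchar(drug))
  exposed <- is_suspect_of(rs, drug)
  hit <- matches_term(rs, term)
  structure(
    list(a = sum(exposed & hit), b = sum(exposed & !hit),
         c = sum(!exposed & hit), d = sum(!exposed & !hit),
         drug = normalize_name(drug), term = normalize_name(term),
         n_reports = n_reports(rs)),
    class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %s x %s\n", x$drug, x$term))
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("index drug", "other drugs"),
                              c("index term", "other ADR")))
  print(m)
  invisible(x)
}

#' Proportional reporting ratio
#'
#' PRR = (a / (a + b)) / (c / (c + d)): the proportion of the index drug's
#' cases that mention the index term, relative to the same proportion among
#' all remaining drugs. No continuity correction is applied: a zero
#' denominator cell is an explicit error, never silently adjusted.
#'
#' @param t A `contingency_table`.
#' @return Non-negative finite number (0 when `a = 0`).
#' @export
#' @examples
#' t <- structure(list(a = 10, b = 90, c = 90, d = 9810),
#'                class = "contingency_table")
#' compute_prr(t)  # 11
compute_prr <- function(t) {
  if (t$a + t$b == 0) {
    stop("PRR undefined: a + b = 0 (drug never reported)", call. = FALSE)
  }
  if (t$c == 0) {
    stop("PRR undefined: c = 0 (index term exclusive to the drug)",
         call. = FALSE)
  }
  (t$a / (t$a + t$b)) / (t$c / (t$c + t$d))
}

#' Confidence interval for the PRR
#'
#' Log-normal Wald interval: `exp(log(PRR) +/- z * se)` with
#' `se = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`, the standard error of the log
#' ratio of two binomial proportions.
#'
#' @param t A `contingency_table` with `a > 0` and `c > 0`.
#' @param criteria A [signal_criteria()] supplying the confidence level.
#' @return Numeric vector `c(ci_low, ci_high)` bracketing the point estimate.
#' @export
compute_prr_ci <- function(t, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  if (t$a == 0 || t$c == 0) {
    stop("CI undefined: requires a > 0 and c > 0", call. = FALSE)
  }
  prr <- compute_prr(t)
  se <- sqrt(1 / t$a - 1 / (t$a + t$b) + 1 / t$c - 1 / (t$c + t$d))
  z <- criteria$z_value
  c(ci_low = exp(log(prr) - z * se), ci_high = exp(log(prr) + z * se))
}

#' Classify a drug's signal tier
#'
#' `"STRONG"` when PRR exceeds the strong cutoff and the lower confidence
#' bound exceeds the elevated cutoff; `"DISPROPORTIONATE"` when only the
#' lower bound clears the cutoff; `"NONE"` otherwise. Inverse (protective)
#' associations, whose whole interval lies below 1, classify as `"NONE"`.
#' Vectorised over `prr`/`ci_low`.
#'
#' @param prr PRR point estimate(s).
#' @param ci_low Lower confidence bound(s).
#' @param criteria A [signal_criteria()] object.
#' @return Character vector over `{"NONE", "DISPROPORTIONATE", "STRONG"}`
#'   (`NA` where either input is `NA`).
#' @export
#' @examples
#' classify_signal(16.04, 12.67)  # STRONG
#' classify_signal(1.72, 1.20)    # DISPROPORTIONATE
#' classify_signal(0.51, 0.30)    # NONE (protective)
classify_signal <- function(prr, ci_low, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"),
            length(prr) == length(ci_low))
  ifelse(is.na(prr) | is.na(ci_low), NA_character_,
         ifelse(ci_low > criteria$prr_elevated_cutoff,
                ifelse(prr > criteria$prr_strong_cutoff,
                       "STRONG", "DISPROPORTIONATE"),
                "NONE"))
}

#' Run the primary disproportionality analysis
#'
#' Full pipeline for one index term: count cases per suspect drug, apply the
#' minimum-report filter, and compute the contingency table, PRR, confidence
#' interval and signal tier for each surviving drug. The per-drug percentage
#' column uses the number of distinct analyzed cases (reports matching the
#' term that involve at least one included drug) as its denominator, so
#' percentages of multi-suspect reports can sum above 100.
#'
#' @param rs A non-empty `report_set`.
#' @param term Index reaction term.
#' @param criteria A [signal_criteria()] object.
#' @return A tibble with one row per included drug, sorted by decreasing case
#'   count then name: `drug`, `n_cases`, `pct_cases`, `a`, `b`, `c`, `d`,
#'   `prr`, `ci_low`, `ci_high`, `signal_tier`, `analysis_label`.
#'   Attributes `term`, `criteria`, `n_reports` (database size),
#'   `n_term_reports` (all index-term cases) and `n_analyzed_reports`
#'   (distinct cases behind the included drugs) record the denominators.
#' @export
run_primary_analysis <- function(rs, term, criteria = signal_criteria()) {
  stopifnot(inherits(rs, "report_set"))
  if (n_reports(rs) == 0) stop("report set is empty", call. = FALSE)
  counts <- count_term_cases(rs, term)
  kept <- filter_min_reports(counts, criteria)
  hit <- matches_term(rs, term)
  if (length(kept) == 0) {
    message(sprintf("no drug reaches %d reports for term '%s'",
                    criteria$min_reports, term))
  }
  analyzed <- hit & vapply(rs$reports$suspect_drugs,
                           function(d) any(d %in% names(kept)), FALSE)
  rows <- lapply(names(kept), function(drug) {
    t <- build_contingency(rs, drug, term)
    prr <- compute_prr(t)
    ci <- if (t$a > 0) compute_prr_ci(t, criteria) else
      c(ci_low = NA_real_, ci_high = NA_real_)
    tibble::tibble(
      drug = drug, n_cases = t$a,
      pct_cases = share_of_total(t$a, max(sum(analyzed), 1L), 2),
      a = t$a, b = t$b, c = t$c, d = t$d,
      prr = prr, ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
      signal_tier = classify_signal(prr, ci[["ci_low"]], criteria),
      analysis_label = "PRIMARY")
  })
  out <- if (length(rows) == 0) {
    tibble::tibble(drug = character(), n_cases = integer(),
                   pct_cases = numeric(), a = integer(), b = integer(),
                   c = integer(), d = integer(), prr = numeric(),
                   ci_low = numeric(), ci_high = numeric(),
                   signal_tier = character(), analysis_label = character())
  } else {
    do.call(rbind, rows)
  }
  structure(out, term = normalize_name(term), criteria = criteria,
            n_reports = n_reports(rs), n_term_reports = sum(hit),
            n_analyzed_reports = sum(analyzed))
}
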