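# Descriptive summaries: shares of totals, categorical breakdowns (reporter
# type, reason for use, country, year), mean ages, yearly term counts.

BREAKDOWN_DIMENSIONS <- c("REPORTER_TYPE", "REASON_FOR_USE", "COUNTRY",
                          "YEAR")

#' Percentage share with half-away-from-zero rounding
#'
#' `100 * count / denominator`, rounded half away from zero to `decimals`
#' places (the rounding convention of printed epidemiological tables; R's
#' own `round()` rounds half to even and would turn 2.675% into 2.67%).
#'
#' @param count Non-negative numerator(s).
#' @param denominator Positive denominator.
#' @param decimals Number of decimal places.
#' @return Numeric vector of percentages.
#' @export
#' @examples
#' share_of_total(86, 408, 2)   # 21.08
#' share_of_total(408, 955, 1)  # 42.7
share_of_total <- function(count, denominator, decimals = 1) {
  if (length(denominator) != 1 || is.na(denominator) || denominator <= 0) {
    stop("share undefined: denominator must be a single positive number",
         call. = FALSE)
  }
  stopifnot(all(count >= 0, na.rm = TRUE))
  round_half_away(100 * count / denominator, decimals)
}

# round half away from zero; tiny epsilon absorbs float artifacts such as
# 823.4999999999999 standing in for 823.5
round_half_away <- function(x, decimals) {
  p <- 10^decimals
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Categorical breakdown of a report set
#'
#' Tabulates reports along one dimension, optionally restricted to the
#' reports naming `drug` as a suspect. Missing values form their own
#' `"UNKNOWN"` row; the percentage denominator is always the scoped report
#' count, so rows sum to 100 (up to rounding). For `"REASON_FOR_USE"` a
#' `drug` scope is required, and the tallied label is the reason attached to
#' that drug's suspect mention.
#'
#' @param rs A `report_set`.
#' @param dimension One of `"REPORTER_TYPE"`, `"REASON_FOR_USE"`,
#'   `"COUNTRY"`, `"YEAR"`.
#' @param drug Optional suspect-drug scope.
#' @param decimals Decimal places for the percent column.
#' @return An object of class `breakdown_table`: list with `dimension`,
#'   `scope`, `denominator` and `rows` (tibble `label`, `count`, `percent`,
#'   sorted by decreasing count then label).
#' @export
breakdown <- function(rs, dimension, drug = NULL, decimals = 1) {
  stopifnot(inherits(rs, "report_set"))
  dimension <- match.arg(toupper(dimension), BREAKDOWN_DIMENSIONS)
  in_scope <- if (is.null(drug)) rep(TRUE, n_reports(rs)) else
    is_suspect_of(rs, drug)
  tbl <- rs$reports[in_scope, , drop = FALSE]
  labels <- switch(dimension,
    REPORTER_TYPE = tbl$reporter_type,
    COUNTRY = tbl$country,
    YEAR = as.character(tbl$event_year),
    REASON_FOR_USE = {
      if (is.null(drug)) {
        stop("REASON_FOR_USE breakdown requires a drug scope", call. = FALSE)
      }
      dn <- normalize_name(drug)
      vapply(seq_len(nrow(tbl)), function(i) {
        tbl$reasons_for_use[[i]][match(dn, tbl$suspect_drugs[[i]])]
      }, NA_character_)
    })
  labels[is.na(labels)] <- "UNKNOWN"
  denom <- nrow(tbl)
  if (denom == 0) {
    warning("empty scope: denominator is 0", call. = FALSE)
    rows <- tibble::tibble(label = character(), count = integer(),
                           percent = numeric())
  } else {
    counts <- table(labels)
    rows <- tibble::tibble(
      label = names(counts),
      count = as.integer(counts),
      percent = share_of_total(as.integer(counts), denom, decimals))
    rows <- rows[order(-rows$count, rows$label), ]
  }
  structure(list(dimension = dimension,
                 scope = if (is.null(drug)) NA_character_ else
                   normalize_name(drug),
                 denominator = denom, rows = rows),
            class = "breakdown_table")
}

#' @export
print.breakdown_table <- function(x, ...) {
  cat(sprintf("<breakdown_table> %s%s, denominator = %d\n", x$dimension,
              if (is.na(x$scope)) "" else paste0(" [", x$scope, "]"),
              x$denominator))
  print(x$rows)
  invisible(x)
}

#' Mean patient age over reports with a recorded age
#'
#' Ages are never imputed: the mean is taken over reports where age is
#' specified, within the optional suspect-drug scope.
#'
#' @param rs A `report_set`.
#' @param drug Optional suspect-drug scope.
#' @param decimals Decimal places (half-away-from-zero).
#' @return The rounded mean age, or `NA_real_` when no report in scope
#'   carries an age.
#' @export
#' @examples
#' rs <- report_set(list(aer_report("R1", "D", "X", age_years = 40),
#'                       aer_report("R2", "D", "X", age_years = 48.4)))
#' mean_age(rs)  # 44.2
mean_age <- function(rs, drug = NULL, decimals = 1) {
  stopifnot(inherits(rs, "report_set"))
  in_scope <- if (is.null(drug)) rep(TRUE, n_reports(rs)) else
    is_suspect_of(rs, drug)
  ages <- rs$reports$age_years[in_scope]
  ages <- ages[!is.na(ages)]
  if (length(ages) == 0) return(NA_real_)
  round_half_away(mean(ages), decimals)
}

#' Index-term reports per event year
#'
#' @param rs A `report_set`.
#' @param term Index reaction term.
#' @return Named integer vector mapping year to count of term-matching
#'   reports, ascending by year; reports without an event year are omitted,
#'   and years with no report are absent rather than zero.
#' @export
yearly_counts <- function(rs, term) {
  hit <- matches_term(rs, term)
  years <- rs$reports$event_year[hit]
  years <- years[!is.na(years)]
  if (length(years) == 0) {
    return(stats::setNames(integer(), character()))
  }
  counts <- table(years)
  stats::setNames(as.integer(counts), names(counts))
}
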