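# End-to-end orchestration: read -> primary analysis -> unmasking ->
# descriptive breakdowns -> artifact files + run manifest. The thin
# command-line wrapper in inst/scripts/prr-pipeline.R drives this function.

#' Configure an end-to-end analysis run
#'
#' @param input Path to a report file, or a `report_set` already in memory.
#' @param format `"csv"` or `"jsonl"` (ignored for in-memory input).
#' @param term Index reaction term.
#' @param out_dir Output directory (created if absent).
#' @param criteria A [signal_criteria()] object.
#' @param unmask `"significant"` (unmask the primary-significant drugs,
#'   the default), `"all"` (every included drug), or `"none"`.
#' @param seed Integer recorded in the manifest (and the only seed any
#'   generation step may use).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(input, format = "csv",
                            term = "Infertility male",
                            out_dir = ".",
                            criteria = signal_criteria(),
                            unmask = c("significant", "all", "none"),
                            seed = 1L) {
  stopifnot(nzchar(term), inherits(criteria, "signal_criteria"))
  structure(list(input = input, format = format, term = term,
                 out_dir = out_dir, criteria = criteria,
                 unmask = match.arg(unmask), seed = as.integer(seed)),
            class = "analysis_config")
}

#' Run the full analysis pipeline and write its artifacts
#'
#' Writes into `cfg$out_dir`:
#' \itemize{
#'   \item `signal_table.tsv` -- one row per included drug (case count,
#'     percentage of analyzed cases, PRR, confidence bounds, tier);
#'   \item `unmasking.tsv` -- crude vs unmasked PRR per unmasked drug
#'     (unless `unmask = "none"`);
#'   \item `breakdown_reporter_type.csv`, `breakdown_country.csv`,
#'     `yearly_counts.csv` -- database-wide descriptives;
#'   \item `drug_summaries.csv` -- per included drug: mean age and the
#'     modal stated reason for use;
#'   \item `manifest.json` -- term, every threshold actually used, report
#'     counts, seed, provenance and package version.
#' }
#'
#' @param cfg An [analysis_config()].
#' @return Invisibly, a list with the primary results, unmasking results,
#'   and the paths written.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  rs <- if (inherits(cfg$input, "report_set")) cfg$input else
    read_reports(cfg$input, cfg$format)
  if (!dir.exists(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE)
  }
  paths <- list()
  primary <- run_primary_analysis(rs, cfg$term, cfg$criteria)
  tab <- as.data.frame(primary)
  tab$prr <- round_half_away(tab$prr, 2)
  tab$ci_low <- round_half_away(tab$ci_low, 2)
  tab$ci_high <- round_half_away(tab$ci_high, 2)
  paths$signal_table <- file.path(cfg$out_dir, "signal_table.tsv")
  utils::write.table(tab, paths$signal_table, sep = "\t",
                     row.names = FALSE, quote = FALSE)

  unmasking <- NULL
  if (cfg$unmask != "none" && nrow(primary) > 0) {
    drugs <- if (cfg$unmask == "all") primary$drug else
      primary$drug[primary$signal_tier != "NONE"]
    unmasking <- run_unmasking(rs, cfg$term, cfg$criteria, drugs)
    um <- as.data.frame(unmasking)
    for (col in grep("^(prr|ci)_", names(um), value = TRUE)) {
      um[[col]] <- round_half_away(um[[col]], 2)
    }
    paths$unmasking <- file.path(cfg$out_dir, "unmasking.tsv")
    utils::write.table(um, paths$unmasking, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }

  write_breakdown <- function(dim, file) {
    b <- breakdown(rs, dim)
    p <- file.path(cfg$out_dir, file)
    utils::write.csv(as.data.frame(b$rows), p, row.names = FALSE)
    p
  }
  paths$reporter_type <- write_breakdown("REPORTER_TYPE",
                                         "breakdown_reporter_type.csv")
  paths$country <- write_breakdown("COUNTRY", "breakdown_country.csv")
  yc <- yearly_counts(rs, cfg$term)
  paths$yearly <- file.path(cfg$out_dir, "yearly_counts.csv")
  utils::write.csv(data.frame(year = names(yc), count = unname(yc)),
                   paths$yearly, row.names = FALSE)

  summaries <- do.call(rbind, lapply(primary$drug, function(drug) {
    reasons <- breakdown(rs, "REASON_FOR_USE", drug = drug)
    stated <- reasons$rows[reasons$rows$label != "UNKNOWN", ]
    data.frame(drug = drug,
               mean_age = mean_age(rs, drug),
               top_reason = if (nrow(stated) > 0) stated$label[1] else NA,
               top_reason_n = if (nrow(stated) > 0) stated$count[1] else
                 NA_integer_)
  }))
  paths$drug_summaries <- file.path(cfg$out_dir, "drug_summaries.csv")
  utils::write.csv(summaries %||% data.frame(), paths$drug_summaries,
                   row.names = FALSE)

  manifest <- list(
    term = cfg$term,
    min_reports = cfg$criteria$min_reports,
    prr_strong_cutoff = cfg$criteria$prr_strong_cutoff,
    prr_elevated_cutoff = cfg$criteria$prr_elevated_cutoff,
    confidence_level = cfg$criteria$confidence_level,
    unmask = cfg$unmask,
    seed = cfg$seed,
    n_reports = n_reports(rs),
    n_term_reports = attr(primary, "n_term_reports"),
    n_analyzed_reports = attr(primary, "n_analyzed_reports"),
    n_included_drugs = nrow(primary),
    provenance = rs$provenance,
    package_version = as.character(utils::packageVersion("prrsignal"))
  )
  paths$manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  invisible(list(primary = primary, unmasking = unmasking, paths = paths))
}
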