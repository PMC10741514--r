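# On-disk dialects for report sets.
#
# CSV: UTF-8, header row, one row per individual case, multi-valued cells
# joined with "|", reasons_for_use aligned positionally with suspect_drugs
# ("" = unknown). JSONL: one JSON object per line with drugs as a list of
# {name, role, reason_for_use} objects. Both round-trip losslessly.

CSV_COLUMNS <- c("report_id", "suspect_drugs", "concomitant_drugs",
                 "reactions", "reasons_for_use", "seriousness", "event_year",
                 "sex", "age_years", "weight_kg", "reporter_type", "country",
                 "has_literature_ref")
FIELD_SEP <- "|"

#' Read a report set from disk
#'
#' Parses the documented CSV or JSON-lines dialect into a validated
#' [report_set()]. An empty file yields an empty report set; a missing
#' mandatory column, a duplicated `report_id`, or rows violating the
#' data-model invariants abort with a message naming the offending
#' column/rows (set `on_invalid = "drop"` to instead drop bad rows with a
#' warning summarising the per-row problems).
#'
#' @param path Path to an existing file.
#' @param format `"csv"` or `"jsonl"` (case-insensitive).
#' @param on_invalid `"error"` (default) or `"drop"`.
#' @return A `report_set` whose provenance records `path`.
#' @export
read_reports <- function(path, format = c("csv", "jsonl"),
                         on_invalid = c("error", "drop")) {
  format <- tolower(format)
  format <- match.arg(format)
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) {
    stop(sprintf("input file does not exist: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0 || (format == "csv" && length(lines) == 1)) {
    return(report_set(NULL, provenance = path))
  }
  tbl <- if (format == "csv") parse_csv_reports(path) else
    parse_jsonl_reports(lines)

  dup <- unique(tbl$report_id[duplicated(tbl$report_id)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate report_id value(s): %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  problems <- report_problems(tbl)
  if (nrow(problems) > 0) {
    if (on_invalid == "drop") {
      warning(sprintf("dropping %d invalid row(s): %s",
                      length(unique(problems$row)),
                      paste(sprintf("row %d [%s] %s", problems$row,
                                    problems$field, problems$message),
                            collapse = "; ")), call. = FALSE)
      tbl <- tbl[-unique(problems$row), , drop = FALSE]
    } else {
      msg <- paste(sprintf("row %d [%s]: %s", problems$row, problems$field,
                           problems$message), collapse = "\n  ")
      stop(sprintf("%d invalid report row(s) in %s:\n  %s",
                   length(unique(problems$row)), path, msg), call. = FALSE)
    }
  }
  report_set(tbl, provenance = path)
}

parse_csv_reports <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character(), fileEncoding = "UTF-8")
  missing_cols <- setdiff(CSV_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("CSV is missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  split_multi <- function(x) {
    lapply(x, function(cell) {
      if (!nzchar(cell)) character() else
        strsplit(cell, FIELD_SEP, fixed = TRUE)[[1]]
    })
  }
  blank_na <- function(x) ifelse(nzchar(x), x, NA_character_)
  suspects <- lapply(split_multi(raw$suspect_drugs), normalize_name)
  reasons <- lapply(seq_along(suspects), function(i) {
    cell <- raw$reasons_for_use[i]
    r <- if (!nzchar(cell)) character() else
      strsplit(cell, FIELD_SEP, fixed = TRUE)[[1]]
    # "" marks an unknown reason; pad so alignment with suspects holds even
    # when the cell omits trailing separators
    length(r) <- max(length(r), length(suspects[[i]]))
    r[is.na(r) | !nzchar(trimws(r))] <- NA_character_
    r
  })
  tibble::tibble(
    report_id = raw$report_id,
    suspect_drugs = suspects,
    concomitant_drugs = lapply(split_multi(raw$concomitant_drugs),
                               normalize_name),
    reasons_for_use = reasons,
    reactions = lapply(split_multi(raw$reactions), normalize_name),
    seriousness = blank_na(raw$seriousness),
    event_year = suppressWarnings(as.integer(blank_na(raw$event_year))),
    sex = blank_na(raw$sex),
    age_years = suppressWarnings(as.numeric(blank_na(raw$age_years))),
    weight_kg = suppressWarnings(as.numeric(blank_na(raw$weight_kg))),
    reporter_type = ifelse(nzchar(raw$reporter_type), raw$reporter_type,
                           "UNKNOWN"),
    country = blank_na(raw$country),
    has_literature_ref = tolower(raw$has_literature_ref) %in%
      c("true", "1", "t", "yes")
  )
}

parse_jsonl_reports <- function(lines) {
  rows <- lapply(lines, function(line) {
    obj <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    drugs <- obj$drugs %||% list()
    role <- vapply(drugs, function(d) toupper(d$role %||% ""), "")
    name <- vapply(drugs, function(d) as.character(d$name %||% ""), "")
    reason <- vapply(drugs, function(d) {
      r <- unlist(d$reason_for_use)
      if (length(r) != 1 || is.na(r) || !nzchar(trimws(as.character(r)))) {
        NA_character_
      } else {
        as.character(r)
      }
    }, "")
    sus <- role == "SUSPECT"
    aer_report(
      report_id = obj$report_id %||% "",
      suspect_drugs = name[sus],
      concomitant_drugs = name[!sus],
      reasons_for_use = if (any(sus)) reason[sus] else NULL,
      reactions = unlist(obj$reactions) %||% character(),
      seriousness = obj$seriousness %||% NA_character_,
      event_year = obj$event_year %||% NA_integer_,
      sex = obj$sex %||% NA_character_,
      age_years = obj$age_years %||% NA_real_,
      weight_kg = obj$weight_kg %||% NA_real_,
      reporter_type = obj$reporter_type %||% "UNKNOWN",
      country = obj$country %||% NA_character_,
      has_literature_ref = isTRUE(obj$has_literature_ref)
    )
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a report set to disk
#'
#' Inverse of [read_reports()]: the written file parses back to a report set
#' equal field-by-field, in the same order. An empty set writes a header-only
#' CSV / zero-line JSONL file.
#'
#' @param rs A validated `report_set`.
#' @param path Output file path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_reports <- function(rs, path, format = c("csv", "jsonl")) {
  format <- match.arg(tolower(format), c("csv", "jsonl"))
  validate_report_set(rs)
  tbl <- rs$reports
  if (format == "csv") {
    join <- function(col) vapply(col, paste, "", collapse = FIELD_SEP)
    na_blank <- function(x) ifelse(is.na(x), "", as.character(x))
    out <- data.frame(
      report_id = tbl$report_id,
      suspect_drugs = join(tbl$suspect_drugs),
      concomitant_drugs = join(tbl$concomitant_drugs),
      reactions = join(tbl$reactions),
      reasons_for_use = vapply(tbl$reasons_for_use, function(r) {
        paste(ifelse(is.na(r), "", r), collapse = FIELD_SEP)
      }, ""),
      seriousness = na_blank(tbl$seriousness),
      event_year = na_blank(tbl$event_year),
      sex = na_blank(tbl$sex),
      age_years = na_blank(tbl$age_years),
      weight_kg = na_blank(tbl$weight_kg),
      reporter_type = tbl$reporter_type,
      country = na_blank(tbl$country),
      has_literature_ref = ifelse(tbl$has_literature_ref, "true", "false"),
      check.names = FALSE
    )
    out <- out[, CSV_COLUMNS]
    utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8",
                     quote = TRUE)
  } else {
    lines <- vapply(seq_len(nrow(tbl)), function(i) {
      sus <- tbl$suspect_drugs[[i]]
      conc <- tbl$concomitant_drugs[[i]]
      reas <- tbl$reasons_for_use[[i]]
      drugs <- c(
        lapply(seq_along(sus), function(j) {
          d <- list(name = sus[j], role = "SUSPECT")
          if (!is.na(reas[j])) d$reason_for_use <- reas[j]
          d
        }),
        lapply(conc, function(nm) list(name = nm, role = "CONCOMITANT"))
      )
      obj <- list(
        report_id = tbl$report_id[i],
        drugs = drugs,
        reactions = as.list(tbl$reactions[[i]]),
        seriousness = tbl$seriousness[i],
        event_year = tbl$event_year[i],
        sex = tbl$sex[i],
        age_years = tbl$age_years[i],
        weight_kg = tbl$weight_kg[i],
        reporter_type = tbl$reporter_type[i],
        country = tbl$country[i],
        has_literature_ref = tbl$has_literature_ref[i]
      )
      obj <- obj[!vapply(obj, function(v)
        length(v) == 1 && !is.list(v) && is.na(v), FALSE)]
      as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
    }, "")
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}
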