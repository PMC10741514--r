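test_that("drug names and reaction terms are normalized on construction", {
  r <- aer_report("R1", c("  finasteride ", "Amlodipine   Besylate"),
                  c(" infertility  male "), reasons_for_use = c("alopecia",
                                                                ""))
  expect_equal(r$suspect_drugs[[1]], c("FINASTERIDE", "AMLODIPINE BESYLATE"))
  expect_equal(r$reactions[[1]], "INFERTILITY MALE")
  expect_equal(r$reasons_for_use[[1]], c("alopecia", NA))
})

test_that("report-set invariants are enforced with row-level messages", {
  expect_error(report_set(list(aer_report("R1", "D1", "X"),
                               aer_report("R1", "D2", "Y"))),
               "duplicate report_id.*R1")
  expect_error(report_set(aer_report("R1", character(), "X")),
               "no suspect drug")
  expect_error(report_set(aer_report("R1", "D1", "X", age_years = 150)),
               "age_years")
  expect_error(report_set(aer_report("R1", "D1", "X", sex = "male")),
               "sex")
  expect_error(report_set(aer_report("R1", "D1", "X",
                                     reporter_type = "DOCTOR")),
               "reporter_type")
  expect_error(report_set(aer_report("R1", "D1", "X",
                                     reasons_for_use = c("a", "b"))),
               "aligned")
})

test_that("matches_term is exact-term, case- and whitespace-insensitive", {
  rs <- report_set(list(
    aer_report("R1", "D1", "Infertility male"),
    aer_report("R2", "D1", "Oligozoospermia"),
    aer_report("R3", "D1", c("Infertility male", "Alopecia"))
  ))
  expect_equal(matches_term(rs, "infertility male"), c(TRUE, FALSE, TRUE))
  expect_equal(matches_term(rs, "  INFERTILITY   MALE "),
               c(TRUE, FALSE, TRUE))
  # no substring/hierarchy matching: semen-parameter terms do not match MFI
  expect_false(matches_term(rs, "Infertility male")[2])
  expect_false(any(matches_term(rs, "Infertility")))
  expect_error(matches_term(rs, "  "), "non-empty")
})

test_that("drug_mentions exposes the long per-mention view with roles", {
  rs <- report_set(aer_report("R1", c("D1", "D2"), "X",
                              concomitant_drugs = "D3",
                              reasons_for_use = c("acne", NA)))
  m <- drug_mentions(rs)
  expect_equal(m$drug_name, c("D1", "D2", "D3"))
  expect_equal(m$role, c("SUSPECT", "SUSPECT", "CONCOMITANT"))
  expect_equal(m$reason_for_use, c("acne", NA, NA))
})

test_that("CSV and JSONL round trips are the identity on valid sets", {
  rs <- generate_reports(random_config(401, n_reports = 50))
  for (fmt in c("csv", "jsonl")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_reports(rs, path, fmt)
    back <- read_reports(path, fmt)
    expect_equal(back$reports, rs$reports)
  }
})

test_that("round trip preserves hand-built metadata field-by-field", {
  rs <- report_set(list(
    aer_report("R1", c("D1", "D2"), c("Infertility male", "Rash"),
               concomitant_drugs = c("D3", "D4"),
               reasons_for_use = c("alopecia", NA),
               seriousness = "SERIOUS", event_year = 1997L, sex = "M",
               age_years = 44.2, weight_kg = 81.5,
               reporter_type = "HEALTHCARE_PROFESSIONAL", country = "US",
               has_literature_ref = TRUE),
    aer_report("R2", "D1", "Headache")
  ))
  for (fmt in c("csv", "jsonl")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_reports(rs, path, fmt)
    expect_equal(read_reports(path, fmt)$reports, rs$reports)
  }
})

test_that("read_reports validates its input file", {
  rs3 <- report_set(list(aer_report("R1", "D1", "X"),
                         aer_report("R2", "D2", "Y"),
                         aer_report("R3", "D3", "Z")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_reports(rs3, path, "csv")
  expect_equal(n_reports(read_reports(path, "csv")), 3)

  # duplicate ids in the file
  lines <- readLines(path)
  lines[3] <- sub("R2", "R1", lines[3])
  writeLines(lines, path)
  expect_error(read_reports(path, "csv"), "duplicate report_id.*R1")

  # missing mandatory column named in the error
  writeLines(c("report_id,reactions", "R1,X"), path)
  expect_error(read_reports(path, "csv"), "suspect_drugs")

  # empty file is an empty set, not an error
  writeLines(character(), path)
  expect_equal(n_reports(read_reports(path, "csv")), 0)
  expect_error(read_reports(file.path(tempdir(), "nope.csv"), "csv"),
               "does not exist")
})

test_that("adversarial rows are rejected or dropped, never admitted", {
  # rows engineered to violate each invariant
  bad <- c(
    "report_id,suspect_drugs,concomitant_drugs,reactions,reasons_for_use,seriousness,event_year,sex,age_years,weight_kg,reporter_type,country,has_literature_ref",
    "B1,,,Headache,,,,,,,CONSUMER,,false",          # no suspect drug
    "B2,D1,,,,,,,,,CONSUMER,,false",                # no reaction
    "B3,D1,,Rash,,,,,200,,CONSUMER,,false",         # age out of range
    "B4,D1,,Rash,,,,X,,,CONSUMER,,false",           # bad sex code
    "G1,D1,,Rash,,,,M,44,,CONSUMER,US,true"         # valid
  )
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(bad, path)
  expect_error(read_reports(path, "csv"), "invalid report row")
  rs <- suppressWarnings(read_reports(path, "csv", on_invalid = "drop"))
  expect_equal(rs$reports$report_id, "G1")
  expect_silent(validate_report_set(rs))
})

test_that("empty sets and multi-valued cells use the documented dialect", {
  empty <- report_set()
  csv <- withr::local_tempfile(fileext = ".csv")
  jsonl <- withr::local_tempfile(fileext = ".jsonl")
  write_reports(empty, csv, "csv")
  write_reports(empty, jsonl, "jsonl")
  expect_length(readLines(csv), 1)   # header only
  expect_length(readLines(jsonl), 0)

  two <- report_set(aer_report("R1", c("D1", "D2"), "X"))
  write_reports(two, csv, "csv")
  expect_match(readLines(csv)[2], "D1|D2", fixed = TRUE)
})
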