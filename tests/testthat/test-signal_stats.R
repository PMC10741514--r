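test_that("count_term_cases counts individual cases per suspect drug", {
  rs <- report_set(list(
    aer_report("R1", "D1", MFI),
    aer_report("R2", c("D1", "D2"), MFI),
    aer_report("R3", "D2", "Headache")
  ))
  expect_equal(count_term_cases(rs, MFI), c(D1 = 2L, D2 = 1L))
  expect_length(count_term_cases(rs, "Agranulocytosis"), 0)
})

test_that("case counts match a brute-force double loop on synthetic data", {
  for (seed in c(11, 12)) {
    cfg <- random_config(seed, n_reports = 400)
    rs <- generate_reports(cfg)
    got <- count_term_cases(rs, cfg$index_term)
    want <- oracle_count_cases(rs, cfg$index_term)
    expect_mapequal(as.list(got), as.list(want))
  }
})

test_that("filter_min_reports keeps counts >= threshold, ordered", {
  counts <- c(X = 11L, Y = 10L, Z = 300L)
  expect_equal(filter_min_reports(counts, signal_criteria()),
               c(Z = 300L, X = 11L))
  expect_length(filter_min_reports(stats::setNames(integer(), character()),
                                   signal_criteria()), 0)
  expect_equal(filter_min_reports(counts,
                                  signal_criteria(min_reports = 1)),
               c(Z = 300L, X = 11L, Y = 10L))
})

test_that("build_contingency partitions the report set", {
  rs <- five_report_set()
  t <- build_contingency(rs, "D1", MFI)
  expect_equal(c(t$a, t$b, t$c, t$d), c(2, 1, 1, 1))
  # index drug absent: a = b = 0, c = all index-term reports
  t0 <- build_contingency(rs, "D99", MFI)
  expect_equal(c(t0$a, t0$b, t0$c, t0$d), c(0, 0, 3, 2))
  # cells partition any generated set; a + c equals the term total
  for (seed in c(21, 22, 23)) {
    cfg <- random_config(seed)
    rs <- generate_reports(cfg)
    for (drug in vapply(cfg$drugs, `[[`, "", "name")) {
      t <- build_contingency(rs, drug, cfg$index_term)
      expect_equal(t$a + t$b + t$c + t$d, n_reports(rs))
      expect_equal(t$a + t$c, sum(matches_term(rs, cfg$index_term)))
    }
  }
})

test_that("compute_prr follows the ratio-of-proportions formula", {
  tab <- function(a, b, c, d) {
    structure(list(a = a, b = b, c = c, d = d),
              class = "contingency_table")
  }
  expect_equal(compute_prr(tab(1, 9, 10, 90)), 1)
  expect_equal(compute_prr(tab(10, 90, 90, 9810)), 11)
  expect_equal(compute_prr(tab(0, 50, 100, 1000)), 0)
  expect_error(compute_prr(tab(0, 0, 5, 10)), "a \\+ b = 0")
  expect_error(compute_prr(tab(3, 7, 0, 10)), "c = 0")
  # PRR = 1 whenever the two proportions agree exactly
  expect_equal(compute_prr(tab(7, 14, 30, 60)), 1)
  # strict monotonicity in a with b, c, d fixed
  prrs <- vapply(1:20, function(a) compute_prr(tab(a, 50, 30, 900)), 0)
  expect_true(all(diff(prrs) > 0))
})

test_that("the log-normal Wald interval brackets the estimate", {
  tab <- function(a, b, c, d) {
    structure(list(a = a, b = b, c = c, d = d),
              class = "contingency_table")
  }
  ci <- compute_prr_ci(tab(10, 90, 90, 9810))
  want <- oracle_prr_ci(c(a = 10, b = 90, c = 90, d = 9810))
  expect_equal(unname(ci), unname(want), tolerance = 1e-12)
  expect_equal(round(unname(ci), 2), c(5.90, 20.51), tolerance = 1e-8)
  # symmetric null table straddles 1
  ci1 <- compute_prr_ci(tab(50, 450, 500, 4500))
  expect_lt(ci1[["ci_low"]], 1)
  expect_gt(ci1[["ci_high"]], 1)
  expect_error(compute_prr_ci(tab(0, 50, 10, 100)), "a > 0")
  # halving all cells (fixed ratios) widens the interval
  withr::with_seed(7, {
    for (i in 1:25) {
      cells <- 2L * sample.int(200, 4) # even so halving stays integral
      full <- compute_prr_ci(tab(cells[1], cells[2], cells[3], cells[4]))
      half <- compute_prr_ci(tab(cells[1] / 2, cells[2] / 2,
                                 cells[3] / 2, cells[4] / 2))
      expect_gt(half[["ci_high"]] / half[["ci_low"]],
                full[["ci_high"]] / full[["ci_low"]])
      # CI brackets the point estimate whenever defined
      prr <- compute_prr(tab(cells[1], cells[2], cells[3], cells[4]))
      expect_true(full[["ci_low"]] < prr && prr < full[["ci_high"]])
    }
  })
})

test_that("classify_signal reproduces the published tier examples", {
  expect_equal(classify_signal(16.04, 12.67), "STRONG")
  expect_equal(classify_signal(1.72, 1.20), "DISPROPORTIONATE")
  expect_equal(classify_signal(1.07, 0.66), "NONE")
  # protective association (whole interval below 1) is still NONE
  expect_equal(classify_signal(0.51, 0.30), "NONE")
  # vectorised, NA-propagating, cutoffs configurable
  expect_equal(classify_signal(c(5, NA), c(2, 1)), c("STRONG", NA))
  strict <- signal_criteria(prr_strong_cutoff = 20)
  expect_equal(classify_signal(16.04, 12.67, strict), "DISPROPORTIONATE")
})

test_that("run_primary_analysis assembles the per-drug table", {
  # constructed so exactly 3 drugs clear the default threshold
  reports <- c(
    lapply(1:12, function(i) aer_report(paste0("A", i), "DRUGA", MFI)),
    lapply(1:11, function(i) aer_report(paste0("B", i), "DRUGB", MFI)),
    lapply(1:15, function(i) aer_report(paste0("C", i), "DRUGC", MFI)),
    lapply(1:5, function(i) aer_report(paste0("D", i), "DRUGD", MFI)),
    lapply(1:60, function(i) aer_report(paste0("E", i), "DRUGE", "Rash"))
  )
  rs <- report_set(reports)
  res <- run_primary_analysis(rs, MFI)
  expect_equal(res$drug, c("DRUGC", "DRUGA", "DRUGB"))
  expect_equal(res$n_cases, c(15L, 12L, 11L))
  expect_equal(attr(res, "n_term_reports"), 43L)
  expect_equal(attr(res, "n_analyzed_reports"), 38L)
  expect_equal(res$pct_cases, share_of_total(c(15, 12, 11), 38, 2))
  expect_true(all(res$ci_low < res$prr & res$prr < res$ci_high))
  expect_equal(res$signal_tier,
               classify_signal(res$prr, res$ci_low, signal_criteria()))
  # a term with no matches yields an empty table with a notice
  expect_message(empty <- run_primary_analysis(rs, "Agranulocytosis"),
                 "no drug reaches")
  expect_equal(nrow(empty), 0)
})

test_that("the pipeline matches the brute-force oracle end-to-end", {
  cfg <- masking_scenario(n_reports = 4000, seed = 99)
  rs <- generate_reports(cfg)
  res <- run_primary_analysis(rs, cfg$index_term,
                              signal_criteria(min_reports = 3))
  expect_gt(nrow(res), 3)
  for (i in seq_len(nrow(res))) {
    cell <- oracle_contingency(rs, res$drug[i], cfg$index_term)
    expect_equal(c(res$a[i], res$b[i], res$c[i], res$d[i]), unname(cell))
    expect_equal(res$prr[i], oracle_prr(cell), tolerance = 1e-12)
  }
})
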