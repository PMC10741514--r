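# Fixture builders used across test files; everything is generated in code.

MFI <- "Infertility male"

# the 5-report enumeration set: R1(D1, MFI), R2(D1+D2, MFI), R3(D2, other),
# R4(D1, other), R5(D3, MFI)
five_report_set <- function() {
  report_set(list(
    aer_report("R1", "D1", MFI),
    aer_report("R2", c("D1", "D2"), MFI),
    aer_report("R3", "D2", "Headache"),
    aer_report("R4", "D1", "Rash"),
    aer_report("R5", "D3", MFI)
  ))
}

# small random synthetic config; seeds derived from a root so the suite is
# deterministic
random_config <- function(seed, n_reports = NULL) {
  withr::with_seed(seed, {
    k <- sample(3:6, 1)
    drugs <- lapply(seq_len(k), function(i) {
      drug_profile(paste0("DRUG", i),
                   exposure_weight = stats::runif(1, 0.3, 3),
                   event_rate_ratio = stats::runif(1, 0.2, 2.5),
                   concomitant_rate = stats::runif(1, 0, 0.6),
                   concomitant_event_boost = sample(c(1, 1, 2), 1))
    })
    synthetic_config(
      n_reports = n_reports %||% sample(50:500, 1),
      baseline_event_prob = stats::runif(1, 0.02, 0.15),
      drugs = drugs, seed = seed,
      multi_suspect_prob = sample(c(0, 0.3), 1))
  })
}

# Table 1's printed rows: drug, case count, PRR, lower and upper CI bound,
# and whether the row is bolded (significant) in print
table1_rows <- function() {
  tibble::tibble(
    drug = c("Finasteride", "Testosterone", "Valproic Acid",
             "Carbamazepine", "Sertraline", "Paroxetine", "Fluoxetine",
             "Minoxidil", "Diethylstilbestrol", "Amlodipine Besylate",
             "Verapamil", "Nifedipine", "Diltiazem Hydrochloride",
             "Isotretinoin", "Mechlorethamine", "Ranitidine",
             "Vincristine", "Prednisone", "Lovastatin",
             "Mycophenolate Mofetil"),
    n = c(86, 33, 32, 17, 29, 17, 15, 24, 20, 19, 14, 12, 11, 19, 17, 16,
          13, 13, 13, 11),
    prr = c(16.04, 3.03, 1.72, 1.07, 0.94, 0.92, 0.51, 0.95, 14.3, 0.69,
            1.83, 1.85, 1.49, 0.84, 58.71, 0.10, 1.12, 0.28, 2.51, 0.47),
    ci_low = c(12.67, 2.12, 1.20, 0.66, 0.64, 0.56, 0.30, 0.62, 9.13,
               0.43, 1.07, 1.04, 0.82, 0.53, 36.30, 0.06, 0.65, 0.16,
               1.44, 0.26),
    bold = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
             FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
             TRUE, FALSE)
  )
}
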