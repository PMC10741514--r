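# Seeded generator of FAERS-like spontaneous report databases with known
# ground truth.
#
# Each synthetic report draws one suspect drug from multinomial exposure
# weights; with a per-drug probability it also lists one concomitant
# medication (uniform over the other roster names). The index reaction term
# is included with probability pi0 * rho_drug, multiplied by a per-drug
# boost when a concomitant is present -- the boost is what creates the
# masking/confounding structure that the unmasking analysis removes.
# Non-index ("filler") reactions come from a small fixed vocabulary and only
# populate the b/d cells. Every stochastic component draws from its own
# seed stream, so adding a metadata field never perturbs the event draws.

FILLER_REACTIONS <- c("Headache", "Nausea", "Dizziness", "Rash", "Fatigue",
                      "Insomnia", "Pruritus", "Vomiting", "Arthralgia",
                      "Alopecia")

#' Describe one drug of a synthetic roster
#'
#' @param name Drug name.
#' @param exposure_weight Positive multinomial weight for being the suspect
#'   drug of a report.
#' @param event_rate_ratio Multiplier `rho` on the baseline index-term
#'   probability when this drug is the suspect; the drug's concomitant-free
#'   reporting rate is `pi0 * rho`.
#' @param concomitant_rate Probability `q` in \[0, 1\] that a report of this
#'   drug lists a concomitant medication.
#' @param concomitant_event_boost Multiplier `>= 1` on the index-term
#'   probability when a concomitant is present; values above 1 make the
#'   crude PRR exceed the concomitant-free PRR (a masking confounder).
#' @param reason_labels Named probability vector over reason-for-use strings
#'   for this drug's suspect mentions; probabilities may sum to less than 1
#'   and the remainder is "reason not specified". `NULL` = always
#'   unspecified.
#' @param age_mean,age_sd Optional per-drug age distribution overriding the
#'   config-level one.
#' @return A `drug_profile` list.
#' @export
drug_profile <- function(name, exposure_weight = 1, event_rate_ratio = 1,
                         concomitant_rate = 0, concomitant_event_boost = 1,
                         reason_labels = NULL, age_mean = NA_real_,
                         age_sd = NA_real_) {
  stopifnot(nzchar(name), exposure_weight > 0, event_rate_ratio > 0,
            concomitant_rate >= 0, concomitant_rate <= 1,
            concomitant_event_boost >= 1)
  if (!is.null(reason_labels)) {
    stopifnot(is.numeric(reason_labels), !is.null(names(reason_labels)),
              all(nzchar(names(reason_labels))), all(reason_labels >= 0),
              sum(reason_labels) <= 1 + 1e-12)
  }
  structure(list(name = normalize_name(name),
                 exposure_weight = exposure_weight,
                 event_rate_ratio = event_rate_ratio,
                 concomitant_rate = concomitant_rate,
                 concomitant_event_boost = concomitant_event_boost,
                 reason_labels = reason_labels,
                 age_mean = age_mean, age_sd = age_sd),
            class = "drug_profile")
}

#' Configure a synthetic report database
#'
#' @param n_reports Number of reports to generate.
#' @param baseline_event_prob Baseline index-term probability `pi0`; the
#'   per-report probability is `pi0 * rho * (boost when concomitant)` and
#'   the config is rejected when that product can exceed 1.
#' @param drugs List of [drug_profile()] objects (>= 1; >= 2 if any profile
#'   has a positive concomitant rate).
#' @param seed Integer root seed; all component streams derive from it.
#' @param index_term Index reaction term the generator plants.
#' @param reporter_type_dist,country_dist Named probability vectors for the
#'   report metadata.
#' @param sex_dist Named probability vector over `M`/`F`/`UNKNOWN`.
#' @param year_range Integer vector of candidate event years (uniform).
#' @param age_mean,age_sd Default age distribution (normal, clamped to
#'   \[0, 130\]).
#' @param age_missing,weight_missing Probability that age/weight is absent.
#' @param literature_ref_prob Probability a report carries a literature
#'   reference.
#' @param extra_reaction_prob Probability of one additional filler reaction.
#' @param multi_suspect_prob Probability a report carries a second suspect
#'   drug. Default 0 so [true_prr()] has a clean closed form; the switch
#'   exists solely to exercise the case-counting convention.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_reports, baseline_event_prob, drugs, seed,
                             index_term = "Infertility male",
                             reporter_type_dist = c(
                               CONSUMER = 0.55,
                               HEALTHCARE_PROFESSIONAL = 0.40,
                               UNKNOWN = 0.05),
                             country_dist = c(US = 0.65, GB = 0.10,
                                              IT = 0.07, CA = 0.06,
                                              FR = 0.06, DE = 0.06),
                             sex_dist = c(M = 0.95, UNKNOWN = 0.05),
                             year_range = 1981:2021,
                             age_mean = 40, age_sd = 12,
                             age_missing = 0.35, weight_missing = 0.6,
                             literature_ref_prob = 0.09,
                             extra_reaction_prob = 0.2,
                             multi_suspect_prob = 0) {
  stopifnot(n_reports >= 1, baseline_event_prob >= 0,
            baseline_event_prob <= 1, length(drugs) >= 1,
            all(vapply(drugs, inherits, TRUE, "drug_profile")),
            length(seed) == 1, is.finite(seed))
  rho <- vapply(drugs, `[[`, 1, "event_rate_ratio")
  boost <- vapply(drugs, `[[`, 1, "concomitant_event_boost")
  q <- vapply(drugs, `[[`, 1, "concomitant_rate")
  if (baseline_event_prob * max(rho * pmax(boost, 1)) > 1) {
    stop("invalid config: pi0 * rho * boost exceeds 1 for some drug",
         call. = FALSE)
  }
  if (any(q > 0) && length(drugs) < 2) {
    stop(paste("invalid config: a concomitant cannot be drawn from a",
               "single-drug roster"), call. = FALSE)
  }
  nm <- vapply(drugs, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate drug names", call. = FALSE)
  for (d in c("reporter_type_dist", "country_dist", "sex_dist")) {
    v <- get(d)
    stopifnot(is.numeric(v), !is.null(names(v)), all(v >= 0), sum(v) > 0)
  }
  structure(list(n_reports = as.integer(n_reports),
                 baseline_event_prob = baseline_event_prob, drugs = drugs,
                 seed = as.integer(seed), index_term = index_term,
                 reporter_type_dist = reporter_type_dist,
                 country_dist = country_dist, sex_dist = sex_dist,
                 year_range = as.integer(year_range),
                 age_mean = age_mean, age_sd = age_sd,
                 age_missing = age_missing,
                 weight_missing = weight_missing,
                 literature_ref_prob = literature_ref_prob,
                 extra_reaction_prob = extra_reaction_prob,
                 multi_suspect_prob = multi_suspect_prob),
            class = "synthetic_config")
}

# independent seed stream per stochastic component
component_seed <- function(root, k) {
  as.integer((abs(root) %% 2096999L) * 1000L + k)
}

with_stream <- function(cfg, k, expr) {
  withr::with_seed(component_seed(cfg$seed, k), expr)
}

#' Generate a synthetic report set
#'
#' Deterministic given `cfg$seed`: the same config yields a byte-identical
#' serialized report set.
#'
#' @param cfg A [synthetic_config()].
#' @return A validated `report_set` of `cfg$n_reports` reports, provenance
#'   `"synthetic seed=<seed>"`.
#' @export
generate_reports <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_reports
  nm <- vapply(cfg$drugs, `[[`, "", "name")
  w <- vapply(cfg$drugs, `[[`, 1, "exposure_weight")
  rho <- vapply(cfg$drugs, `[[`, 1, "event_rate_ratio")
  q <- vapply(cfg$drugs, `[[`, 1, "concomitant_rate")
  boost <- vapply(cfg$drugs, `[[`, 1, "concomitant_event_boost")
  K <- length(nm)

  suspect <- with_stream(cfg, 1,
                         sample.int(K, n, replace = TRUE, prob = w))
  second <- with_stream(cfg, 2, {
    pick <- stats::runif(n) < cfg$multi_suspect_prob & K > 1
    idx <- sample.int(K, n, replace = TRUE, prob = w)
    idx[idx == suspect] <- (idx[idx == suspect] %% K) + 1L
    ifelse(pick, idx, NA_integer_)
  })
  conc <- with_stream(cfg, 3, {
    present <- stats::runif(n) < q[suspect] & K > 1
    pick <- sample.int(max(K - 1L, 1L), n, replace = TRUE)
    # uniform over the other names: skip past the suspect's own slot
    other <- pick + (pick >= suspect)
    ifelse(present, other, NA_integer_)
  })
  p_event <- cfg$baseline_event_prob * rho[suspect] *
    ifelse(is.na(conc), 1, boost[suspect])
  event <- with_stream(cfg, 4, stats::runif(n) < p_event)
  fillers <- with_stream(cfg, 5, {
    primary <- sample(FILLER_REACTIONS, n, replace = TRUE)
    extra_on <- stats::runif(n) < cfg$extra_reaction_prob
    extra <- sample(FILLER_REACTIONS, n, replace = TRUE)
    list(primary = primary, extra = ifelse(extra_on, extra, NA))
  })
  reasons <- with_stream(cfg, 6, {
    out <- rep(NA_character_, n)
    for (k in seq_len(K)) {
      labs <- cfg$drugs[[k]]$reason_labels
      if (is.null(labs)) next
      rows <- which(suspect == k)
      if (length(rows) == 0) next
      drawn <- sample(c(names(labs), NA_character_), length(rows),
                      replace = TRUE,
                      prob = c(labs, max(0, 1 - sum(labs))))
      out[rows] <- drawn
    }
    out
  })
  reporter <- with_stream(cfg, 7,
    sample(names(cfg$reporter_type_dist), n, replace = TRUE,
           prob = cfg$reporter_type_dist))
  country <- with_stream(cfg, 8,
    sample(names(cfg$country_dist), n, replace = TRUE,
           prob = cfg$country_dist))
  year <- with_stream(cfg, 9,
    sample(cfg$year_range, n, replace = TRUE))
  age <- with_stream(cfg, 10, {
    mu <- vapply(cfg$drugs, `[[`, 1, "age_mean")[suspect]
    sdv <- vapply(cfg$drugs, `[[`, 1, "age_sd")[suspect]
    mu[is.na(mu)] <- cfg$age_mean
    sdv[is.na(sdv)] <- cfg$age_sd
    a <- round(pmin(pmax(stats::rnorm(n, mu, sdv), 0), 130), 1)
    a[stats::runif(n) < cfg$age_missing] <- NA_real_
    a
  })
  sex <- with_stream(cfg, 11,
    sample(names(cfg$sex_dist), n, replace = TRUE, prob = cfg$sex_dist))
  weight <- with_stream(cfg, 12, {
    wkg <- round(pmax(stats::rnorm(n, 82, 14), 30), 1)
    wkg[stats::runif(n) < cfg$weight_missing] <- NA_real_
    wkg
  })
  serious <- with_stream(cfg, 13,
    sample(c("SERIOUS", "NON_SERIOUS", NA), n, replace = TRUE,
           prob = c(0.45, 0.35, 0.2)))
  litref <- with_stream(cfg, 14,
    stats::runif(n) < cfg$literature_ref_prob)

  term <- normalize_name(cfg$index_term)
  suspects <- lapply(seq_len(n), function(i) {
    s <- nm[suspect[i]]
    if (!is.na(second[i])) s <- c(s, nm[second[i]])
    s
  })
  reactions <- lapply(seq_len(n), function(i) {
    r <- if (event[i]) c(term, fillers$primary[i]) else fillers$primary[i]
    if (!is.na(fillers$extra[i])) r <- c(r, fillers$extra[i])
    unique(normalize_name(r))
  })
  tbl <- tibble::tibble(
    report_id = sprintf("S%07d", seq_len(n)),
    suspect_drugs = suspects,
    concomitant_drugs = lapply(seq_len(n), function(i) {
      if (is.na(conc[i])) character() else nm[conc[i]]
    }),
    reasons_for_use = lapply(seq_len(n), function(i) {
      rep(reasons[i], length(suspects[[i]]))
    }),
    reactions = reactions,
    seriousness = serious,
    event_year = year,
    sex = sex,
    age_years = age,
    weight_kg = weight,
    reporter_type = reporter,
    country = country,
    has_literature_ref = litref
  )
  report_set(tbl, provenance = sprintf("synthetic seed=%d", cfg$seed))
}

#' Closed-form expected PRR of a synthetic config
#'
#' Under single-suspect generation, the expected index-term rate of a drug's
#' reports is `pi0 * rho * (1 - q + q * boost)` (its mixture over the
#' concomitant strata), and the rate among all other drugs' reports is the
#' exposure-weighted average of their mixtures. Their ratio is the PRR the
#' pipeline's estimate converges to as `n_reports` grows. With
#' `concomitant_free = TRUE` the numerator drops to the concomitant-free
#' stratum `pi0 * rho` -- the quantity the unmasking analysis estimates --
#' while the denominator is unchanged (other drugs' reports are untouched by
#' the exclusion rule).
#'
#' @param cfg A [synthetic_config()] with `multi_suspect_prob = 0`.
#' @param drug Drug name present in the config.
#' @param concomitant_free Use the concomitant-free stratum in the
#'   numerator?
#' @return The expected PRR, a positive number.
#' @export
true_prr <- function(cfg, drug, concomitant_free = FALSE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$multi_suspect_prob > 0) {
    stop("closed form requires single-suspect generation", call. = FALSE)
  }
  nm <- vapply(cfg$drugs, `[[`, "", "name")
  s <- match(normalize_name(drug), nm)
  if (is.na(s)) stop(sprintf("drug not in config: %s", drug), call. = FALSE)
  if (length(nm) < 2) {
    stop("expected PRR undefined with no comparator drugs", call. = FALSE)
  }
  w <- vapply(cfg$drugs, `[[`, 1, "exposure_weight")
  rho <- vapply(cfg$drugs, `[[`, 1, "event_rate_ratio")
  q <- vapply(cfg$drugs, `[[`, 1, "concomitant_rate")
  boost <- vapply(cfg$drugs, `[[`, 1, "concomitant_event_boost")
  mix <- cfg$baseline_event_prob * rho * (1 - q + q * boost)
  numer <- if (concomitant_free) cfg$baseline_event_prob * rho[s] else
    mix[s]
  denom <- sum(w[-s] * mix[-s]) / sum(w[-s])
  numer / denom
}

#' Packaged masking scenario
#'
#' A 20-drug roster echoing the pharmacological classes seen in real
#' male-factor-infertility signal screens (a 5-alpha-reductase inhibitor
#' with a strong genuine signal, calcium-channel blockers and an
#' anticonvulsant with mild signals, SSRIs and an H2 antagonist near or
#' below the null) plus one alkylating agent, `MECHLORETHAMINE`, whose
#' index-term reporting is driven almost entirely by its co-chemotherapy
#' stratum (`q = 0.95`, `boost = 10`): its crude PRR is inflated well above
#' its concomitant-free PRR, so the unmasking analysis must pull the
#' estimate down. The direction of (crude - unmasked) is therefore fixed by
#' construction and verifiable with [true_prr()].
#'
#' @param n_reports Database size.
#' @param seed Root seed.
#' @return A [synthetic_config()].
#' @export
masking_scenario <- function(n_reports = 50000, seed = 20230101) {
  roster <- list(
    drug_profile("Finasteride", 3, 16, 0.10,
                 reason_labels = c("alopecia" = 0.70,
                                   "benign prostatic hyperplasia" = 0.05),
                 age_mean = 44, age_sd = 10),
    drug_profile("Testosterone", 8, 3, 0.20,
                 reason_labels = c("hypogonadism" = 0.5),
                 age_mean = 43, age_sd = 11),
    drug_profile("Valproic Acid", 10, 1.7, 0.30,
                 reason_labels = c("epilepsy" = 0.16,
                                   "bipolar disorder" = 0.19),
                 age_mean = 32, age_sd = 9),
    drug_profile("Carbamazepine", 9, 1.05, 0.30,
                 reason_labels = c("epilepsy" = 0.4)),
    drug_profile("Sertraline", 12, 0.95, 0.30,
                 reason_labels = c("depression" = 0.5)),
    drug_profile("Paroxetine", 9, 0.90, 0.30,
                 reason_labels = c("depression" = 0.5)),
    drug_profile("Fluoxetine", 11, 0.50, 0.30,
                 reason_labels = c("depression" = 0.5)),
    drug_profile("Minoxidil", 10, 0.95, 0.20,
                 reason_labels = c("alopecia" = 0.8)),
    drug_profile("Diethylstilbestrol", 0.8, 14, 0.10, age_mean = 35,
                 age_sd = 8),
    drug_profile("Amlodipine Besylate", 12, 0.70, 0.40,
                 reason_labels = c("hypertension" = 0.6)),
    drug_profile("Verapamil", 4, 1.80, 0.30,
                 reason_labels = c("hypertension" = 0.3),
                 age_mean = 35, age_sd = 9),
    drug_profile("Nifedipine", 3.5, 1.85, 0.30,
                 reason_labels = c("hypertension" = 0.3),
                 age_mean = 37, age_sd = 9),
    drug_profile("Diltiazem Hydrochloride", 3.5, 1.50, 0.30,
                 reason_labels = c("hypertension" = 0.5)),
    drug_profile("Isotretinoin", 10, 0.85, 0.10,
                 reason_labels = c("acne" = 0.9),
                 age_mean = 24, age_sd = 6),
    drug_profile("Mechlorethamine", 2, 0.50, 0.95,
                 concomitant_event_boost = 10, age_mean = 33, age_sd = 10),
    drug_profile("Ranitidine", 9, 0.10, 0.30,
                 reason_labels = c("dyspepsia" = 0.4)),
    drug_profile("Vincristine", 5, 1.10, 0.60,
                 reason_labels = c("hodgkin disease" = 0.3)),
    drug_profile("Prednisone", 15, 0.30, 0.50),
    drug_profile("Lovastatin", 2.5, 2.50, 0.20,
                 reason_labels = c("hypercholesterolaemia" = 0.5), age_mean = 40, age_sd = 10),
    drug_profile("Mycophenolate Mofetil", 10, 0.50, 0.50,
                 reason_labels = c("transplant rejection" = 0.7))
  )
  synthetic_config(n_reports = n_reports, baseline_event_prob = 0.01,
                   drugs = roster, seed = seed)
}
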