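---
title: "PRR disproportionality analysis of spontaneous reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PRR disproportionality analysis of spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prrsignal)
```

## The problem

Spontaneous-report databases such as FAERS collect individual case reports
of suspected adverse drug reactions. They have no denominator of exposed
patients, so absolute risks cannot be estimated; what can be asked is
whether an event is reported *disproportionately* often for one drug
relative to the rest of the database. `prrsignal` implements this screen
for a single index MedDRA preferred term — the motivating application is
"Infertility male" (MFI), a rare event where semen-parameter terms like
"Oligozoospermia" are deliberately *not* pooled in: matching is exact-term
equality, because an abnormal semen analysis does not itself establish
infertility.

## The model and its assumptions

Each individual case is the counting unit. For an index drug the database
partitions into the 2×2 table (A, B, C, D) described in `?build_contingency`,
and the proportional reporting ratio is

$$\mathrm{PRR} = \frac{A/(A+B)}{C/(C+D)},$$

the ratio of the index drug's event-reporting proportion to that of all
remaining drugs. Assumptions worth keeping in mind:

* **Suspect mentions only.** Only drugs reported as *suspect* contribute to
  A/B; concomitant mentions never do. Concomitants matter solely for the
  unmasking exclusion rule.
* **Case-level counting.** A report with $k$ suspect drugs contributes one
  case to each of the $k$ drugs. Per-drug case counts can therefore sum to
  more than the number of distinct reports, which is why the summary table
  reports both (`n_analyzed_reports` attribute) and why per-drug
  percentages use the distinct-case denominator.
* **Reporting, not risk.** A PRR of 14 says reports of the drug mention the
  event 14× as often as other drugs' reports do — notoriety bias,
  indication bias and under-reporting all pass straight through.

### Confidence interval

The source methodology for the PRR does not pin down one interval
construction, so this is a package design decision: the log-normal Wald
interval
$\exp(\ln \mathrm{PRR} \pm z \cdot se)$ with
$se = \sqrt{1/A - 1/(A+B) + 1/C - 1/(C+D)}$, the delta-method standard
error of the log ratio of two binomial proportions, and
$z = \Phi^{-1}(1 - \alpha/2)$ (1.96 at 95%). This is the construction used
throughout the PRR screening literature. Zero cells are *not* continuity
corrected: $A + B = 0$ or $C = 0$ raise explicit errors, $A = 0$ yields a
point estimate of 0 with no interval. In screening practice the inclusion
filter (below) guarantees $A \ge 11$, so these cases only arise in the
unmasking re-analysis, where they are flagged `UNDEFINED` rather than
silently adjusted.

## Tunable parameters

All thresholds live in one `signal_criteria()` object:

| parameter | default | meaning |
|---|---|---|
| `min_reports` | 11 | keep drugs with at least this many index-term cases ("more than 10"); guards against anecdotal counts |
| `prr_elevated_cutoff` | 1 | lower CI bound must exceed this for any signal |
| `prr_strong_cutoff` | 3 | PRR point estimate above this (plus the bound condition) = strong signal |
| `confidence_level` | 0.95 | two-sided level of the Wald interval (z derived, not hard-coded) |

The "more than 10" reading of the inclusion rule (11, not 10) follows the
stricter of the two phrasings in circulation; both agree with published MFI
screens whose smallest included count is 11, and the threshold is
configurable anyway. Classification treats a protective association
(interval entirely below 1) as `NONE`: the screen is one-sided by design.

## Unmasking

Co-reported products distort disproportionality: if an event is heavily
reported for products that accompany the index drug, the index drug can be
masked (or, symmetrically, carried). Identifying *which* co-product is
responsible is empirical, so the package implements the conservative
blanket rule: for each flagged drug, drop every report naming it as a
suspect that lists **any** concomitant medication, and recompute the whole
table on the reduced set. Two readings of the exclusion scope exist (drop
such reports from the drug's own dataset only, or from the entire
database); `prrsignal` removes only index-drug reports, the most
conservative reading, and recomputes C and D on the same reduced set so
the partition invariant ($A+B+C+D =$ database size) always holds. Because
published unmasked intervals are not reproducible without the full source
database — and are much narrower than either reading produces — the package
documents its convention and verifies behaviour against its own generator's
ground truth instead of targeting published unmasked values. Suspect
co-drugs do not trigger exclusion; the rule is about concomitant-role
mentions only.

## The synthetic world

`generate_reports()` emulates the statistical structure the analysis
assumes, with one suspect drug per report by default:

* suspect drug ~ multinomial over `exposure_weight`;
* with probability `concomitant_rate` (q), one concomitant drawn uniformly
  from the other roster names;
* index term present with probability
  $\pi_0 \cdot \rho_{\mathrm{drug}} \cdot (\mathrm{boost\ if\ concomitant})$,
  otherwise a filler reaction from a fixed 10-term vocabulary (fillers
  only ever populate B/D cells);
* reporter type, country, year, sex, age, weight, seriousness and a
  literature-reference flag drawn from configurable distributions, each
  from its own seed stream so adding a metadata field never perturbs the
  event draws.

`true_prr()` gives the closed-form expectation the estimate converges to:
the drug's event rate is the mixture
$\pi_0\rho(1 - q + q\cdot\mathrm{boost})$, the comparator rate is the
exposure-weighted mixture over the other drugs, and their ratio is the
expected PRR (with `concomitant_free = TRUE` the numerator drops to
$\pi_0\rho$, the quantity unmasking estimates). The closed form is exact
only for single-suspect generation, hence the default; the multi-suspect
switch exists to exercise the counting convention, not for calibration.

`masking_scenario()` packages a 20-drug roster spanning the
pharmacological classes seen in real MFI screens. Defaults chosen once as
a realistic stated world: baseline event probability $\pi_0 = 0.01$ (MFI
is rare relative to filler ADRs), rate ratios $\rho$ from 0.1 (an
H2-antagonist far below the null) to 16 (a 5α-reductase inhibitor),
concomitant rates 0.1–0.6 for most drugs, reporter mix ~55% consumer /
40% professional, years 1981–2021, ages normal around 24–44 by drug
(clamped to [0, 130]), ~9% literature-referenced reports. The masked drug
is `MECHLORETHAMINE`: $\rho = 0.5$, $q = 0.95$, boost = 10, so its crude
expected PRR (≈3.5) is inflated almost entirely by the co-chemotherapy
stratum (concomitant-free ≈0.36) and the unmasking analysis must pull it
down — the direction is fixed by construction, which is what the
unmasking tests assert.

What the generator does **not** emulate: duplicate/regulatory re-submission
structure, real FAERS marginal distributions, drug-name variants needing an
ingredient thesaurus, MedDRA hierarchies, event-year trends, or
informative missingness. A green test therefore establishes that the
pipeline computes its statistics correctly on data satisfying the model's
own assumptions — not that those assumptions hold in FAERS.

## Numerical choices

* **Rounding for display** is half-away-from-zero (`share_of_total()`,
  pipeline TSVs): R's banker's rounding would print 12.5% of 8 as 12%,
  which no epidemiological table does. Internal computation is full
  precision; a 1e-9 epsilon absorbs float artifacts at the .5 boundary.
  Published MFI percentages reproduce under this rule except for three
  values that no standard rounding yields (a 82.35→"82.3", a 18.75→"18.7"
  and one percentage printed from a different denominator than stated);
  these are documented, not targeted.
* **Ordering** is deterministic everywhere: descending case count, ties by
  name, so reruns are byte-identical.
* **Normalization**: drug names and reaction terms are uppercased,
  trimmed, whitespace-collapsed; no salt/ingredient mapping (inventing a
  thesaurus would silently merge distinct products).
* **Degenerate inputs**: empty files parse to empty report sets; an empty
  post-filter drug list is an empty result with a message; zero-cell
  tables raise named errors (primary) or `UNDEFINED` flags (unmasking).
* **Missing metadata** is explicitly absent, never imputed; means and
  breakdowns are computed over recorded values with the scoped report
  count as denominator.

## Limitations

Signals of disproportionate reporting are hypothesis-generating only:
causality needs clinical assessment (e.g. Naranjo scoring, out of scope
here because it requires case narratives). The PRR here is unstratified —
no adjustment for sex, age, year or reporter type — and alternative
statistics (ROR, IC/BCPNN, EBGM) are out of scope. Reaction matching is a
single preferred term; related terms must be queried separately.
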