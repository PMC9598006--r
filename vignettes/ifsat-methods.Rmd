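---
title: "Scoring and validating the infant facial skin assessment tool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and validating the infant facial skin assessment tool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifsat)
```

## The instrument

Severe eczema on a one-month-old infant's face — skin problems that take
weeks to clear, or that a pediatrician would want to treat — is worth
catching early, but caregivers at home have no clinical yardstick. The
IFSAT (Infant Facial Skin Assessment Tool) addresses this with a purely
visual checklist: four binary symptoms (erythema, papules, dryness,
exudate/yellow scaling) recorded as present or absent in each of nine
facial areas (scalp/hairline, right and left forehead, eyebrows/eyes,
nose, right and left cheek, mouth/jaw, ears). A completed grid is a 4 x 9
table of checkmarks; the package represents it as a logical matrix
(`assessment_grid()`).

Three scores summarize a grid:

* **original** — the raw count of present cells (0–36).
* **version 1** — a weighted count on the nine-area grid. Items that track
  a longer cure period are doubled: erythema on either forehead, papules
  on either forehead, either cheek or the mouth/jaw, and all dryness and
  exudate cells (0–61).
* **version 2** — the finalized method. The two forehead areas are first
  merged (a symptom is present on the combined forehead if it is present
  on either side); then forehead erythema, forehead papules, cheek and
  mouth papules, and every dryness and exudate cell are doubled (0–53).

Two representational choices are worth making explicit. "Doubling the
dryness total" is implemented as per-cell weight 2, which is arithmetically
identical and keeps a single uniform weight table per version. And the
doubled "papules_mouth" item maps to the mouth/jaw area — the only mouth
area the instrument has. Grids are strictly binary and must be complete;
partially observed grids are rejected rather than imputed, because the
instrument records only presence/absence and there is no principled fill-in
for a missing checkbox.

`max_score()` computes the attainable maxima by scoring the all-present
grid rather than quoting constants, so the weight tables are the single
source of truth.

## The validation statistics

All procedures used by the validation design are implemented from first
principles in the package and are exercised against independent oracles in
the test suite.

**Jonckheere–Terpstra trend test** (`jonckheere_terpstra()`). The statistic
sums, over ordered group pairs $i<j$, the Mann–Whitney count
$\#\{x_b > x_a\} + \tfrac12\#\{x_b = x_a\}$. Its null mean is
$\tfrac12\sum_{i<j} n_i n_j$ and the tie-corrected null variance is the
standard three-term expression in group sizes and tie multiplicities. The
asymptotic p-value applies a continuity correction of 1/2; the default is
two-sided. For total $N \le 20$ the exact permutation distribution is used
instead: exhaustively when the number of distinct label arrangements is at
most 20,000, otherwise by 10,000 seeded Monte Carlo permutations. The
20,000 cap keeps worst-case exhaustive enumeration around a second in pure
R; beyond it the Monte Carlo p-value has standard error below 0.005, which
is negligible for a trend screen.

**ROC, AUC and the Youden cutoff** (`empirical_roc()`). The AUC is the
tie-adjusted concordance probability computed by direct case–control pair
counting (ties count 1/2) — identical to the trapezoidal area under the
empirical ROC but defined without interpolation. The operating-point
convention is "positive means score at or above the cutoff", so an integer
cutoff is inclusive; candidate cutoffs are the distinct observed scores
plus one value above the maximum (the all-negative corner). Among cutoffs
maximizing $J = \text{sensitivity} + \text{specificity} - 1$, the smallest
is returned, which favors sensitivity — the right tie-break for a
screening instrument whose cost asymmetry is missed treatment need.

**Intraclass correlation** (`icc_two_way()`). Ratings are modeled by the
two-way crossed design (every rater or occasion rates every subject). The
default form is ICC(A,1): two-way random effects, absolute agreement,
single measure, computed from the ANOVA mean squares with the F-based 95%
interval (Satterthwaite degrees of freedom for the rater–error
combination). Absolute agreement is the default because the design treats
raters as interchangeable and systematic rater shifts should count as
disagreement; the consistency form ICC(C,1) is available through
`form = "consistency"` since the choice is not always recoverable from a
study report. The same routine serves intra-examiner analysis, with the
two rating occasions playing the role of raters.

**Mann–Whitney, Spearman, agreement** (`mann_whitney_u()`,
`spearman_rho()`, `agreement_rate()`). The U statistic counts x-over-y
wins with half-ties via midranks. P-values are exact (full enumeration of
label assignments) when the combined sample size is at most 12, and use
the tie-corrected normal approximation with continuity correction
otherwise. Group summaries report medians and 25th–75th percentile IQRs
using linear-interpolation (type 7) quantiles — a documented convention,
since different software defaults disagree on small samples. Spearman's
rho is the Pearson correlation of midranks; the agreement rate is the
percentage of concordant positions of two binary judgment vectors.

No confidence intervals are attached to AUC or Youden J, and no
multiplicity correction is applied across the trend/AUC table; the
validation design reports per-cell tests.

## The synthetic cohort generator

No individual-level data ship with the package, so the generator
(`cohort_params()`, `generate_cohort()`) provides cohorts with the
statistical structure the validation design assumes, making every pipeline
stage testable and allowing parameter-recovery experiments.

A single latent severity $s_i \sim \mathrm{Gamma}(2, 1)$ drives everything
observable:

* **True symptom grid.** Cell $(k, a)$ is present with probability
  $\mathrm{logit}^{-1}(\beta_{ka} + 0.4\, s_i)$. Default intercepts are
  per-symptom (erythema $-2.6$, papules $-2.3$, dryness $-3.0$, exudate
  $-3.6$), reflecting that papules are the most common finding and exudate
  the rarest. Cells are independent given severity — an explicit
  simplification; real symptoms co-occur spatially.
* **Rater observation.** Each role sees the true grid through a binary
  channel with role-specific false-negative/false-positive rates
  (pediatrician 0.10/0.02, nurse 0.30/0.05, caregiver 0.35/0.08). The
  repeat pediatrician occasion for the intra-examiner analysis (first 20
  infants by default, emulating photograph re-rating) re-draws the same
  channel independently.
* **Treatment need.** `needs_treatment` is the deterministic indicator
  $s_i > q_{0.903}$ of the Gamma distribution, fixing the expected
  prevalence at 11/113 ≈ 9.7%. A second pediatrician's judgment (for the
  agreement-rate analysis) applies the same threshold, with an optional
  flip probability defaulting to 0 — reproducing perfect
  between-pediatrician agreement.
* **Cure period.** $\text{days} = \mathrm{round}\,
  e^{1.9 + 0.5 s_i + \varepsilon}$, $\varepsilon \sim N(0, 0.6^2)$,
  right-censored at 28 days after the checkup ("problems did not disappear
  within 4 weeks"); the log-normal form produces the right-skewed,
  integer-day outcomes and a natural censoring mechanism. Censoring in
  the reporting bins (0–7, 8–14, 15–28, over 28) is always at 28 days,
  matching the instrument's grouping, regardless of a configured
  follow-up horizon.
* **Nuisance processes.** Dropout (21/113) and dermatologic-agent use
  (13/92) are independent coin flips; agent users are excluded from
  cure-period analyses because topical agents alter the cure period.
* **Skin-barrier readings.** TEWL (mean 12, SD 4 g/m²/h), SCH (40 ± 12
  AU) and sebum (8 ± 6 µg/cm²) are drawn independently of severity by
  default, mirroring the concurrent-validity null finding (forehead
  measurements do not capture whole-face severity and vary with season);
  a severity slope per measure is available for sensitivity experiments.

The defaults were calibrated once so that cohort summaries are of the same
order as a real validation cohort — caregiver version-2 medians around 7–8
(no-need) vs ~14 (need), inter-rater ICCs in the 0.6–0.7 range,
intra-examiner ICC near 0.87 — and are not revisited per analysis. They
are calibration targets, not asserted reproductions: a single simulated
cohort of 113 pairs has wide sampling variability, and quantities the
generator does not model (most notably rater-level judgment noise in the
treatment-need gold standard) make simulated AUCs run higher than observed
ones. Passing tests therefore demonstrate that the pipeline recovers the
qualitative structure the generator encodes, not that the generator
reproduces any particular cohort.

## The pipeline

`run_validation()` reproduces the full study flow on a cohort:

1. scores every rater grid under all three versions (the comparison tables
   always carry all versions, whatever the configured choice);
2. cure-period trend analysis — Jonckheere–Terpstra per rater x version on
   follow-up completers who did not use dermatologic agents, with group
   medians/IQRs;
3. ROC/AUC per rater x version against treatment need, on all
   completed-checkup records — the AUC population deliberately includes
   agent users, whereas the trend population does not, and both n's are
   reported;
4. the caregiver Youden cutoff for the configured version;
5. need vs no-need Mann–Whitney per rater;
6. intra-examiner ICC (two pediatrician occasions), inter-rater ICCs
   (pediatrician–caregiver, nurse–caregiver) and the between-pediatrician
   agreement rate on treatment need;
7. Spearman correlations of scores with TEWL, SCH and sebum.

Filter counts are logged so the participant flow is auditable:
`recruited = completed_followup + dropouts` and
`completed_followup = analyzed_for_cure + agent_excluded`. Dropouts are by
default excluded only from the cure-period analysis (whether a validation
study drops them elsewhere is usually unstated; a config switch covers the
alternative). Degenerate subsets are signalled rather than silently
dropped: a single-class treatment-need vector yields an explicit message
and `NA` ROC/Youden entries, and trend cells with fewer than three
non-empty groups yield `NA` p-values.

Runs are bit-reproducible: the only stochastic subroutine (the Monte Carlo
permutation fallback) is seeded from `analysis_config(mc_seed = )`, and
the generator is seeded from `cohort_params(seed = )` without touching the
caller's RNG state.

```{r example}
cohort <- generate_cohort(cohort_params(n_pairs = 113, seed = 7))
report <- run_validation(cohort, analysis_config())
report$youden
subset(report$auc_table, version == "v2")
```

## What the tests establish, and at what scale

The suite checks every scoring method against an independently coded
literal weight-table oracle on random grids; trend, rank-sum and AUC
routines against brute-force pair counting and exhaustive permutation
enumeration; the ICC against definition-sums ANOVA oracles and a
variance-component recovery experiment (500 replicates of 200 subjects x 3
raters, true ICC recovered within 0.03); and the end-to-end pipeline on
200 simulated cohorts of 113 pairs with strong severity effects
(symptom-expression slope 0.6, cure-period noise SD 0.3), where the
caregiver trend and the need/no-need separation are significant in at
least 95% of seeds and all score–barrier correlations stay below 0.4 in
magnitude in at least 99%. The asymptotic-vs-exact agreement check uses
N = 12 instances with continuous responses: with heavy ties at such sizes
the permutation distribution collapses to a few atoms and no normal
approximation can track it closely — a known small-sample limitation, not
a defect of the tie correction.

These sizes keep the full suite comfortably fast while leaving Monte Carlo
standard errors well inside the asserted tolerances.

## Known limitations

* Symptom cells are conditionally independent given severity; spatial
  co-occurrence (e.g. symmetric cheek involvement) is not modeled.
* The treatment-need gold standard is deterministic in severity, so
  simulated AUCs are optimistic relative to a human judgment.
* Seasonality of skin-barrier measurements (temperature/humidity) is not
  modeled; the default barrier readings are pure nulls.
* Cure periods beyond the censoring horizon are unobserved by design, so
  the pipeline treats "over 28 days" as a terminal ordinal category, not a
  survival analysis.
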