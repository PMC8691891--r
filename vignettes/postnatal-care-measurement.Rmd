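---
title: "Measuring newborn postnatal care from household surveys: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring newborn postnatal care from household surveys: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnccoverage)
```

## The measurement problem

Most newborn deaths occur in the first two days of life, and the global
tracking indicator for newborn postnatal care is a single household-survey
question: did anyone check on the baby's health? Since the DHS-7
questionnaire, surveys also ask whether a health care provider performed
five specific interventions in those first two days — examining the
umbilical cord (B1), measuring temperature (B2), counselling on newborn
danger signs (B3), counselling on breastfeeding (B4), and observing a
breastfeed (B5). The gap between *contact* (a reported check, A) and
*content* (the interventions actually delivered) is the quality-coverage
gap; and because the postnatal-check question cites a cord examination as
its example of a check, a respondent who reports a cord check but denies a
postnatal check has given an internally inconsistent answer. This package
implements the full measurement chain — indicator construction,
co-coverage, gaps, consistency auditing, pairwise agreement — as
design-based estimation over a birth-level extract, plus a synthetic
generator so the chain can be validated end to end without restricted
survey microdata.

## Indicator definitions

* **A (postnatal check within 2 days).** Facility births are asked about a
  check before discharge (q438) and after discharge (q445); non-facility
  births a single general question (q453). A counts if any applicable
  route reports a check with first-check timing of 0–2 days. `dont_know`
  and `missing` responses count as *no* — the standard convention for
  survey coverage numerators, and a requirement for the consistency
  classification to partition all records. A sensitivity mode
  (`missing = "drop"`) removes records with non-substantive core responses
  instead.
* **Timing unknown.** The survey does not define how a reported check with
  unknown timing should be treated when restricting to two days. The
  default (`timing_unknown = "count"`) counts it as within-window,
  mirroring how DHS postnatal-care indicators tabulate undated checks;
  `"strict"` is available. The B questions embed the two-day window in
  their wording, so no timing test applies to them.
* **Co-coverage** is the count of B1–B5 received (0–5). The postnatal
  check does not contribute to the count.
* **Any contact** is A OR any B — deliberately broad, so a respondent who
  misunderstood the check question but reported interventions still enters
  the quality-gap denominator.
* **Consistency** classifies (A, B1): yes/yes coverage, yes/no
  quality-coverage gap, no/no coverage gap, no/yes internal inconsistency.
  Only B1 is used, because only the cord check appears as an example
  inside the check question; other "B yes / A no" patterns are not
  logically contradictory.

## Eligibility

The analysis sample is most-recent live births within 2 years of the
interview, excluding newborns who died in the first 2 days and births in
the 2 days before interview (for whom the recall window had not elapsed).
Exclusions are attributed to the first matching reason in a fixed order
(not-most-recent, over-two-years, died-first-two-days,
born-within-two-days), so the log partitions the removals exactly.

Two operationalizations deserve note. Dates are carried as century-month
codes (months since January 1900), so "within 2 years" is implemented at
month resolution as `interview_cmc − birth_cmc < 24`, the standard
construction for "births in the last 2 years". "Died in the first 2 days"
is read as age at death ∈ {0, 1} days, matching the 48-hour indicator
window; the boundary convention (strict `< 2` vs `≤ 2` days) is not
determined by the indicator's verbal definition, and the package uses the
strict reading. The born-within-two-days rule needs day resolution that
month-coded dates lack; it is applied through an explicit
`days_since_birth` field, which synthetic extracts always carry — for real
extracts without it the rule is inert, which the documentation flags as an
approximation.

## Design-based estimation

All quantities are ratio-to-domain estimators under the stratified
two-stage design: \(\hat p = \sum_i w_i y_i d_i / \sum_i w_i d_i\).
Variance is Taylor-linearized with the with-replacement first-stage
approximation (no finite-population correction), the standard treatment
for DHS-type designs: per-record scores
\(u_i = w_i d_i (y_i - \hat p) / \sum w_i d_i\) are totalled by PSU and
contrasted within strata with an \(n_h/(n_h-1)\) factor. Domain estimation
keeps every PSU in the contrasts (PSUs with no domain members contribute
zero totals), so the randomness of domain size is accounted for. Design
degrees of freedom are (#PSUs − #strata).

Numerical and policy choices:

* **Confidence intervals** are computed on the logit scale with the design
  t quantile and back-transformed, which keeps them inside (0, 1); a plain
  Wald interval is used at degenerate estimates (0 or 1) and available via
  `ci_method = "wald"`. No method is canonical for survey proportions;
  logit-Wald is the common default in survey software.
* **Lonely PSUs** (a stratum with a single PSU) have no internal contrast.
  The default policy contrasts the lone PSU total against the grand mean
  of PSU totals (conservative); `"certainty"` (zero contribution) and
  `"error"` are selectable.
* **Weights.** Point estimates and with-replacement SEs are invariant to
  uniform weight rescaling, so the DHS ×10⁶ storage convention only
  matters for weighted-N reporting; descaling is an explicit mapping flag.
* **Agreement** between two indicators is the weighted share of records on
  which they coincide (both yes or both no). Whether published agreement
  figures of this kind are weighted is typically unstated; the package
  defaults to weighted, with `weighted = FALSE` as a diagnostic.
* The **co-coverage SD** is the population SD of the weighted distribution,
  \(\sqrt{\sum_k k^2 p_k - (\sum_k k p_k)^2}\); the identities linking
  shares, mean and SD hold to 10⁻⁹ by construction and are asserted in the
  tests.

## The synthetic generator

`generate_births()` emulates the structure the estimators need from a DHS
child-recode extract: strata of clusters with lognormal cluster-level
relative weights; facility/home delivery mix; a latent provider-contact
event; interventions drawn conditionally independently given contact — so
the shared contact variable, not a copula, induces the positive pairwise
correlation seen in real data, and every population quantity keeps a
closed form (`generator_truth()`) obtained by enumerating the latent cells
place × contact × cord-check receipt; the postnatal-check response, with
an injectable inconsistency rate τ = P(A flipped to no | A would be yes,
B1 received); per-question don't-know noise; and mutually exclusive
planted ineligible records, so the eligibility log can be compared to
planted counts exactly.

Defaults are chosen once to represent a mid-sized survey from the DHS
2015–2018 round: 8 strata × 25 clusters × 20 births ≈ 4,000 most-recent
births (about the per-survey median in that round); 65% facility births
(that round spans roughly 36–93%); contact probabilities 0.75 (facility)
and 0.35 (home), giving any-contact coverage near 61%, mid-range of the
observed 39–90%; intervention probabilities given contact of 0.75, 0.65,
0.50, 0.60, 0.40 (cord check most common, breastfeeding observation
least, the ordering seen in the published coverage profiles); τ = 0.10,
which yields an inconsistency rate near 11% of newborns, within the
observed <1%–16% range; 2% don't-know responses; and small planting rates
for ineligible records (3% non-most-recent, 5% over two years, 1% early
neonatal death, 0.5% born within two days — early neonatal mortality near
1% is typical of these settings).

What the generator does *not* emulate: questionnaire skip logic beyond the
six questions, recall bias and its correlation with facility birth, twin
structure, within-cluster correlation beyond the shared cluster weight,
non-response patterns that correlate with care received. Passing the
validation suite therefore shows the estimators are correct for data *of
this structure*; it does not validate the survey questions themselves
against clinical observation, which is exactly the measurement problem the
indicators are designed to expose.

## Validation strategy and problem sizes

The test suite validates each layer against an independent reference:
brute-force weighted tabulation (exact agreement on 1,000 random small
datasets), a hand-worked two-stratum Taylor calculation, the closed-form
simple-random-sampling SE \(\sqrt{p(1-p)/(n-1)}\), a 10,000-replicate
rescaled cluster bootstrap (SE agreement within 10%), the generator's
closed forms (marginals, agreement, co-coverage pmf within one point at
n = 10⁵), recovery of a planted inconsistency rate with closed form
0.6·0.8·0.15 = 7.2% (95% CI coverage ≥93% over 500 replicates at
n = 50,000), and CI calibration at 95% ± 3 points over 500 replicates at
the default n = 4,000. These sizes were chosen so each property is tested
with comfortable Monte-Carlo margin while the whole suite completes in a
few minutes.

One reproduction caveat is deliberate: recomputing a co-coverage SD from a
*published percentage distribution* inherits the 1-decimal rounding of the
printed cells, which can move the SD by about ±0.01. Across the 15
published country rows shipped in `inst/extdata/`, all 15 means and 13 of
15 SDs reproduce at printed precision; the Burundi and Ethiopia SDs differ
by 0.006 and 0.005 — consistent with cell rounding, not with an error in
the summary formula, as the tests' exact identities show.

## Known limitations

* Real DHS recode files (Stata/SPSS) are out of scope; the loader reads
  the analysis-relevant CSV extract shape with an explicit column mapping.
* Jackknife/BRR replication variance and design-effect decompositions are
  not implemented; variance is Taylor linearization only.
* Per-group estimation (e.g. by country) is sequential and independent;
  there is no pooled multi-survey model.
* The month-resolution date handling means the born-within-two-days rule
  depends on a day-level field where available, as noted above.
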