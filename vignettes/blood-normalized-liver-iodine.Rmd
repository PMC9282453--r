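---
title: "Blood-normalized liver iodine: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blood-normalized liver iodine: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iodinorm)
```

## The problem

Dual-energy CT material-density iodine images report, per voxel, the iodine
concentration in mg/ml rather than a Hounsfield value. Measuring the mean
concentration in liver-parenchyma ROIs therefore gives a quantitative
enhancement biomarker — but its diagnostic use needs physiological reference
ranges, and the raw (absolute) concentration is confounded by each patient's
circulatory state: blood volume, cardiac output and injection hemodynamics
scale the amount of contrast delivered to the liver at the portal venous
phase time point. Two patients with identical liver tissue can differ
substantially in absolute liver iodine simply because their vessel iodine
differs.

`iodinorm` implements the analysis that addresses this: blood normalization
of the liver concentration, the statistical battery establishing which
strata the reference ranges need, and the construction of age-adjustable
mean ± 2 SD ranges. A seeded synthetic-cohort generator stands in for
clinical raw data so that every stage — and the method's two headline
mechanisms — can be tested end to end.

## The model

Per patient \(x\), three parenchymal ROIs (liver segments 3, 4b, 7) are
averaged into the absolute liver concentration

\[ I_{abs}(x) = \tfrac{1}{3}\left(I_{s3}(x) + I_{s4b}(x) + I_{s7}(x)\right). \]

The liver has a dual blood supply, approximately 75% portal-venous and 25%
hepatic-arterial, so the supplying blood concentration is modelled as

\[ I_{mixed}(x) = 0.75\, I_{pv}(x) + 0.25\, I_{aorta}(x). \]

Blood normalization divides by the patient's own vessel concentration and
rescales by the cohort-average vessel concentration, keeping mg/ml units:

\[ I_{bn}(x) = \frac{I_{abs}(x)}{I_{blood}(x)} \cdot \overline{I_{blood}}, \]

with \(I_{blood}\) one of \(I_{pv}\), \(I_{aorta}\) or \(I_{mixed}\). Two exact
identities follow and are enforced at tolerance 1e-12 in the tests: if
\(I_{blood}\) is constant across the cohort, normalized equals absolute; and
jointly rescaling all vessel concentrations by any \(c > 0\) leaves the
normalized values unchanged (the cohort mean cancels the per-patient
factor). This cancellation is precisely why normalization removes the
circulatory confounder.

Reference ranges are \([\mu - 2\sigma,\ \mu + 2\sigma]\), stratified by sex
only where the Mann–Whitney gender comparison on that measure is
significant, and shifted by the fitted regression slope per year of age away
from the cohort reference age for the blood-normalized measures.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| supply weights | (0.75, 0.25) | — | approximate portal/arterial flow split; configurable because the split is approximate |
| `alpha` | 0.05 | — | conventional two-sided significance level |
| range width | mean ± 2·SD | mg/ml | stated as *two* standard deviations, not 1.96 |
| SD denominator | n − 1 | — | the cohort is a sample used to generalize; at n ≈ 105 the difference is below print precision |
| `reference_age` | rounded cohort mean age | years | ranges apply unadjusted at the cohort's mean age |
| report rounding | 3 decimals (concentrations), 4 (slopes) | — | print-comparable output; rounding is a pure view, never fed back into computation |

## The synthetic generator: what it emulates

`synthetic_config()` states the world the analysis assumes; its defaults are
the benchmark cohort's published summaries, not knobs:

* **Cohort**: n = 105, 43/105 female, ages 17–86 from a truncated
  skew-normal (location 71.7, scale 22, shape −3) tuned to mean ≈ 55.6 years
  and skewed toward older ages.
* **Vessels**: male means 3.942 (aorta) and 4.479 (portal vein) mg/ml; a
  per-patient circulatory factor (lognormal, CV 0.18) scales both vessels
  jointly; females carry a 1.27 circulatory multiplier. This reproduces the
  sex-mixed vessel means (≈ 4.38 / 4.97 mg/ml) and the female/male
  portal-vein ratio.
* **Uptake**: true liver iodine is an age-dependent uptake fraction times
  the mixed supply concentration. The fraction at the reference age is
  derived so the mixed-normalized mean is ≈ 2.10 mg/ml; it declines by
  0.0056 mg/ml (normalized scale) per year, re-expressed on the fraction
  scale by dividing by the expected mixed-supply mean. Between-patient
  uptake CV is 0.14.
* **Measurement noise**: multiplicative lognormal with mean 1 — CV 0.03 per
  ROI (three independent draws) and 0.05 per vessel. Log-scale noise
  guarantees positive concentrations; only means and SDs are published, so
  the lognormal family is a modelling choice, not an estimate.

The two mechanisms are encoded *by construction*: the sex effect enters only
through the circulatory factor (so absolute liver iodine differs by sex
while the uptake fraction does not), and the age effect enters only through
the uptake fraction (so it is masked on the absolute scale by circulatory
variability and visible after normalization). A green Monte-Carlo test
therefore establishes that the pipeline detects what the generator encodes —
it does not validate the generative assumptions against real livers, nor the
lognormal noise family, nor independence of ROI errors (real ROI errors
share scanner and placement effects), nor any body-weight, protocol or
scanner-platform dependence, all of which are out of scope.

```{r}
cfg <- synthetic_config(seed = 1)
cfg
print(analyze(simulate_cohort(cfg)))
```

## Numerical and design choices

* **Mann–Whitney U.** U is the cross-pair count with half-ties, computed via
  midranks. The two-sided p uses exact enumeration when a group has fewer
  than 8 observations *and* `choose(n1 + n2, n1)` ≤ 2e6; enumerating all
  assignments of midranks is valid under ties. Beyond that cap (e.g. 5
  versus 100 patients) exact enumeration is intractable and the normal
  approximation with midrank tie correction and continuity correction is
  used. For the study-sized 43/62 split the approximation path always
  applies.
* **Pearson / regression.** Closed-form \(r\), \(t = r\sqrt{(n-2)/(1-r^2)}\)
  with n − 2 df, OLS slope = cov/var; the slope test is algebraically the
  Pearson test, and the suite asserts the identity slope·sd(age)/sd(value)
  = r at 1e-12.
* **Sidedness and multiplicity.** All tests two-sided; no multiple-testing
  correction (raw p-values per endpoint, kept for fidelity with standard
  practice in this literature — a caveat, not a recommendation).
* **Boundary convention.** A gender-test p exactly equal to alpha does *not*
  stratify (strict inequality).
* **Stratification and age adjustment.** Sex strata only where the gender
  test is significant — in practice the absolute measure. The age slope is
  attached only to blood-normalized ranges by default, because the age
  effect is not established on the absolute scale; `adjust_absolute = TRUE`
  forces it. Ages outside the cohort's observed span warn (extrapolation)
  rather than error.
* **Full precision throughout.** All intermediates are unrounded; report
  rounding is applied at write time only. Published bounds show 0.001-level
  artifacts of rounding summary moments before subtracting — recomputing
  from raw values is treated as authoritative.
* **Interchange formats.** Cohort tables are plain CSV with a fixed header;
  extra columns (e.g. Hounsfield exports) pass through ignored. The CLI's
  generator config is JSON (`jsonlite` is a hard dependency; no TOML parser
  is assumed). Numeric serialization uses 17 significant digits so
  write→read round-trips are exact.
* **Rejected rows.** Row validation never aborts a batch run by default;
  every input row is either accepted or listed with a reason
  (accepted + rejected = input), and `strict = TRUE` promotes rejects to
  errors. This mirrors a clinical exclusion workflow while keeping the
  pipeline safe in scripts.
* **External calibration.** The vessel reference means are recomputed from
  the analyzed cohort by default, but `external_blood_reference()` lets a
  published calibration be applied prospectively to new patients, which is
  what makes the ranges usable outside the original cohort.

## Known limitations

* The generator draws sex per patient (Bernoulli), so a simulated cohort's
  sex split varies around 62/43; the published split is the expectation,
  not a constraint.
* The clinical raw measurement table is not redistributable with the
  package, so end-to-end descriptive checks run against the generator's
  default calibration rather than the original data; agreement is at
  Monte-Carlo tolerance, not row-level.
* One published all-patients SD for the absolute measure (0.216) is
  inconsistent with the corresponding per-sex SDs (≈ 0.47–0.48) and looks
  like a misprint or a standard error; the package always computes SDs from
  data and makes no attempt to match it.
* No percentile-based or robust reference-interval estimators, no
  partitioning criteria beyond the Mann–Whitney gate, no survival or
  covariate-adjusted models, no DICOM/image handling: the pipeline begins
  at already-measured ROI values.
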