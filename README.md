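# iodinorm

Blood-normalized liver iodine concentrations and physiological reference
ranges from dual-energy CT.

## The problem

Dual-energy CT material-density iodine images measure the iodine
concentration of liver parenchyma directly, in mg/ml — a quantitative
enhancement biomarker. Its diagnostic use requires physiological reference
ranges for healthy liver, and the absolute concentration is confounded by
each patient's circulatory state (blood volume, cardiac output,
hemodynamics), which scales the contrast delivered through the supplying
vessels. `iodinorm` is for imaging scientists and biostatisticians working
with per-patient ROI iodine measurements (three liver ROIs in segments 3,
4b and 7, plus aorta and portal vein) who want the full analysis from raw
measurement table to stratified, age-adjusted reference ranges.

## The method

Per patient *x*, with the three-ROI average *I*<sub>abs</sub>(*x*) and the
mixed hepatic supply
*I*<sub>mixed</sub>(*x*) = 0.75 *I*<sub>pv</sub>(*x*) + 0.25 *I*<sub>aorta</sub>(*x*),
the blood-normalized concentration is

> *I*<sub>bn</sub>(*x*) = *I*<sub>abs</sub>(*x*) / *I*<sub>blood</sub>(*x*) · mean(*I*<sub>blood</sub>)

for *I*<sub>blood</sub> ∈ {portal vein, aorta, mixed}; the cohort-mean
rescaling keeps mg/ml units. Normalization cancels any per-patient factor
common to the vessels, which removes the circulatory confounder: a sex
difference present in absolute values disappears after normalization, and a
weak negative age trend in parenchymal uptake becomes detectable.
Reference ranges are μ ± 2σ (sample SD), stratified by sex only where the
Mann–Whitney gender comparison is significant, and shifted by the fitted
regression slope for each year of age away from the cohort reference age.

## Worked example

```r
library(iodinorm)
cohort <- simulate_cohort(synthetic_config(seed = 1))  # or read_cohort("cohort.csv")
report <- analyze(cohort)
print(report)
```

```
<run_report> n = 105 (64 male, 41 female), age 57.21 y (range 26.1331-83.9213)

Per-measure mean (sd) [mg/ml]:
  i_l_abs        all 2.047 (0.515)  male 1.848 (0.409)  female 2.358 (0.514)
  i_pv_n         all 2.055 (0.331)  male 2.052 (0.325)  female 2.060 (0.344)
  i_a_n          all 2.058 (0.327)  male 2.083 (0.316)  female 2.019 (0.343)
  i_mixed_n      all 2.054 (0.325)  male 2.057 (0.318)  female 2.049 (0.339)

Gender comparisons (Mann-Whitney U):
  absolute          U =   2063.0  p = 8.242e-07 *
  pv_normalized     U =   1338.0  p = 0.867
  aorta_normalized  U =   1115.0  p = 0.1968
  mixed_normalized  U =   1291.0  p = 0.8929

Age correlations (Pearson) and regression slopes:
  absolute          r = -0.101  R^2 = 0.010  p = 0.307    slope = -0.0044 mg/ml/yr
  pv_normalized     r = -0.278  R^2 = 0.077  p = 0.004036 *  slope = -0.0078 mg/ml/yr
  aorta_normalized  r = -0.281  R^2 = 0.079  p = 0.003696 *  slope = -0.0078 mg/ml/yr
  mixed_normalized  r = -0.284  R^2 = 0.080  p = 0.003376 *  slope = -0.0078 mg/ml/yr

Reference ranges (mean +/- 2 sd; reference age 57 y):
  absolute          male    [ 1.029,  2.666]
  absolute          female  [ 1.331,  3.385]
  pv_normalized     all     [ 1.393,  2.717]  (-0.0078 mg/ml per year of age)
  aorta_normalized  all     [ 1.404,  2.712]  (-0.0078 mg/ml per year of age)
  mixed_normalized  all     [ 1.405,  2.704]  (-0.0078 mg/ml per year of age)
```

Reading this output: females show significantly higher *absolute* liver
iodine (p ≈ 1e-6) but the three blood-normalized measures do not differ by
sex — so absolute ranges are sex-stratified while normalized ranges pool
both sexes. Age correlates negatively with the normalized measures only
(the circulatory variability masks it on the absolute scale), so normalized
ranges carry a per-year slope: e.g. a 67-year-old's mixed-normalized range
is shifted down by 10 × 0.0078 mg/ml. `write_report(report, "out/")` writes
the summary tables, test results, rounded and full-precision range tables
and a `summary.json`.

The per-patient CSV layout is
`patient_id,age,sex,roi_s3,roi_s4b,roi_s7,aorta,portal_vein`
(concentrations mg/ml, age years; sex `M/F/male/female`). A command-line
interface wraps the same pipeline:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "iodinorm.R", package = "iodinorm"))')
Rscript "$CLI" simulate --config inst/extdata/sim_default.json --seed 42 --out cohort.csv
Rscript "$CLI" analyze --input cohort.csv --alpha 0.05 --out report_dir
Rscript "$CLI" replicate --config inst/extdata/sim_default.json --replicates 2000 --out power.csv
```

`replicate_study()` (the `replicate` subcommand) is the Monte-Carlo harness:
it re-runs the whole pipeline over many simulated cohorts and reports
type-I/power rejection rates per measure and slope-recovery summaries.

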