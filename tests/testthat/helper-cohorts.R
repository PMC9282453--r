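# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# small hand-typed cohort used for arithmetic spot checks
tiny_cohort <- function() {
  new_cohort(data.frame(
    patient_id  = c("P1", "P2", "P3"),
    age         = c(30, 56, 70),
    sex         = c("male", "female", "M"),
    roi_s3      = c(2.0, 2.4, 1.8),
    roi_s4b     = c(2.1, 2.3, 1.9),
    roi_s7      = c(2.2, 2.5, 1.7),
    aorta       = c(4.0, 5.0, 3.5),
    portal_vein = c(4.5, 5.5, 4.2),
    stringsAsFactors = FALSE
  ))
}

# random valid cohort with uniform-ish measurements (not the generative
# model under test -- deliberately independent of synthetic_config)
random_cohort <- function(n, seed) {
  set.seed(seed)
  new_cohort(data.frame(
    patient_id  = sprintf("R%03d", seq_len(n)),
    age         = runif(n, 18, 85),
    sex         = sample(c("male", "female"), n, replace = TRUE),
    roi_s3      = runif(n, 1, 3),
    roi_s4b     = runif(n, 1, 3),
    roi_s7      = runif(n, 1, 3),
    aorta       = runif(n, 3, 6),
    portal_vein = runif(n, 3.5, 7),
    stringsAsFactors = FALSE
  ))
}

# brute-force Mann-Whitney U: count of cross pairs won plus half the ties
brute_force_u <- function(x, y) {
  cmp <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
  sum(cmp)
}

write_csv_text <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
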