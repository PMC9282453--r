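# six-patient fixture with values small enough to hand-check
fixture6 <- function() new_cohort(data.frame(
  patient_id  = sprintf("F%d", 1:6),
  age         = c(25, 40, 55, 60, 70, 80),
  sex         = c("male", "male", "male", "female", "female", "female"),
  roi_s3      = c(1.8, 2.0, 1.9, 2.4, 2.3, 2.2),
  roi_s4b     = c(1.9, 2.1, 2.0, 2.5, 2.4, 2.1),
  roi_s7      = c(2.0, 2.2, 1.8, 2.6, 2.2, 2.3),
  aorta       = c(3.8, 4.2, 4.0, 5.2, 5.0, 4.8),
  portal_vein = c(4.4, 4.8, 4.6, 5.8, 5.6, 5.4),
  stringsAsFactors = FALSE
))

test_that("analyze reproduces spreadsheet arithmetic on the 6-patient fixture", {
  co <- fixture6()
  rep <- analyze(co)

  # flat-arithmetic oracle, written out independently of the pipeline
  abs_liver <- rowMeans(cbind(co$records$roi_s3, co$records$roi_s4b,
                              co$records$roi_s7))
  mixed <- 0.75 * co$records$portal_vein + 0.25 * co$records$aorta
  pv_n <- abs_liver / co$records$portal_vein * mean(co$records$portal_vein)

  expect_equal(rep$cohort_summary$n, 6)
  expect_equal(rep$cohort_summary$age_mean, mean(co$records$age))
  mt <- rep$measure_table
  expect_equal(mt$all_mean[mt$variable == "i_l_abs"], mean(abs_liver))
  expect_equal(mt$all_sd[mt$variable == "i_l_abs"], sd(abs_liver))
  expect_equal(mt$all_mean[mt$variable == "i_pv_n"], mean(pv_n))
  expect_equal(mt$female_mean[mt$variable == "i_l_abs"],
               mean(abs_liver[4:6]))
  expect_equal(rep$blood_reference$mean_mixed, mean(mixed))

  vt <- rep$vessel_table
  expect_equal(vt$all_mean[vt$variable == "aorta"], mean(co$records$aorta))
  expect_equal(vt$male_sd[vt$variable == "portal_vein"],
               sd(co$records$portal_vein[1:3]))

  # reference age: rounded cohort mean age
  expect_equal(rep$reference_age, round(mean(co$records$age)))
})

test_that("shared vessel profile makes all four measures identical per patient", {
  co <- fixture6()
  co$records$aorta <- 4.5
  co$records$portal_vein <- 5.0
  rep <- analyze(co)
  norm <- rep$normalized
  expect_equal(norm$i_pv_n, norm$i_l_abs, tolerance = 1e-14)
  expect_equal(norm$i_a_n, norm$i_l_abs, tolerance = 1e-14)
  expect_equal(norm$i_mixed_n, norm$i_l_abs, tolerance = 1e-14)
})

test_that("absolute ranges carry no age slope by default; normalized ranges do", {
  rep <- analyze(simulate_cohort(synthetic_config(seed = 21)))
  rt <- range_table(rep$ranges)
  expect_true(all(rt$slope_per_year[rt$measure == "absolute"] == 0))
  norm_rows <- rt$measure != "absolute"
  expect_true(all(rt$slope_per_year[norm_rows] != 0))
  expect_equal(rt$slope_per_year[rt$measure == "mixed_normalized"],
               rep$regressions$mixed_normalized$effect$slope)
})

test_that("analyze(simulate(config)) composes for varied configs and is deterministic", {
  for (seed in c(5, 6)) {
    cfg <- synthetic_config(n = 40, seed = seed)
    path <- tempfile(fileext = ".csv")
    write_cohort(simulate_cohort(cfg), path)
    rep1 <- analyze(path)
    rep2 <- analyze(path)
    expect_s3_class(rep1, "run_report")
    # rounding is a view: full-precision outputs identical across runs
    expect_identical(range_table(rep1$ranges), range_table(rep2$ranges))
    expect_identical(rep1$measure_table, rep2$measure_table)
  }
})

test_that("write_report emits the advertised tables and summary", {
  rep <- analyze(simulate_cohort(synthetic_config(n = 30, seed = 8)))
  dir <- tempfile()
  write_report(rep, dir)
  files <- c("roi_table.csv", "vessel_table.csv", "measure_table.csv",
             "tests.csv", "ranges.csv", "ranges_full_precision.csv",
             "normalized.csv", "summary.json")
  expect_true(all(file.exists(file.path(dir, files))))

  ranges <- read.csv(file.path(dir, "ranges.csv"))
  full <- read.csv(file.path(dir, "ranges_full_precision.csv"))
  expect_equal(ranges$lower, round(full$lower, 3))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$cohort$n, 30)

  norm <- read.csv(file.path(dir, "normalized.csv"))
  expect_named(norm, c("patient_id", "i_l_abs", "i_mixed_blood",
                       "i_pv_n", "i_a_n", "i_mixed_n"))
})

test_that("CLI subcommands simulate, analyze and replicate run end to end", {
  cohort_csv <- tempfile(fileext = ".csv")
  cfg_json <- tempfile(fileext = ".json")
  jsonlite::write_json(list(n = 30), cfg_json, auto_unbox = TRUE)

  expect_message(
    iodinorm_main(c("simulate", "--config", cfg_json, "--seed", "42",
                    "--out", cohort_csv)),
    "simulated cohort of 30")
  first <- readLines(cohort_csv)
  # fixed seed: byte-identical re-run
  iodinorm_main(c("simulate", "--config", cfg_json, "--seed", "42",
                  "--out", cohort_csv))
  expect_identical(readLines(cohort_csv), first)

  out_dir <- tempfile()
  expect_output(
    iodinorm_main(c("analyze", "--input", cohort_csv, "--out", out_dir)),
    "run_report")
  expect_true(file.exists(file.path(out_dir, "ranges.csv")))

  power_csv <- tempfile(fileext = ".csv")
  expect_output(
    iodinorm_main(c("replicate", "--config", cfg_json, "--seed", "1",
                    "--replicates", "5", "--out", power_csv)),
    "replicate_summary")
  expect_equal(nrow(read.csv(power_csv)), 4)

  expect_error(iodinorm_main(c("simulate", "--out", tempfile(), "--n", "0")),
               "n must be")
  expect_error(iodinorm_main("frobnicate"), "unknown subcommand")
  bad_cfg <- tempfile(fileext = ".json")
  jsonlite::write_json(list(not_a_field = 1), bad_cfg, auto_unbox = TRUE)
  expect_error(iodinorm_main(c("simulate", "--config", bad_cfg,
                               "--out", tempfile())),
               "not_a_field")
})
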