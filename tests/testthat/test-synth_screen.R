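test_that("dose series halves from the top dose and spans the printed range", {
  d <- dose_series()
  expect_length(d, 7)
  expect_equal(max(d), 10.64)
  # exact minimum is 10.64 / 2^6 = 0.16625, printed as 0.16
  expect_equal(min(d), 10.64 / 64)
  expect_equal(floor(min(d) * 100) / 100, 0.16)
  expect_equal(d[-1] / d[-length(d)], rep(2, 6))
  expect_error(dose_series(top_dose = -1))
})

test_that("cohort generation honours size, tissue panel and seed", {
  cohort <- generate_cohort(cohort_spec(), seed = 11)
  expect_equal(nrow(cohort), 624)
  expect_true(all(cohort$tissue %in% default_tissues()))
  expect_length(default_tissues(), 22)

  # determinism
  expect_identical(cohort, generate_cohort(cohort_spec(), seed = 11))

  # degenerate specs
  one <- generate_cohort(cohort_spec(n_lines = 1, tissues = "Breast"), seed = 1)
  expect_equal(one$tissue, "Breast")
  expect_error(cohort_spec(tissues = character()), "tissue")
  expect_error(cohort_spec(proportions = rep(0.5, 22)), "sum to 1")
})

test_that("tissue counts are multinomial-consistent with the proportions", {
  spec <- cohort_spec(n_lines = 1000, tissues = c("A", "B"),
                      proportions = c(0.5, 0.5))
  cohort <- generate_cohort(spec, seed = 42)
  counts <- table(cohort$tissue)
  sigma <- sqrt(1000 * 0.25)
  expect_true(all(abs(counts - 500) < 3 * sigma))

  # independent multinomial oracle under the same seed stays in the same band
  set.seed(42)
  oracle <- stats::rmultinom(1, 1000, c(0.5, 0.5))
  expect_true(all(abs(oracle - 500) < 3 * sigma))
})

test_that("genomics tables have the requested shapes and binary mutations", {
  cohort <- generate_cohort(cohort_spec(n_lines = 40), seed = 5)
  gen <- generate_genomics(cohort,
                           genomics_spec(n_exp = 12, n_cn = 1700, n_mut = 8),
                           seed = 6)
  expect_equal(dim(gen$expression), c(40, 12))
  expect_equal(dim(gen$cn), c(40, 1700))
  expect_equal(dim(gen$mutations), c(40, 8))
  expect_true(all(gen$mutations %in% c(0, 1)))
  expect_identical(rownames(gen$expression), cohort$cell_line_id)
  expect_named(gen$latent, cohort$cell_line_id)
})

test_that("planted effects shift the latent score by beta per feature SD", {
  cohort <- generate_cohort(cohort_spec(n_lines = 400), seed = 7)
  spec <- genomics_spec(n_exp = 5, n_cn = 5, n_mut = 5,
                        planted = planted_effect("MUT_MG0002", -2),
                        residual_sd = 0)
  gen <- generate_genomics(cohort, spec, seed = 8)

  # group-means oracle: direct subtraction on the emitted table
  mut <- gen$mutations[, "MG0002"]
  gap <- mean(gen$latent[mut == 1]) - mean(gen$latent[mut == 0])
  expect_equal(gap, -2 * (1 - 0) / sd(mut), tolerance = 1e-10)

  # no planted effects + zero residual -> constant baseline
  flat <- generate_genomics(cohort, genomics_spec(n_exp = 2, n_cn = 2,
                                                  n_mut = 2, residual_sd = 0),
                            seed = 9)
  expect_equal(unname(flat$latent), rep(log10(1.33), 400))

  # unknown planted feature errors by name
  expect_error(
    generate_genomics(cohort,
                      genomics_spec(n_exp = 2, n_cn = 2, n_mut = 2,
                                    planted = planted_effect("MUT_ZZZZ", 1)),
                      seed = 1),
    "MUT_ZZZZ")
  expect_error(planted_effect("MUT_MG0001", 0), "beta")
})

test_that("screen generation is conservative, deterministic and QC-ready", {
  cohort <- generate_cohort(cohort_spec(n_lines = 30), seed = 1)
  spec <- screen_spec(noise_sd = 0.03)
  scr <- generate_screen(cohort, spec, seed = 2)

  treated <- scr$wells[scr$wells$role == "treated", ]
  expect_equal(nrow(treated), 30 * length(spec$doses) * spec$replicates)
  expect_true(all(treated$cell_line_id %in% cohort$cell_line_id))
  expect_true(all(treated$dose_um %in% spec$doses))
  expect_true(all(is.na(scr$wells$cell_line_id[scr$wells$role != "treated"])))
  expect_true(all(scr$wells$raw_signal >= 0))

  # every plate carries enough control/blank wells
  per_plate <- split(scr$wells, scr$wells$plate_id)
  for (pl in per_plate) {
    expect_gte(sum(pl$role == "control"), 8)
    expect_gte(sum(pl$role == "blank"), 8)
  }

  # byte-identical rerun
  scr2 <- generate_screen(cohort, spec, seed = 2)
  expect_identical(scr$wells, scr2$wells)
  expect_identical(scr$truth, scr2$truth)

  expect_error(screen_spec(noise_sd = -0.1), "noise_sd")
  expect_error(screen_spec(doses = c(2, 1, 4)), "increasing")
})

test_that("noiseless non-responders sit exactly at the control signal", {
  cohort <- generate_cohort(cohort_spec(n_lines = 10), seed = 3)
  spec <- screen_spec(noise_sd = 0, responder_fraction = 0)
  scr <- generate_screen(cohort, spec, seed = 4)
  treated <- scr$wells[scr$wells$role == "treated", ]
  expect_equal(treated$raw_signal, rep(spec$control_level, nrow(treated)))
})

test_that("noiseless responder viability matches the closed-form 4PL", {
  # ic50 = 1 uM, hill 1, top 1, bottom 0 -> viability at 1 uM exactly 0.5
  expect_identical(viability_4pl(1.0, ic50 = 1.0), 0.5)
  cohort <- data.frame(cell_line_id = "CL0001", tissue = "Breast",
                       stringsAsFactors = FALSE)
  spec <- screen_spec(noise_sd = 0, responder_fraction = 1)
  scr <- generate_screen(cohort, spec,
                         latent = c(CL0001 = 0), seed = 5)
  treated <- scr$wells[scr$wells$role == "treated", ]
  v <- (treated$raw_signal - spec$blank_level) /
    (spec$control_level - spec$blank_level)
  expect_equal(v, viability_4pl(treated$dose_um, 1.0), tolerance = 1e-12)
})

test_that("screen tables round-trip through the TSV writers", {
  cohort <- generate_cohort(cohort_spec(n_lines = 8), seed = 1)
  gen <- generate_genomics(cohort, genomics_spec(n_exp = 3, n_cn = 3,
                                                 n_mut = 3), seed = 2)
  scr <- generate_screen(cohort, screen_spec(), latent = gen$latent, seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_screen_tables(scr, gen, cohort, dir)
  expect_true(all(file.exists(paths)))
  wells <- read_wells(paths[["wells"]])
  expect_equal(nrow(wells), nrow(scr$wells))
  expect_equal(wells$raw_signal, scr$wells$raw_signal, tolerance = 1e-6)
  expr <- read_feature_table(paths[["expression"]])
  expect_equal(dim(expr), dim(gen$expression))
  expect_equal(unname(expr), unname(gen$expression), tolerance = 1e-6)
})
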