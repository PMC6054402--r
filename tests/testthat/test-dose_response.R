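test_that("AUC matches trapezoid oracles and unit relabelling", {
  d <- dose_series()
  expect_equal(compute_auc(d, rep(1, 7)), 1.0)
  expect_equal(compute_auc(d, rep(0, 7)), 0.0)

  # linear decline in log2 dose from 1 to 0 -> exactly 0.5
  v <- seq(1, 0, length.out = 7)
  expect_equal(compute_auc(d, v), 0.5, tolerance = 1e-12)

  # invariant to dose units (uM vs nM) because the span is normalized
  set.seed(1)
  v2 <- runif(7)
  expect_equal(compute_auc(d, v2), compute_auc(d * 1000, v2),
               tolerance = 1e-12)
  expect_error(compute_auc(1, 0.5), "2 distinct")
})

test_that("Emax is the min of replicate-mean viabilities at the two top doses", {
  d <- dose_series()
  v <- c(1, 0.9, 0.8, 0.7, 0.6, 0.42, 0.35)
  expect_equal(compute_emax(d, v), 0.35)
  expect_equal(compute_emax(d, rep(1, 7)), 1.0)

  # replicate wells at top dose (0.30, 0.40) and second dose 0.50
  dd <- c(5.32, 10.64, 10.64)
  expect_equal(compute_emax(dd, c(0.50, 0.30, 0.40)), 0.35)
})

test_that("Emax equals a brute-force min over the two top doses on every curve", {
  cohort <- generate_cohort(cohort_spec(n_lines = 40), seed = 6)
  scr <- generate_screen(cohort, screen_spec(noise_sd = 0.05), seed = 7)
  ns <- normalize_screen(scr$wells)
  for (cur in split(ns$curves, ns$curves$cell_line_id)) {
    top2 <- sort(cur$dose_um, decreasing = TRUE)[1:2]
    brute <- min(vapply(top2, function(d) {
      mean(cur$viability[cur$dose_um == d])
    }, numeric(1)))
    expect_identical(compute_emax(cur$dose_um, cur$viability), brute)
  }
})

test_that("noiseless 4PL curves are recovered within 1% on IC50", {
  d <- dose_series()
  for (true_ic50 in c(0.4, 1.0, 3.7)) {
    v <- viability_4pl(d, true_ic50, hill = 1, top = 1, bottom = 0)
    fit <- fit_curve(d, v)
    expect_true(fit$converged)
    expect_false(fit$ic50_censored)
    expect_equal(fit$ic50_um, true_ic50, tolerance = 0.01)
    expect_equal(fit$hill, 1, tolerance = 0.05)
  }
  # steeper curve
  v <- viability_4pl(d, 1.5, hill = 3, top = 1, bottom = 0)
  fit <- fit_curve(d, v)
  expect_equal(fit$ic50_um, 1.5, tolerance = 0.01)
})

test_that("flat curves are censored at the documented bounds", {
  d <- dose_series()
  up <- fit_curve(d, rep(1, 7))
  expect_true(up$ic50_censored)
  expect_equal(up$ic50_um, 10 * max(d))
  expect_equal(up$auc, 1)

  down <- fit_curve(d, rep(0, 7))
  expect_true(down$ic50_censored)
  expect_lte(down$ic50_um, min(d))
  expect_equal(down$auc, 0)
  expect_error(fit_curve(d[1:3], rep(0.5, 3)), ">= 4")
})

test_that("lower true IC50 gives lower AUC (noiseless monotonicity)", {
  d <- dose_series()
  auc <- vapply(c(0.3, 0.8, 2, 6), function(ic) {
    compute_auc(d, viability_4pl(d, ic))
  }, numeric(1))
  expect_true(all(diff(auc) > 0))
})

test_that("IC50 is recovered across a noisy synthetic screen", {
  # 200 responders at noise_sd = 0.02: median |log10(fitted/true)| < 0.05
  cohort <- generate_cohort(cohort_spec(n_lines = 200), seed = 8)
  scr <- generate_screen(cohort, screen_spec(noise_sd = 0.02,
                                             responder_fraction = 1),
                         seed = 9)
  ns <- normalize_screen(scr$wells)
  fits <- fit_screen(ns$curves)
  j <- merge(fits, scr$truth, by = "cell_line_id")
  ok <- !is.na(j$ic50_um) & !j$ic50_censored & !is.na(j$true_ic50_um)
  expect_gt(sum(ok), 100)
  err <- abs(log10(j$ic50_um[ok] / j$true_ic50_um[ok]))
  expect_lt(median(err), 0.05)
})

test_that("noiseless pipeline recovers responder IC50s within 1%", {
  cohort <- generate_cohort(cohort_spec(n_lines = 60), seed = 10)
  scr <- generate_screen(cohort,
                         screen_spec(noise_sd = 0, responder_fraction = 1,
                                     responder_ic50_log10_sd = 0.3),
                         seed = 11)
  ns <- normalize_screen(scr$wells)
  fits <- fit_screen(ns$curves)
  j <- merge(fits, scr$truth, by = "cell_line_id")
  in_range <- !is.na(j$ic50_um) & !j$ic50_censored &
    j$true_ic50_um >= min(dose_series()) & j$true_ic50_um <= max(dose_series())
  expect_gt(sum(in_range), 30)
  rel <- abs(j$ic50_um[in_range] / j$true_ic50_um[in_range] - 1)
  expect_lt(max(rel), 0.01)
})

test_that("screen summary orders lines by ascending AUC within tissue", {
  fits <- data.frame(cell_line_id = c("A", "B", "C"),
                     qc_status = "pass", top = 1, bottom = 0, hill = 1,
                     ic50_um = c(1, 2, 3), ic50_censored = FALSE,
                     auc = c(0.9, 0.3, 0.6), emax = 0.5, converged = TRUE,
                     rss = 0, stringsAsFactors = FALSE)
  tissues <- data.frame(cell_line_id = c("A", "B", "C"),
                        tissue = c("Lung", "Lung", "Breast"),
                        stringsAsFactors = FALSE)
  out <- summarize_screen(fits, tissues)
  expect_equal(out$cell_line_id, c("C", "B", "A"))
  expect_equal(out$auc[out$tissue == "Lung"], c(0.3, 0.9))

  expect_error(summarize_screen(fits, tissues[1:2, ]), "C")
  empty <- summarize_screen(fits[0, ], tissues)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("tissue", "auc", "emax") %in% names(empty)))
})

test_that("censored IC50 fraction tracks the planted responder fraction", {
  cohort <- generate_cohort(cohort_spec(n_lines = 150), seed = 12)
  scr <- generate_screen(cohort,
                         screen_spec(noise_sd = 0.02, responder_fraction = 0.3,
                                     responder_ic50_log10_sd = 0.3),
                         seed = 13)
  ns <- normalize_screen(scr$wells)
  fits <- fit_screen(ns$curves)
  # lines with a measurable, uncensored IC50 are (mostly) true responders
  measured <- fits$cell_line_id[!is.na(fits$ic50_um) & !fits$ic50_censored]
  frac <- length(measured) / nrow(cohort)
  ci <- qbinom(c(0.005, 0.995), 150, 0.3) / 150
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
  truth_resp <- scr$truth$cell_line_id[scr$truth$responder]
  expect_gt(mean(measured %in% truth_resp), 0.95)
})
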