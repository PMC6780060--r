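test_that("ISTD normalization divides by the matching ISTD peak", {
  panel <- small_panel()
  peaks <- rbind(
    data.frame(sample_id = "S1", injection_index = 1L, entity = "A",
               channel = "analyte", peak_area = 1000, stringsAsFactors = FALSE),
    data.frame(sample_id = "S1", injection_index = 1L, entity = "A",
               channel = "istd", peak_area = 500, stringsAsFactors = FALSE),
    # D has no ISTD: raw area passes through, tagged unnormalized
    data.frame(sample_id = "S1", injection_index = 1L, entity = "D",
               channel = "analyte", peak_area = 1234, stringsAsFactors = FALSE)
  )
  ratios <- normalize_to_istd(peaks, panel)
  expect_equal(ratios$ratio[ratios$entity == "A"], 2.0)
  expect_true(ratios$normalized[ratios$entity == "A"])
  expect_equal(ratios$ratio[ratios$entity == "D"], 1234)
  expect_false(ratios$normalized[ratios$entity == "D"])
})

test_that("missing and zero ISTD peaks become error records, not drops", {
  panel <- small_panel()
  peaks <- rbind(
    data.frame(sample_id = "S1", injection_index = 1L, entity = "A",
               channel = "analyte", peak_area = 1000, stringsAsFactors = FALSE),
    data.frame(sample_id = "S2", injection_index = 1L, entity = "A",
               channel = "analyte", peak_area = 900, stringsAsFactors = FALSE),
    data.frame(sample_id = "S2", injection_index = 1L, entity = "A",
               channel = "istd", peak_area = 0, stringsAsFactors = FALSE)
  )
  ratios <- normalize_to_istd(peaks, panel)
  expect_equal(nrow(ratios), 2L)
  expect_equal(ratios$status[ratios$sample_id == "S1"], "missing_istd")
  expect_equal(ratios$status[ratios$sample_id == "S2"], "zero_istd")
  expect_true(all(is.na(ratios$ratio)))
})

test_that("merged entities in the clinical panel normalize against the shared ISTD", {
  panel <- load_panel()
  models <- noise_free_models(panel)
  sim <- simulate_calibration_series(panel, levels = c(10, 100, 1000),
                                     models = models, seed = 1)
  ratios <- normalize_to_istd(sim$peaks, panel)
  r <- ratios[ratios$entity == "ADMA and SDMA" &
                ratios$sample_id == "CAL_start_L02", ]
  # noise-free ratio = (rf * c) / (rf * istd_mix); ADMA-d7 mix = 5000 ng/mL
  expect_equal(r$ratio, 100 / 5000)
  expect_true(r$normalized)
})

test_that("exact linear points fit to slope 1, intercept 0, R^2 1", {
  fit <- fit_calibration(c(1, 2, 4), c(1, 2, 4), min_points = 3)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(coef(fit)), c(0, 1), tolerance = 1e-12)
})

test_that("the weighted fit matches the normal-equations oracle on random instances", {
  set.seed(424242)
  for (i in 1:200) {
    n <- sample(5:12, 1)
    x <- sort(exp(runif(n, 0, 8)))
    y <- runif(1, 0.5, 5) * x + rnorm(n, 0, 0.1 * x) + runif(1, -1, 1)
    fit <- fit_calibration(x, y)
    oracle <- wls_oracle(x, y, 1 / x)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
    expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-10)
  }
})

test_that("too few calibration levels raise unless min_points is lowered", {
  expect_error(fit_calibration(c(1, 2, 4, 8), c(1, 2, 4, 8)),
               class = "srmquant_calibration_error")
  # the short-curve exception: explicit 3-point fit is allowed
  fit <- fit_calibration(c(1, 2, 4), c(1.1, 2.0, 4.2), min_points = 3)
  expect_s3_class(fit, "calibration_fit")
  # replicate measurements at the same level count as one level
  expect_error(fit_calibration(c(1, 1, 2, 2, 4, 4), c(1, 1, 2, 2, 4, 4)),
               class = "srmquant_calibration_error")
})

test_that("predict back-calculates concentrations by inverting the line", {
  fit <- fit_calibration(c(1, 2, 4, 8, 16), 0.5 + 2 * c(1, 2, 4, 8, 16))
  expect_equal(predict(fit, concentration = 10), 20.5, tolerance = 1e-9)
  expect_equal(predict(fit, ratio = 20.5), 10, tolerance = 1e-9)
  expect_error(predict(fit, concentration = 1, ratio = 1),
               class = "srmquant_argument_error")
})

test_that("LOD is the lowest level whose median S/N reaches the threshold", {
  # qualifying at the lowest measured level: flagged below-lowest
  lod <- determine_lod(c(2.5, 5, 10), c(5, 9, 20))
  expect_equal(lod$flag, "below_lowest")
  expect_equal(lod$label, "< 2.5")

  lod <- determine_lod(c(2.5, 5, 10, 25), c(1, 2, 4, 9))
  expect_equal(lod$flag, "measured")
  expect_equal(lod$value, 10)

  lod <- determine_lod(c(2.5, 5, 10), c(1, 1.5, 2))
  expect_equal(lod$flag, "above_highest")
  expect_equal(lod$label, "> 10")

  # median across replicate series at a level decides
  lod <- determine_lod(c(5, 5, 5), c(1, 4, 5))
  expect_equal(lod$flag, "below_lowest")
})

test_that("noise-free data keep the full 19-level linear range", {
  lv <- calibration_levels()
  x <- rep(lv, 2)
  y <- 3 * x + 0.5
  fit <- determine_linear_range(x, y)
  expect_equal(fit$lloq, 2.5)
  expect_equal(fit$uloq, 75000)
  expect_equal(length(fit$levels_used), 19L)
})

test_that("linear-range selection equals the exhaustive-scan oracle", {
  set.seed(20240917)
  n_checked <- 0
  for (i in 1:60) {
    lv <- calibration_levels()
    rf <- runif(1, 10, 100)
    noise_sd <- runif(1, 0, 400)
    x <- rep(lv, 2)
    y <- rf * x * (1 + rnorm(length(x), 0, 0.04)) +
      rnorm(length(x), 0, noise_sd)
    oracle <- range_oracle(x, y, min_points = 5)
    if (is.null(oracle)) {
      expect_error(determine_linear_range(x, y),
                   class = "srmquant_no_linear_range")
    } else {
      fit <- determine_linear_range(x, y)
      expect_equal(fit$lloq, oracle$lloq)
      expect_equal(fit$uloq, oracle$uloq)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 30)  # most draws must exercise the comparison
})

test_that("a failing middle level truncates the range on the longer side", {
  lv <- c(1, 2, 5, 10, 20, 50, 100, 200, 500, 1000)
  y <- 2 * lv
  y[lv == 20] <- 2 * 20 * 2.5  # gross outlier at one interior level
  fit <- determine_linear_range(lv, y, min_points = 3)
  oracle <- range_oracle(lv, y, min_points = 3)
  expect_equal(fit$lloq, oracle$lloq)
  expect_equal(fit$uloq, oracle$uloq)
  # the longer side (50..1000, 6 levels) wins over (1..10, 4 levels)
  expect_equal(fit$lloq, 50)
  expect_equal(fit$uloq, 1000)
})

test_that("apply_calibration inverts and flags against LOD/LLOQ/ULOQ", {
  fit <- fit_calibration(c(10, 100, 1000, 10000, 75000),
                         2 * c(10, 100, 1000, 10000, 75000))
  fit$lod <- determine_lod(c(10, 100), c(5, 50))  # below-lowest
  fit$lloq <- 100
  fit$uloq <- 10000
  ratios <- data.frame(
    sample_id = c("a", "b", "c", "d"), injection_index = 1L, entity = "E",
    ratio = c(2 * 1000, 2 * 50, 2 * 20000, -5), stringsAsFactors = FALSE
  )
  ct <- apply_calibration(ratios, fit)
  expect_equal(ct$concentration[1], 1000, tolerance = 1e-12)
  expect_equal(ct$flag, c("ok", "below_lloq", "above_uloq", "below_lod"))
  # value reported below LLOQ, absent below LOD
  expect_equal(ct$concentration[2], 50, tolerance = 1e-12)
  expect_true(is.na(ct$concentration[4]))

  fit$slope <- -1
  expect_error(apply_calibration(ratios, fit),
               class = "srmquant_calibration_error")
})

test_that("study injections below the S/N detection threshold are censored", {
  fit <- fit_calibration(c(10, 100, 1000, 10000, 75000),
                         2 * c(10, 100, 1000, 10000, 75000))
  fit$lod <- determine_lod(c(10, 100), c(5, 50))  # below-lowest, threshold 3
  ratios <- data.frame(
    sample_id = c("hi", "lo"), injection_index = 1L, entity = "E",
    ratio = c(2 * 500, 2 * 500), signal_to_noise = c(40, 1.2),
    stringsAsFactors = FALSE
  )
  ct <- apply_calibration(ratios, fit)
  expect_equal(ct$flag, c("ok", "below_lod"))
  expect_true(is.na(ct$concentration[2]))
})

test_that("measured LOD censors low back-calculations", {
  fit <- fit_calibration(c(10, 100, 1000, 10000, 75000),
                         2 * c(10, 100, 1000, 10000, 75000))
  fit$lod <- determine_lod(c(10, 100, 1000), c(1, 2, 5))  # LOD = 1000
  fit$lloq <- 10
  fit$uloq <- 75000
  ct <- apply_calibration(
    data.frame(sample_id = "a", injection_index = 1L, entity = "E",
               ratio = 2 * 500, stringsAsFactors = FALSE), fit)
  expect_equal(ct$flag, "below_lod")
  expect_true(is.na(ct$concentration))
})

test_that("noise-free quantitation round-trips true concentrations exactly", {
  panel <- small_panel()
  models <- noise_free_models(panel)
  cal <- simulate_calibration_series(panel, models = models, seed = 1)
  curves <- calibrate_panel(cal$peaks, cal$samples, panel)
  expect_length(curves, 3L)  # A, the merged pair, and D
  for (cv in curves) {
    expect_equal(cv$r_squared, 1, tolerance = 1e-12)
    expect_equal(cv$lloq, 2.5)
    expect_equal(cv$uloq, 75000)
  }
  # quantify an independent noise-free cohort and compare to truth
  co <- simulate_cohort(panel,
                        cohort_effect_spec(n_per_group = 5, replicate_cv = 0,
                                           residual_sd_log10 = 0.3),
                        seed = 2, models = models)
  conc <- quantify_samples(co$peaks, panel, curves)
  truth <- co$truth$true_concentration[
    match(paste(conc$sample_id, conc$entity),
          paste(co$truth$sample_id, co$truth$entity))]
  in_range <- conc$flag == "ok"
  expect_gt(sum(in_range), 0)
  expect_equal(conc$concentration[in_range], truth[in_range],
               tolerance = 1e-9)
})

test_that("back-calculation error stays small at 5% proportional noise", {
  panel <- synthetic_panel(5)
  models <- default_response_models(panel, proportional_cv = 0.05,
                                    baseline_noise_sd = 50, istd_cv = 0.03)
  cal <- simulate_calibration_series(panel, models = models, seed = 31)
  curves <- calibrate_panel(cal$peaks, cal$samples, panel)
  co <- simulate_cohort(panel,
                        cohort_effect_spec(n_per_group = 25,
                                           replicate_cv = 0.05),
                        seed = 32, models = models)
  conc <- quantify_samples(co$peaks, panel, curves)
  truth <- co$truth$true_concentration[
    match(paste(conc$sample_id, conc$entity),
          paste(co$truth$sample_id, co$truth$entity))]
  ok <- conc$flag == "ok"
  rel_err <- abs(conc$concentration[ok] - truth[ok]) / truth[ok]
  expect_lte(median(rel_err), 0.10)
})

test_that("LLOQ does not decrease as baseline noise grows", {
  panel <- synthetic_panel(1)
  lloqs <- sapply(c(0, 50, 200, 800, 3200), function(bsd) {
    models <- default_response_models(panel, proportional_cv = 0.02,
                                      baseline_noise_sd = bsd, istd_cv = 0)
    cal <- simulate_calibration_series(panel, models = models, seed = 99)
    curves <- calibrate_panel(cal$peaks, cal$samples, panel)
    curves$M01$lloq
  })
  expect_true(all(diff(lloqs) >= 0))
})

test_that("the per-entity min_points override supports short curves", {
  panel <- synthetic_panel(2)
  models <- noise_free_models(panel)
  cal <- simulate_calibration_series(panel, levels = c(10, 100, 1000),
                                     models = models, seed = 1)
  # default min_points = 5 fails on a 3-level series
  curves <- calibrate_panel(cal$peaks, cal$samples, panel)
  expect_length(curves, 0L)
  expect_length(attr(curves, "failures"), 2L)
  # explicit 3-point override fits both entities
  curves3 <- calibrate_panel(cal$peaks, cal$samples, panel, min_points = 3)
  expect_length(curves3, 2L)
})
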