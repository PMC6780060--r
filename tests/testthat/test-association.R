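test_that("the detection filter applies a strict over-70% rule", {
  conc <- rbind(conc_with_detection("kept72", 36, 50),    # 72% > 70%
                conc_with_detection("dropped70", 35, 50), # exactly 70%
                conc_with_detection("all", 50, 50))
  kept <- detection_filter(conc)
  expect_setequal(kept, c("kept72", "all"))
  frac <- attr(kept, "detection_fraction")
  expect_equal(unname(frac["kept72"]), 0.72)
  expect_equal(unname(frac["dropped70"]), 0.70)
})

test_that("a sample counts as detected if any replicate injection is detected", {
  conc <- data.frame(
    sample_id = rep(c("P1", "P2"), each = 3),
    injection_index = rep(1:3, 2), entity = "E",
    concentration = c(NA, NA, 50, NA, NA, NA),
    flag = c("below_lod", "below_lod", "ok",
             "below_lod", "below_lod", "below_lod"),
    stringsAsFactors = FALSE
  )
  kept <- detection_filter(conc, threshold = 0.4)
  expect_equal(unname(attr(kept, "detection_fraction")["E"]), 0.5)
})

test_that("BH adjustment matches its definition on worked examples", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(c(0.001, 1.0)), c(0.002, 1.0))
  expect_error(adjust_bh(c(0.1, 1.2)), class = "srmquant_argument_error")
  expect_error(adjust_bh(c(0.1, NA)), class = "srmquant_argument_error")
})

test_that("BH adjustment matches the brute-force step-up oracle and its laws", {
  set.seed(606)
  for (i in 1:300) {
    m <- sample(1:25, 1)
    p <- runif(m)^sample(1:3, 1)
    adj <- adjust_bh(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-14)
    # raw p <= adjusted p <= Bonferroni
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= pmin(m * p, 1) + 1e-15))
    # permutation equivariance
    perm <- sample(m)
    expect_equal(adjust_bh(p[perm]), adj[perm], tolerance = 1e-14)
  }
  # monotone in the inputs
  p <- c(0.01, 0.2, 0.5)
  expect_true(all(adjust_bh(p) <= adjust_bh(p + 0.1) + 1e-15))
})

# Shared fixture: quantified cohort with one strong planted group effect.
make_assoc_fixture <- function(seed, group_effect = 0.3, n_entities = 4) {
  panel <- synthetic_panel(n_entities)
  models <- default_response_models(panel, proportional_cv = 0.02,
                                    baseline_noise_sd = 20, istd_cv = 0.02)
  cal <- simulate_calibration_series(panel, models = models, seed = seed)
  curves <- calibrate_panel(cal$peaks, cal$samples, panel)
  eff <- stats::setNames(c(group_effect, rep(0, n_entities - 1)),
                         quantification_entities(panel)$entity)
  co <- simulate_cohort(panel,
                        cohort_effect_spec(n_per_group = 25,
                                           group_effect_log10 = eff,
                                           residual_sd_log10 = 0.2),
                        seed = seed + 1, models = models)
  list(panel = panel, curves = curves, cohort = co,
       conc = quantify_samples(co$peaks, panel, curves))
}

test_that("the mixed model recovers a planted group effect", {
  fx <- make_assoc_fixture(71, group_effect = 0.3)
  res <- fit_metabolite_model(fx$conc[fx$conc$entity == "M01", ],
                              fx$cohort$clinical)
  expect_equal(res$term[1], "group")
  expect_equal(res$estimate[res$term == "group"], 0.3, tolerance = 0.1)
  expect_lt(res$p_value[res$term == "group"], 0.01)
  expect_true(attr(res, "converged"))
})

test_that("near-noise-free data recover the planted effect almost exactly", {
  panel <- synthetic_panel(1)
  models <- default_response_models(panel, proportional_cv = 0,
                                    baseline_noise_sd = 0, istd_cv = 0)
  cal <- simulate_calibration_series(panel, models = models, seed = 3)
  curves <- calibrate_panel(cal$peaks, cal$samples, panel)
  co <- simulate_cohort(panel,
                        cohort_effect_spec(n_per_group = 10,
                                           group_effect_log10 = 0.4,
                                           residual_sd_log10 = 0.01,
                                           replicate_cv = 1e-3),
                        seed = 4, models = models)
  conc <- quantify_samples(co$peaks, panel, curves)
  res <- fit_metabolite_model(conc, co$clinical, terms = "group")
  expect_equal(res$estimate[res$term == "group"], 0.4, tolerance = 0.02)
  expect_lt(res$p_value[res$term == "group"], 1e-10)
})

test_that("aliased fixed effects raise a rank-deficiency error naming them", {
  fx <- make_assoc_fixture(91, n_entities = 1)
  clinical <- fx$cohort$clinical
  clinical$age_copy <- clinical$age
  expect_error(
    fit_metabolite_model(fx$conc, clinical,
                         terms = c("group", "age", "age_copy")),
    "age_copy", class = "srmquant_model_error"
  )
})

test_that("singleton injections cannot support the participant random effect", {
  fx <- make_assoc_fixture(95, n_entities = 1)
  single <- fx$conc[fx$conc$injection_index == 1L, ]
  expect_error(fit_metabolite_model(single, fx$cohort$clinical),
               class = "srmquant_model_error")
})

test_that("with vanishing replicate noise the group effect matches OLS on participant means", {
  panel <- synthetic_panel(1)
  models <- default_response_models(panel, proportional_cv = 0,
                                    baseline_noise_sd = 0, istd_cv = 0)
  cal <- simulate_calibration_series(panel, models = models, seed = 21)
  curves <- calibrate_panel(cal$peaks, cal$samples, panel)
  co <- simulate_cohort(panel,
                        cohort_effect_spec(n_per_group = 15,
                                           group_effect_log10 = 0.2,
                                           residual_sd_log10 = 0.15,
                                           replicate_cv = 1e-3),
                        seed = 22, models = models)
  conc <- quantify_samples(co$peaks, panel, curves)
  res <- fit_metabolite_model(conc, co$clinical, terms = c("group", "age"))

  means <- aggregate(log10(concentration) ~ sample_id, conc, mean)
  names(means)[2] <- "y"
  md <- merge(means, co$clinical, by.x = "sample_id", by.y = "participant_id")
  ols <- coef(lm(y ~ group + age, md))
  expect_equal(res$estimate[res$term == "group"], unname(ols["group"]),
               tolerance = 1e-6)
})

test_that("associations are BH-corrected per term across metabolites", {
  fx <- make_assoc_fixture(141, group_effect = 0.5, n_entities = 5)
  assoc <- associate_metabolites(fx$conc, fx$cohort$clinical,
                                 terms = c("group", "age"))
  expect_s3_class(assoc, "metabolite_associations")
  expect_equal(attr(assoc, "m"), 5L)
  for (tm in c("group", "age")) {
    sel <- assoc$term == tm
    expect_equal(assoc$adj_p_value[sel], adjust_bh(assoc$p_value[sel]),
                 tolerance = 1e-12)
  }
  expect_true(all(assoc$adj_p_value >= assoc$p_value - 1e-15))
  expect_equal(assoc$significant, assoc$adj_p_value < 0.05)
  # the strong planted effect on M01 is discovered
  expect_true(assoc$significant[assoc$entity == "M01" & assoc$term == "group"])
})

test_that("network edges mirror the significant associations", {
  fx <- make_assoc_fixture(151, group_effect = 0.5, n_entities = 5)
  assoc <- associate_metabolites(fx$conc, fx$cohort$clinical)
  net <- build_network(assoc)
  expect_equal(nrow(net), sum(assoc$significant))
  if (nrow(net)) {
    m <- match(paste(net$term, net$metabolite),
               paste(assoc$term, assoc$entity))
    expect_equal(net$coefficient, assoc$estimate[m])
    expect_equal(net$sign, ifelse(net$coefficient >= 0, "positive", "negative"))
    expect_equal(net$strength, log10(abs(net$coefficient)))
    expect_true(all(net$width > 0))
    expect_equal(net$highlighted, net$term %in% c("group", "egfr"))
  }

  # no significant results: empty edge list
  none <- assoc
  none$adj_p_value <- pmin(none$adj_p_value + 0.999, 1)
  expect_equal(nrow(build_network(none)), 0L)
})
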