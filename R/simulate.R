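#' Default calibration levels (ng/mL)
#'
#' The 19-level standard series used for calibration, spanning
#' 2.5-75,000 ng/mL.
#'
#' @return numeric vector of 19 strictly increasing concentrations.
#' @export
calibration_levels <- function() {
  c(2.5, 5, 7.5, 10, 25, 50, 75, 100, 250, 500, 750,
    1000, 2500, 5000, 7500, 10000, 25000, 50000, 75000)
}

#' Instrument response model for one quantification entity
#'
#' Describes how a true concentration maps to a detected peak area:
#' `area = response_factor * c * (1 + eps_prop) + eps_base`, with
#' multiplicative noise `eps_prop ~ N(0, proportional_cv^2)` (dominating at
#' high concentration, the heteroscedasticity that motivates 1/x-weighted
#' calibration) and additive baseline noise `eps_base ~
#' N(0, baseline_noise_sd^2)` (dominating at low concentration, creating a
#' finite limit of detection). Signal-to-noise is reported as
#' `area / baseline_noise_sd`. The matching ISTD channel responds at its
#' fixed mix concentration with coefficient of variation `istd_cv`;
#' `istd_stable = FALSE` marks an ISTD whose signal is not repeatable
#' (simulated as an inflated `istd_cv`).
#'
#' @param response_factor peak area per ng/mL of analyte.
#' @param istd_response_factor peak area per ng/mL of ISTD.
#' @param proportional_cv fractional multiplicative noise, in `[0, 1)`.
#' @param baseline_noise_sd additive noise standard deviation (area units).
#' @param istd_cv fractional ISTD area variability.
#' @param istd_stable logical; unstable ISTDs get `istd_cv` inflated to at
#'   least 0.25.
#' @return object of class `response_model`.
#' @export
response_model <- function(response_factor = 50,
                           istd_response_factor = 50,
                           proportional_cv = 0.05,
                           baseline_noise_sd = 200,
                           istd_cv = 0.03,
                           istd_stable = TRUE) {
  stopifnot(response_factor > 0,
            proportional_cv >= 0, proportional_cv < 1,
            baseline_noise_sd >= 0, istd_cv >= 0)
  if (!istd_stable) istd_cv <- max(istd_cv, 0.25)
  structure(
    list(response_factor = response_factor,
         istd_response_factor = istd_response_factor,
         proportional_cv = proportional_cv,
         baseline_noise_sd = baseline_noise_sd,
         istd_cv = istd_cv,
         istd_stable = istd_stable),
    class = "response_model"
  )
}

#' Default response models for each entity of a panel
#'
#' One [response_model()] per quantification entity. Entities without an
#' ISTD pairing are marked `istd_stable = FALSE` (their ISTD signal is the
#' reason the pairing is absent).
#'
#' @param panel an `analyte_panel`.
#' @param ... overrides passed to every [response_model()] call.
#' @return named list of `response_model` objects, one per entity.
#' @export
default_response_models <- function(panel, ...) {
  ents <- quantification_entities(panel)
  models <- lapply(seq_len(nrow(ents)), function(i) {
    response_model(istd_stable = ents$normalized[i], ...)
  })
  names(models) <- ents$entity
  models
}

# Deterministic nominal retention time per entity (minutes), spread over
# the 0.5-8.5 min elution window in entity order.
nominal_rt <- function(entities) {
  n <- length(entities)
  rt <- if (n == 1) 4.5 else 0.5 + 8 * (seq_len(n) - 1) / (n - 1)
  stats::setNames(rt, entities)
}

empty_peaks <- function() {
  data.frame(sample_id = character(), injection_index = integer(),
             entity = character(), channel = character(),
             retention_time_min = numeric(), peak_area = numeric(),
             signal_to_noise = numeric(), stringsAsFactors = FALSE)
}

# ISTD mix concentration per entity (NA when the entity has no ISTD).
entity_istd_conc <- function(panel) {
  ents <- quantification_entities(panel)
  conc <- rep(NA_real_, nrow(ents))
  has <- nzchar(ents$istd_abbreviation)
  idx <- match(ents$istd_abbreviation[has], panel$istds$abbreviation)
  conc[has] <- panel$istds$mix_concentration_ng_per_ml[idx]
  stats::setNames(conc, ents$entity)
}

#' Simulate a two-series calibration standard sequence
#'
#' Generates peak tables for the calibration standards of each
#' quantification entity, one full series at the start and one at the end
#' of the injection sequence, with proportional-plus-additive Gaussian
#' noise on areas (see [response_model()]) and matching ISTD peaks at the
#' ISTD MIX concentration.
#'
#' @param panel an `analyte_panel`.
#' @param levels standard concentrations (ng/mL), strictly increasing and
#'   positive. Defaults to the 19-level series of [calibration_levels()].
#' @param models named list of [response_model()] per entity; defaults to
#'   [default_response_models()].
#' @param seed integer seed; all randomness in the simulation derives
#'   from it.
#' @return list of class `srm_calibration_sim` with elements `peaks`
#'   (long-format peak table: `sample_id`, `injection_index`, `entity`,
#'   `channel`, `retention_time_min`, `peak_area`, `signal_to_noise`),
#'   `samples` (sample metadata: `sample_id`, `sample_type`,
#'   `nominal_concentration`, `series` in `start`/`end`), and `truth`
#'   (true concentration per sample and entity).
#' @export
simulate_calibration_series <- function(panel,
                                        levels = calibration_levels(),
                                        models = default_response_models(panel),
                                        seed = 1L) {
  stopifnot(inherits(panel, "analyte_panel"))
  if (any(!is.finite(levels)) || any(levels <= 0)) {
    stop_srm("calibration levels must be positive", class = "srmquant_argument_error")
  }
  if (is.unsorted(levels, strictly = TRUE)) {
    stop_srm("calibration levels must be strictly increasing",
             class = "srmquant_argument_error")
  }
  ents <- quantification_entities(panel)$entity
  stopifnot(all(ents %in% names(models)))
  istd_conc <- entity_istd_conc(panel)
  rts <- nominal_rt(ents)

  sids <- c(sprintf("CAL_start_L%02d", seq_along(levels)),
            sprintf("CAL_end_L%02d", seq_along(levels)))
  series <- rep(c("start", "end"), each = length(levels))
  nominal <- rep(levels, 2L)
  samples <- data.frame(
    sample_id = sids, sample_type = "standard",
    nominal_concentration = nominal, series = series,
    stringsAsFactors = FALSE
  )
  with_seed(seed, {
    peaks_list <- vector("list", length(ents))
    truth_list <- vector("list", length(ents))
    for (k in seq_along(ents)) {
      e <- ents[k]
      peaks_list[[k]] <- sim_peak_block(sids, 1L, e, nominal, models[[e]],
                                        istd_conc[e], rts[e],
                                        prop_cv = models[[e]]$proportional_cv)
      truth_list[[k]] <- data.frame(
        sample_id = sids, entity = e, true_concentration = nominal,
        stringsAsFactors = FALSE
      )
    }
    structure(
      list(peaks = do.call(rbind, c(peaks_list, make.row.names = FALSE)),
           samples = samples,
           truth = do.call(rbind, c(truth_list, make.row.names = FALSE))),
      class = "srm_calibration_sim"
    )
  })
}

# Vectorized analyte + optional ISTD peak rows for one entity over a block
# of injections at known true concentrations.
sim_peak_block <- function(sample_id, injection_index, entity, conc, m,
                           istd_conc, rt0, prop_cv, area_scale = 1,
                           rt_jitter_sd = 0.005) {
  k <- length(conc)
  area <- m$response_factor * conc * area_scale *
    (1 + stats::rnorm(k, 0, prop_cv)) +
    stats::rnorm(k, 0, m$baseline_noise_sd)
  area <- pmax(area, 0)
  sn <- if (m$baseline_noise_sd > 0) area / m$baseline_noise_sd else Inf
  out <- data.frame(
    sample_id = sample_id,
    injection_index = rep_len(injection_index, k),
    entity = entity, channel = "analyte",
    retention_time_min = rt0 + stats::rnorm(k, 0, rt_jitter_sd),
    peak_area = area, signal_to_noise = sn, stringsAsFactors = FALSE
  )
  if (!is.na(istd_conc)) {
    iarea <- m$istd_response_factor * istd_conc *
      (1 + stats::rnorm(k, 0, m$istd_cv)) +
      stats::rnorm(k, 0, m$baseline_noise_sd)
    iarea <- pmax(iarea, 0)
    isn <- if (m$baseline_noise_sd > 0) iarea / m$baseline_noise_sd else Inf
    out <- rbind(out, data.frame(
      sample_id = sample_id,
      injection_index = rep_len(injection_index, k),
      entity = entity, channel = "istd",
      retention_time_min = rt0 + stats::rnorm(k, 0, rt_jitter_sd),
      peak_area = iarea, signal_to_noise = isn, stringsAsFactors = FALSE
    ))
  }
  out
}

#' Simulate quality-control replicate injections
#'
#' Generates the repeatability study design: for each QC level, a block of
#' `intra_n` consecutive runs on one day (intra-day) and `days` x
#' `runs_per_day` runs on consecutive days (inter-day). A per-day
#' multiplicative shift drawn from `N(0, day_cv^2)` is applied to the
#' analyte channel of the inter-day runs (not to the ISTD channel, so it
#' survives normalization), producing inter-day dispersion exceeding
#' intra-day dispersion.
#'
#' @inheritParams simulate_calibration_series
#' @param qc_levels QC concentrations (ng/mL); defaults to 100, 1000
#'   and 10,000.
#' @param intra_n consecutive runs in the intra-day block.
#' @param days,runs_per_day inter-day design.
#' @param day_cv fractional between-day shift SD.
#' @return list of class `srm_qc_sim` with `peaks` and `samples`
#'   (`sample_id`, `sample_type`, `qc_level`, `block` in `intra`/`inter`,
#'   `day`, `run`).
#' @export
simulate_qc_replicates <- function(panel,
                                   qc_levels = c(100, 1000, 10000),
                                   intra_n = 4L, days = 5L, runs_per_day = 3L,
                                   models = default_response_models(panel),
                                   day_cv = 0.08,
                                   seed = 1L) {
  stopifnot(inherits(panel, "analyte_panel"),
            intra_n >= 1, days >= 1, runs_per_day >= 1,
            all(qc_levels > 0))
  ents <- quantification_entities(panel)$entity
  istd_conc <- entity_istd_conc(panel)
  rts <- nominal_rt(ents)

  # run design: intra block (one day) then the inter-day grid, per level
  intra <- expand.grid(run = seq_len(intra_n), qc_level = qc_levels,
                       KEEP.OUT.ATTRS = FALSE)
  intra$block <- "intra"
  intra$day <- 0L
  intra$sample_id <- sprintf("QC_%g_intra_r%d", intra$qc_level, intra$run)
  inter <- expand.grid(run = seq_len(runs_per_day), day = seq_len(days),
                       qc_level = qc_levels, KEEP.OUT.ATTRS = FALSE)
  inter$block <- "inter"
  inter$sample_id <- sprintf("QC_%g_d%d_r%d", inter$qc_level, inter$day,
                             inter$run)
  design <- rbind(intra[, c("sample_id", "qc_level", "block", "day", "run")],
                  inter[, c("sample_id", "qc_level", "block", "day", "run")])
  samples <- data.frame(sample_id = design$sample_id, sample_type = "qc",
                        qc_level = design$qc_level, block = design$block,
                        day = design$day, run = design$run,
                        stringsAsFactors = FALSE)

  with_seed(seed, {
    day_shift <- 1 + stats::rnorm(days, 0, day_cv)
    scale <- ifelse(design$block == "inter", day_shift[pmax(design$day, 1L)], 1)
    peaks_list <- lapply(seq_along(ents), function(k) {
      e <- ents[k]
      sim_peak_block(design$sample_id, 1L, e, design$qc_level, models[[e]],
                     istd_conc[e], rts[e],
                     prop_cv = models[[e]]$proportional_cv,
                     area_scale = scale)
    })
    structure(
      list(peaks = do.call(rbind, c(peaks_list, make.row.names = FALSE)),
           samples = samples),
      class = "srm_qc_sim"
    )
  })
}

#' Cohort simulation design
#'
#' Parameters of the synthetic clinical cohort: group sizes, planted
#' group and covariate effects on log10 concentration, residual and
#' replicate dispersion, and the per-metabolite non-detection rate.
#' Planted effects may be scalars (applied to every entity) or named
#' vectors keyed by entity.
#'
#' @param n_per_group participants per albuminuria group (>= 2).
#' @param group_effect_log10 effect of group membership on log10
#'   concentration.
#' @param covariate_effects named list, covariate name -> effect per unit
#'   of the (mean-centered) covariate on log10 concentration.
#' @param residual_sd_log10 between-participant residual SD of log10
#'   concentration (> 0).
#' @param replicate_cv fractional technical-replicate noise on peak areas.
#' @param missingness_rate per-metabolite probability that a participant's
#'   true concentration falls below the detection limit.
#' @param baseline_log10 baseline log10 concentration (ng/mL).
#' @param n_replicates technical replicate injections per sample.
#' @return object of class `cohort_effect_spec`.
#' @export
cohort_effect_spec <- function(n_per_group = 25L,
                               group_effect_log10 = 0,
                               covariate_effects = list(),
                               residual_sd_log10 = 0.2,
                               replicate_cv = 0.05,
                               missingness_rate = 0,
                               baseline_log10 = 3,
                               n_replicates = 3L) {
  if (n_per_group < 2) {
    stop_srm("n_per_group must be >= 2", class = "srmquant_argument_error")
  }
  stopifnot(residual_sd_log10 > 0,
            missingness_rate >= 0, missingness_rate <= 1,
            replicate_cv >= 0, n_replicates >= 1)
  structure(
    list(n_per_group = as.integer(n_per_group),
         group_effect_log10 = group_effect_log10,
         covariate_effects = covariate_effects,
         residual_sd_log10 = residual_sd_log10,
         replicate_cv = replicate_cv,
         missingness_rate = missingness_rate,
         baseline_log10 = baseline_log10,
         n_replicates = as.integer(n_replicates)),
    class = "cohort_effect_spec"
  )
}

# Effect value for one entity from a scalar or entity-named vector.
effect_for <- function(eff, entity) {
  if (length(eff) == 1L && is.null(names(eff))) return(as.numeric(eff))
  if (!is.null(names(eff))) {
    return(if (entity %in% names(eff)) as.numeric(eff[[entity]]) else 0)
  }
  as.numeric(eff[1])
}

# Continuous covariate samplers (documented placeholder distributions; the
# source study reports no cohort distribution table).
cohort_continuous_defs <- function() {
  list(age = c(55, 10), bmi = c(25, 4), hba1c = c(8, 1), egfr = c(80, 20),
       sbp = c(130, 15), total_cholesterol = c(4.8, 0.9),
       total_triglycerides = c(1.3, 0.6), diabetes_duration = c(25, 10),
       insulin_dose = c(50, 15))
}

cohort_binary_defs <- function() {
  c("sex", "smoking", "antihypertensive_medication", "statin_medication")
}

#' Simulate a clinical cohort with technical triplicates
#'
#' Generates participant covariates, true metabolite concentrations with
#' planted group/covariate effects on the log10 scale, and a peak table
#' with `n_replicates` replicate injections per participant sample.
#' True log10 concentration for participant p and entity e is
#' `baseline + group_effect * group_p + sum_k beta_k * (x_pk - mean(x_k))
#' + N(0, residual_sd^2)`. With probability `missingness_rate` a
#' participant/entity concentration is replaced by a value well below the
#' entity's detection limit, exercising the downstream detection filter.
#'
#' @inheritParams simulate_calibration_series
#' @param spec a [cohort_effect_spec()].
#' @return list of class `srm_cohort_sim` with `clinical` (one row per
#'   participant: `participant_id`, `group` 0/1, continuous and binary
#'   covariates), `truth`, `peaks`, and `samples` (sample metadata linking
#'   `sample_id` to `participant_id`).
#' @export
simulate_cohort <- function(panel, spec = cohort_effect_spec(), seed = 1L,
                            models = default_response_models(panel)) {
  stopifnot(inherits(panel, "analyte_panel"),
            inherits(spec, "cohort_effect_spec"))
  ents <- quantification_entities(panel)$entity
  istd_conc <- entity_istd_conc(panel)
  rts <- nominal_rt(ents)
  n <- 2L * spec$n_per_group

  with_seed(seed, {
    clinical <- data.frame(
      participant_id = sprintf("P%03d", seq_len(n)),
      group = rep(c(0L, 1L), each = spec$n_per_group),
      stringsAsFactors = FALSE
    )
    for (nm in names(cohort_continuous_defs())) {
      d <- cohort_continuous_defs()[[nm]]
      clinical[[nm]] <- stats::rnorm(n, d[1], d[2])
    }
    for (nm in cohort_binary_defs()) {
      clinical[[nm]] <- stats::rbinom(n, 1L, 0.5)
    }

    cov_names <- names(spec$covariate_effects)
    centered <- lapply(cov_names, function(nm) {
      if (!nm %in% names(clinical)) {
        stop_srm("covariate_effects names unknown covariate: ", nm,
                 class = "srmquant_argument_error")
      }
      clinical[[nm]] - mean(clinical[[nm]])
    })
    names(centered) <- cov_names

    peaks_list <- list()
    truth_list <- list()
    for (e in ents) {
      m <- models[[e]]
      ge <- effect_for(spec$group_effect_log10, e)
      mu <- spec$baseline_log10 + ge * clinical$group
      for (nm in cov_names) {
        mu <- mu + effect_for(spec$covariate_effects[[nm]], e) * centered[[nm]]
      }
      log10c <- mu + stats::rnorm(n, 0, spec$residual_sd_log10)
      conc <- 10^log10c
      # non-detects: push below the entity's area-derived detection limit
      lod_guess <- if (m$baseline_noise_sd > 0) {
        3 * m$baseline_noise_sd / m$response_factor
      } else {
        0
      }
      masked <- stats::runif(n) < spec$missingness_rate
      conc[masked] <- lod_guess * 0.05
      truth_list[[e]] <- data.frame(
        sample_id = clinical$participant_id, entity = e,
        true_concentration = conc, masked = masked,
        stringsAsFactors = FALSE
      )
      rep_idx <- rep(seq_len(spec$n_replicates), times = n)
      peaks_list[[e]] <- sim_peak_block(
        rep(clinical$participant_id, each = spec$n_replicates), rep_idx, e,
        rep(conc, each = spec$n_replicates), m, istd_conc[e], rts[e],
        prop_cv = spec$replicate_cv
      )
    }
    samples <- data.frame(
      sample_id = clinical$participant_id,
      sample_type = "study",
      participant_id = clinical$participant_id,
      stringsAsFactors = FALSE
    )
    structure(
      list(clinical = clinical,
           truth = do.call(rbind, c(truth_list, make.row.names = FALSE)),
           peaks = do.call(rbind, c(peaks_list, make.row.names = FALSE)),
           samples = samples),
      class = "srm_cohort_sim"
    )
  })
}

#' Construct a simple synthetic panel
#'
#' Builds a minimal valid panel of `n_entities` stand-alone analytes
#' (`M01`, `M02`, ...), each with one quantifier transition and its own
#' ISTD, for simulation studies where the full clinical panel is not
#' needed.
#'
#' @param n_entities number of analytes.
#' @param istd logical; if `FALSE` the analytes carry no ISTD pairing.
#' @return an `analyte_panel`.
#' @export
synthetic_panel <- function(n_entities = 20L, istd = TRUE) {
  stopifnot(n_entities >= 1)
  ab <- sprintf("M%02d", seq_len(n_entities))
  analytes <- data.frame(
    abbreviation = ab, name = ab, group = "other",
    precursor_mz = 200 + seq_len(n_entities),
    product_mz = 100 + seq_len(n_entities),
    polarity = "negative", role = "quantifier",
    istd_abbreviation = if (istd) sprintf("IS%02d", seq_len(n_entities)) else "",
    co_quantified_group = "", stringsAsFactors = FALSE
  )
  istds <- if (istd) {
    data.frame(abbreviation = sprintf("IS%02d", seq_len(n_entities)),
               mix_concentration_ng_per_ml = 1000,
               stringsAsFactors = FALSE)
  } else {
    data.frame(abbreviation = character(),
               mix_concentration_ng_per_ml = numeric())
  }
  build_panel(analytes, istds)
}
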