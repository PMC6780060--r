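#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Unknown
#' keys are rejected; the object round-trips through YAML serialization
#' unchanged.
#'
#' @param seed integer master seed; every stage derives its own seed from
#'   it, so a config + seed pair determines all outputs byte-for-byte.
#' @param panel name of a built-in panel fixture or path to an analyte CSV.
#' @param levels calibration levels (ng/mL).
#' @param qc_levels QC concentrations for the repeatability study.
#' @param min_points minimum calibration levels per curve.
#' @param accuracy_band back-calculated accuracy bounds (fractions).
#' @param detection_threshold detection fraction that must be exceeded.
#' @param pool_per_group simulated cohort size per group before selection.
#' @param k_per_group selected subsample size per group.
#' @param n_draws subsample draw budget.
#' @param alpha significance level on adjusted p-values.
#' @param model_terms fixed-effect terms of the metabolite models.
#' @param log10_response model concentrations on the log10 scale.
#' @param group_effect_log10 planted group effect for the simulated
#'   cohort (scalar or named per-entity).
#' @param missingness_rate simulated per-metabolite non-detection rate.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            panel = "diabetes_t1d_34",
                            levels = calibration_levels(),
                            qc_levels = c(100, 1000, 10000),
                            min_points = 5L,
                            accuracy_band = c(0.8, 1.2),
                            detection_threshold = 0.70,
                            pool_per_group = 60L,
                            k_per_group = 25L,
                            n_draws = 10000,
                            alpha = 0.05,
                            model_terms = association_terms(),
                            log10_response = TRUE,
                            group_effect_log10 = 0,
                            missingness_rate = 0.05) {
  cfg <- list(seed = as.integer(seed), panel = panel, levels = levels,
              qc_levels = qc_levels, min_points = min_points,
              accuracy_band = accuracy_band,
              detection_threshold = detection_threshold,
              pool_per_group = as.integer(pool_per_group),
              k_per_group = as.integer(k_per_group),
              n_draws = n_draws, alpha = alpha, model_terms = model_terms,
              log10_response = log10_response,
              group_effect_log10 = group_effect_log10,
              missingness_rate = missingness_rate)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop_srm("unknown config keys: ", paste(unknown, collapse = ", "),
             class = "srmquant_config_error")
  }
  missing_keys <- setdiff(known, names(cfg))
  if (length(missing_keys)) {
    stop_srm("config lacks keys: ", paste(missing_keys, collapse = ", "),
             class = "srmquant_config_error")
  }
  stopifnot(cfg$alpha > 0, cfg$alpha < 1,
            cfg$detection_threshold >= 0, cfg$detection_threshold <= 1,
            cfg$min_points >= 2, cfg$k_per_group >= 2,
            cfg$pool_per_group >= cfg$k_per_group,
            cfg$n_draws >= 1,
            length(cfg$accuracy_band) == 2,
            cfg$accuracy_band[1] > 0,
            cfg$accuracy_band[1] < cfg$accuracy_band[2],
            all(cfg$levels > 0), all(cfg$qc_levels > 0))
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config a `pipeline_config`.
#' @return `read_config()` returns a validated `pipeline_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  fnv1a_hash(yaml::as.yaml(unclass(config)))
}

#' Run the end-to-end pipeline
#'
#' Executes simulate, quantify, validate, select-cohort, associate and
#' network stages in order on synthetic data generated under the config's
#' seed, writing each stage's output as CSV with a provenance header
#' (config hash and seed). Running twice with the same config produces
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the stage result objects and the paths
#'   written.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(paste("config_hash:", config_hash(config)),
           paste("seed:", config$seed))
  panel <- load_panel(config$panel)
  models <- default_response_models(panel)

  cal <- simulate_calibration_series(panel, levels = config$levels,
                                     models = models,
                                     seed = child_seed(config$seed, "calibration"))
  qc <- simulate_qc_replicates(panel, qc_levels = config$qc_levels,
                               models = models,
                               seed = child_seed(config$seed, "qc"))
  cohort <- simulate_cohort(
    panel,
    spec = cohort_effect_spec(n_per_group = config$pool_per_group,
                              group_effect_log10 = config$group_effect_log10,
                              missingness_rate = config$missingness_rate),
    seed = child_seed(config$seed, "cohort"),
    models = models
  )

  curves <- calibrate_panel(cal$peaks, cal$samples, panel,
                            min_points = config$min_points,
                            accuracy_band = config$accuracy_band)
  cal_report <- calibration_report(curves)
  conc <- quantify_samples(cohort$peaks, panel, curves)
  rep_report <- repeatability_report(qc$peaks, qc$samples, panel)

  selection <- select_balanced_subsample(
    cohort$clinical, k_per_group = config$k_per_group,
    n_draws = config$n_draws,
    seed = child_seed(config$seed, "selection")
  )
  sel_clinical <- cohort$clinical[
    cohort$clinical$participant_id %in% selection$selected_ids, , drop = FALSE]
  sel_conc <- conc[conc$sample_id %in% selection$selected_ids, , drop = FALSE]

  assoc <- associate_metabolites(sel_conc, sel_clinical,
                                 terms = config$model_terms,
                                 alpha = config$alpha,
                                 detection_threshold = config$detection_threshold,
                                 log10_response = config$log10_response)
  network <- build_network(assoc, alpha = config$alpha)

  paths <- c(
    peaks_calibration = file.path(out_dir, "peaks_calibration.csv"),
    peaks_qc = file.path(out_dir, "peaks_qc.csv"),
    peaks_cohort = file.path(out_dir, "peaks_cohort.csv"),
    clinical = file.path(out_dir, "clinical.csv"),
    calibration_report = file.path(out_dir, "calibration_report.csv"),
    concentrations = file.path(out_dir, "concentrations.csv"),
    validation_report = file.path(out_dir, "validation_report.csv"),
    subsample = file.path(out_dir, "subsample.csv"),
    balance = file.path(out_dir, "balance_report.csv"),
    associations = file.path(out_dir, "associations.csv"),
    network = file.path(out_dir, "network_edges.csv")
  )
  write_stage_csv(cal$peaks, paths["peaks_calibration"], hdr)
  write_stage_csv(qc$peaks, paths["peaks_qc"], hdr)
  write_stage_csv(cohort$peaks, paths["peaks_cohort"], hdr)
  write_stage_csv(cohort$clinical, paths["clinical"], hdr)
  write_stage_csv(cal_report, paths["calibration_report"], hdr)
  write_stage_csv(conc, paths["concentrations"], hdr)
  write_stage_csv(as.data.frame(rep_report), paths["validation_report"], hdr)
  write_stage_csv(data.frame(participant_id = selection$selected_ids),
                  paths["subsample"], hdr)
  write_stage_csv(balance_report(selection, cohort$clinical),
                  paths["balance"], hdr)
  write_stage_csv(as.data.frame(assoc), paths["associations"], hdr)
  write_stage_csv(as.data.frame(network), paths["network"], hdr)

  invisible(list(panel = panel, curves = curves, calibration_report = cal_report,
                 concentrations = conc, validation_report = rep_report,
                 selection = selection, associations = assoc,
                 network = network, paths = paths))
}
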