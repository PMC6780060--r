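#' Normalize analyte peak areas to internal-standard areas
#'
#' For every (sample, injection, entity), divides the analyte peak area by
#' the matching ISTD peak area. Entities without an ISTD pairing pass
#' their raw analyte area through unchanged and are tagged
#' `normalized = FALSE`. Rows whose required ISTD peak is missing, or
#' whose ISTD area is zero, are kept with an `NA` ratio and a diagnostic
#' `status` (`missing_istd`, `zero_istd`) rather than silently dropped.
#'
#' @param peaks long-format peak table with columns `sample_id`,
#'   `injection_index`, `entity`, `channel` (`analyte`/`istd`),
#'   `peak_area`, and optionally `retention_time_min`, `signal_to_noise`.
#' @param panel an `analyte_panel`.
#' @return data frame with columns `sample_id`, `injection_index`,
#'   `entity`, `ratio`, `normalized`, `status`, plus the analyte channel's
#'   `peak_area`, `retention_time_min`, `signal_to_noise` when present.
#'   Rows with `status != "ok"` are the per-row error records.
#' @export
normalize_to_istd <- function(peaks, panel) {
  stopifnot(inherits(panel, "analyte_panel"))
  req <- c("sample_id", "injection_index", "entity", "channel", "peak_area")
  if (!all(req %in% names(peaks))) {
    stop_srm("peak table lacks columns: ",
             paste(setdiff(req, names(peaks)), collapse = ", "),
             class = "srmquant_schema_error")
  }
  ents <- quantification_entities(panel)
  unknown <- setdiff(unique(peaks$entity), ents$entity)
  if (length(unknown)) {
    stop_srm("peak table entities not in panel: ",
             paste(unknown, collapse = ", "),
             class = "srmquant_schema_error")
  }
  an <- peaks[peaks$channel == "analyte", , drop = FALSE]
  is_ <- peaks[peaks$channel == "istd", , drop = FALSE]
  key <- function(df) paste(df$sample_id, df$injection_index, df$entity, sep = "\r")
  istd_area <- stats::setNames(is_$peak_area, key(is_))

  norm_flag <- stats::setNames(ents$normalized, ents$entity)
  needs_istd <- norm_flag[an$entity]
  iarea <- istd_area[key(an)]

  ratio <- ifelse(needs_istd, an$peak_area / iarea, an$peak_area)
  status <- rep("ok", nrow(an))
  status[needs_istd & is.na(iarea)] <- "missing_istd"
  status[needs_istd & !is.na(iarea) & iarea == 0] <- "zero_istd"
  ratio[status != "ok"] <- NA_real_

  out <- data.frame(
    sample_id = an$sample_id, injection_index = an$injection_index,
    entity = an$entity, ratio = as.numeric(ratio),
    normalized = as.logical(needs_istd), status = status,
    peak_area = an$peak_area, stringsAsFactors = FALSE
  )
  for (col in c("retention_time_min", "signal_to_noise")) {
    if (col %in% names(an)) out[[col]] <- an[[col]]
  }
  rownames(out) <- NULL
  out
}

#' Fit a 1/x-weighted linear calibration curve
#'
#' Weighted least-squares regression of response (area ratio) on nominal
#' concentration with weights `1/x`, the standard countermeasure for
#' proportional (heteroscedastic) detector noise in bioanalytical
#' calibration. The fit is the exact solution of the two-parameter
#' weighted normal equations (via [stats::lm()]); the coefficient of
#' determination is the weighted R-squared.
#'
#' @param concentration nominal standard concentrations (ng/mL); replicate
#'   points at the same level are allowed and pooled.
#' @param ratio measured responses (ISTD-normalized area ratios, or raw
#'   areas for unnormalized entities).
#' @param entity optional entity label carried into the result.
#' @param min_points minimum number of distinct concentration levels
#'   (default 5; lower it explicitly for short curves such as analytes
#'   quantifiable at only three levels).
#' @param weighting weighting scheme; only `"one_over_x"` is supported.
#' @return object of class `calibration_fit` with elements `entity`,
#'   `slope`, `intercept`, `r_squared`, `weighting`, `levels_used`, `n`,
#'   and (once set by [determine_linear_range()] / [calibrate_panel()])
#'   `lod`, `lloq`, `uloq`.
#' @examples
#' fit <- fit_calibration(c(1, 2, 4, 8, 16), c(1.1, 2.2, 4.1, 8.3, 15.9),
#'                        entity = "demo")
#' coef(fit)
#' predict(fit, concentration = 10)
#' @export
fit_calibration <- function(concentration, ratio, entity = NA_character_,
                            min_points = 5L, weighting = "one_over_x") {
  if (!identical(weighting, "one_over_x")) {
    stop_srm("unsupported weighting: ", weighting,
             class = "srmquant_argument_error")
  }
  keep <- is.finite(concentration) & is.finite(ratio)
  concentration <- concentration[keep]
  ratio <- ratio[keep]
  if (any(concentration <= 0)) {
    stop_srm("concentrations must be positive for 1/x weighting",
             class = "srmquant_argument_error")
  }
  levels_used <- sort(unique(concentration))
  if (length(levels_used) < min_points) {
    stop_srm("calibration needs >= ", min_points,
             " distinct levels with finite responses; got ",
             length(levels_used),
             class = "srmquant_calibration_error")
  }
  df <- data.frame(concentration = concentration, ratio = ratio)
  fit <- stats::lm(ratio ~ concentration, data = df,
                   weights = 1 / concentration)
  cf <- stats::coef(fit)
  # weighted coefficient of determination, computed directly (summary.lm
  # warns on exact fits)
  w <- 1 / concentration
  ybar_w <- sum(w * ratio) / sum(w)
  ss_tot <- sum(w * (ratio - ybar_w)^2)
  ss_res <- sum(w * stats::residuals(fit)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(
    list(entity = entity,
         slope = unname(cf["concentration"]),
         intercept = unname(cf["(Intercept)"]),
         r_squared = r2,
         weighting = weighting,
         levels_used = levels_used,
         n = nrow(df),
         lod = NULL, lloq = min(levels_used), uloq = max(levels_used),
         lm = fit, data = df),
    class = "calibration_fit"
  )
}

#' @export
coef.calibration_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.calibration_fit <- function(object, ...) {
  stats::residuals(object$lm)
}

#' Predict from a calibration curve
#'
#' With `concentration` supplied, returns the fitted response; with
#' `ratio` supplied, back-calculates concentration
#' `(ratio - intercept) / slope`.
#'
#' @param object a `calibration_fit`.
#' @param concentration concentrations at which to predict responses.
#' @param ratio responses to back-calculate into concentrations.
#' @param ... unused.
#' @export
predict.calibration_fit <- function(object, concentration = NULL,
                                    ratio = NULL, ...) {
  if (!is.null(concentration) && !is.null(ratio)) {
    stop_srm("supply either concentration or ratio, not both",
             class = "srmquant_argument_error")
  }
  if (!is.null(ratio)) {
    return((ratio - object$intercept) / object$slope)
  }
  if (is.null(concentration)) {
    return(stats::fitted(object$lm))
  }
  object$intercept + object$slope * concentration
}

#' @export
print.calibration_fit <- function(x, digits = 4, ...) {
  cat("1/x-weighted calibration",
      if (!is.na(x$entity)) paste0("for ", x$entity), "\n")
  cat(sprintf("  slope %.*g, intercept %.*g, weighted R^2 %.*g (n = %d, %d levels)\n",
              digits, x$slope, digits, x$intercept, digits, x$r_squared,
              x$n, length(x$levels_used)))
  if (!is.null(x$lod)) cat("  LOD:", format_lod(x$lod), "ng/mL\n")
  cat(sprintf("  linear range: %g - %g ng/mL\n", x$lloq, x$uloq))
  invisible(x)
}

#' @export
summary.calibration_fit <- function(object, ...) {
  s <- summary(object$lm)
  out <- list(entity = object$entity, coefficients = s$coefficients,
              r_squared = object$r_squared, lod = object$lod,
              lloq = object$lloq, uloq = object$uloq,
              levels_used = object$levels_used)
  class(out) <- "summary.calibration_fit"
  out
}

#' @export
print.summary.calibration_fit <- function(x, ...) {
  cat("Calibration summary", if (!is.na(x$entity)) paste0("(", x$entity, ")"), "\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("Weighted R^2: %.5f; range %g - %g ng/mL; levels: %s\n",
              x$r_squared, x$lloq, x$uloq,
              paste(x$levels_used, collapse = ", ")))
  if (!is.null(x$lod)) cat("LOD:", format_lod(x$lod), "ng/mL\n")
  invisible(x)
}

#' @export
plot.calibration_fit <- function(x, ...) {
  graphics::plot(x$data$concentration, x$data$ratio, log = "xy",
                 xlab = "nominal concentration (ng/mL)",
                 ylab = "response (area ratio)",
                 main = if (!is.na(x$entity)) x$entity else "calibration", ...)
  cs <- exp(seq(log(min(x$data$concentration)),
                log(max(x$data$concentration)), length.out = 100))
  graphics::lines(cs, pmax(x$intercept + x$slope * cs, .Machine$double.eps),
                  col = "steelblue")
  graphics::abline(v = c(x$lloq, x$uloq), lty = 2, col = "grey50")
  invisible(x)
}

#' Determine the limit of detection from standard-series signal-to-noise
#'
#' The LOD is the lowest nominal level whose median signal-to-noise across
#' replicate series reaches the threshold (S/N >= 3 by default). When the
#' lowest measured level already qualifies, the LOD is reported as below
#' the lowest level (rendered `"< 2.5"` for a series starting at
#' 2.5 ng/mL); when no level qualifies, as above the highest.
#'
#' @param level nominal concentrations of the standard injections.
#' @param signal_to_noise matching S/N values.
#' @param threshold S/N threshold (default 3).
#' @return object of class `lod_estimate`: list with `value` (numeric LOD,
#'   or the boundary level for flagged results), `flag` (`measured`,
#'   `below_lowest`, `above_highest`) and `label`.
#' @export
determine_lod <- function(level, signal_to_noise, threshold = 3) {
  keep <- is.finite(level) & !is.na(signal_to_noise)
  level <- level[keep]
  signal_to_noise <- signal_to_noise[keep]
  if (!length(level)) {
    stop_srm("no signal-to-noise data for LOD determination",
             class = "srmquant_argument_error")
  }
  med <- tapply(signal_to_noise, level, stats::median)
  lv <- as.numeric(names(med))
  ord <- order(lv)
  lv <- lv[ord]
  med <- med[ord]
  qual <- med >= threshold
  if (!any(qual)) {
    out <- list(value = lv[length(lv)], flag = "above_highest",
                label = paste0("> ", lv[length(lv)]))
  } else {
    first <- min(which(qual))
    if (first == 1L) {
      out <- list(value = lv[1], flag = "below_lowest",
                  label = paste0("< ", lv[1]))
    } else {
      out <- list(value = lv[first], flag = "measured",
                  label = as.character(lv[first]))
    }
  }
  out$threshold <- threshold
  structure(out, class = "lod_estimate")
}

format_lod <- function(lod) {
  if (is.null(lod)) return(NA_character_)
  lod$label
}

#' @export
print.lod_estimate <- function(x, ...) {
  cat("LOD:", x$label, "ng/mL\n")
  invisible(x)
}

#' Determine the linear range by back-calculated accuracy
#'
#' Scans all contiguous runs of calibration levels containing at least
#' `min_points` levels and keeps those in which every level's
#' back-calculated concentration (from a 1/x-weighted fit restricted to
#' that run, applied to the level's mean response) lies within the
#' accuracy band (80-120% of nominal by default). The largest qualifying
#' run defines the lower and upper limits of quantitation; ties prefer
#' the wider concentration span, then the lower starting level.
#'
#' @param concentration nominal concentrations of the calibration points.
#' @param ratio matching responses.
#' @param min_points minimum levels in a qualifying run.
#' @param accuracy_band length-2 numeric, lower and upper accuracy bounds
#'   as fractions of nominal.
#' @param entity optional label.
#' @return a `calibration_fit` refitted on the selected run, with `lloq`,
#'   `uloq` and `levels_used` set to the run.
#' @export
determine_linear_range <- function(concentration, ratio, min_points = 5L,
                                   accuracy_band = c(0.8, 1.2),
                                   entity = NA_character_) {
  stopifnot(length(accuracy_band) == 2, accuracy_band[1] < accuracy_band[2])
  keep <- is.finite(concentration) & is.finite(ratio)
  concentration <- concentration[keep]
  ratio <- ratio[keep]
  lv <- sort(unique(concentration))
  if (length(lv) < min_points) {
    stop_srm("need >= ", min_points, " distinct levels; got ", length(lv),
             class = "srmquant_calibration_error")
  }
  mean_ratio <- tapply(ratio, concentration, mean)
  mean_ratio <- mean_ratio[as.character(lv)]

  # closed-form weighted normal equations for the candidate-run scans
  wls2 <- function(x, y, w) {
    sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
    swxx <- sum(w * x * x); swxy <- sum(w * x * y)
    slope <- (sw * swxy - swx * swy) / (sw * swxx - swx^2)
    c(intercept = (swy - slope * swx) / sw, slope = slope)
  }
  best <- NULL
  for (i in seq_along(lv)) {
    for (j in seq_along(lv)) {
      if (j - i + 1L < min_points) next
      run <- lv[i:j]
      in_run <- concentration %in% run
      cf <- wls2(concentration[in_run], ratio[in_run],
                 1 / concentration[in_run])
      back <- (mean_ratio[as.character(run)] - cf[1]) / cf[2]
      acc <- back / run
      if (all(acc >= accuracy_band[1] & acc <= accuracy_band[2])) {
        cand <- list(i = i, j = j, n = j - i + 1L, span = lv[j] / lv[i])
        if (is.null(best) ||
            cand$n > best$n ||
            (cand$n == best$n && cand$span > best$span) ||
            (cand$n == best$n && cand$span == best$span && cand$i < best$i)) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best)) {
    stop_srm("no contiguous run of >= ", min_points,
             " levels meets the accuracy band",
             if (!is.na(entity)) paste0(" for entity ", entity),
             class = "srmquant_no_linear_range")
  }
  run <- lv[best$i:best$j]
  in_run <- concentration %in% run
  fit_calibration(concentration[in_run], ratio[in_run], entity = entity,
                  min_points = min_points)
}

#' Back-calculate concentrations and assign range flags
#'
#' Inverts the calibration curve, `c = (ratio - intercept) / slope`, and
#' flags each result against the curve's detection and quantitation
#' limits: `below_lod` (no concentration reported), `below_lloq` (value
#' reported, below the validated range), `ok`, or `above_uloq`. Negative
#' back-calculations are flagged `below_lod`, as is any injection whose
#' own signal-to-noise (when the `ratios` table carries a
#' `signal_to_noise` column) falls below the LOD threshold of the curve -
#' the same S/N >= 3 detection rule applied to the standards. Input rows
#' with missing ratios (e.g. a zero or missing ISTD peak) are excluded
#' and returned in the `errors` attribute.
#'
#' @param ratios data frame from [normalize_to_istd()] (columns
#'   `sample_id`, `injection_index`, `entity`, `ratio`), or any data frame
#'   with those columns.
#' @param curve a `calibration_fit` with limits set (its `lod` may be
#'   `NULL`, in which case only the quantitation limits are applied).
#' @return concentration table: `sample_id`, `injection_index`, `entity`,
#'   `concentration` (`NA` for `below_lod`), `flag`.
#' @export
apply_calibration <- function(ratios, curve) {
  stopifnot(inherits(curve, "calibration_fit"))
  if (curve$slope <= 0) {
    stop_srm("invalid calibration: slope must be positive",
             class = "srmquant_calibration_error")
  }
  bad <- is.na(ratios$ratio)
  errors <- ratios[bad, , drop = FALSE]
  ok_rows <- ratios[!bad, , drop = FALSE]
  conc <- (ok_rows$ratio - curve$intercept) / curve$slope

  lod_value <- if (is.null(curve$lod)) {
    0
  } else if (curve$lod$flag == "below_lowest") {
    0
  } else if (curve$lod$flag == "above_highest") {
    Inf
  } else {
    curve$lod$value
  }

  flag <- rep("ok", length(conc))
  flag[conc > curve$uloq] <- "above_uloq"
  flag[conc < curve$lloq] <- "below_lloq"
  flag[conc < lod_value | conc < 0] <- "below_lod"
  if (!is.null(curve$lod) && "signal_to_noise" %in% names(ok_rows)) {
    sn <- ok_rows$signal_to_noise
    flag[!is.na(sn) & sn < curve$lod$threshold] <- "below_lod"
  }
  conc[flag == "below_lod"] <- NA_real_

  out <- data.frame(
    sample_id = ok_rows$sample_id, injection_index = ok_rows$injection_index,
    entity = if ("entity" %in% names(ok_rows)) ok_rows$entity else curve$entity,
    concentration = conc, flag = flag, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "errors") <- errors
  out
}

#' Calibrate every entity of a panel from a standard sequence
#'
#' Runs the full per-entity calibration workflow on a calibration
#' standard sequence: ISTD normalization, LOD determination from the
#' analyte channel's signal-to-noise, linear-range selection by
#' back-calculated accuracy, and the final 1/x-weighted fit on the
#' selected range. Start- and end-of-sequence series are pooled into one
#' fit by default; `combine_series = "average"` instead averages the
#' coefficients of per-series fits over the jointly selected range.
#'
#' @param peaks calibration peak table (analyte + istd channels).
#' @param samples sample metadata with `sample_id`,
#'   `nominal_concentration` and `series`.
#' @param panel an `analyte_panel`.
#' @param min_points minimum levels per curve; may be a single number or a
#'   named vector keyed by entity for per-entity overrides (short-curve
#'   analytes).
#' @param accuracy_band back-calculated accuracy bounds.
#' @param sn_threshold LOD signal-to-noise threshold.
#' @param combine_series `"pool"` or `"average"`.
#' @return object of class `calibration_set`: named list of
#'   `calibration_fit` objects, with attribute `failures` (named character
#'   vector of error messages for entities with no valid curve).
#' @export
calibrate_panel <- function(peaks, samples, panel, min_points = 5L,
                            accuracy_band = c(0.8, 1.2), sn_threshold = 3,
                            combine_series = c("pool", "average")) {
  combine_series <- match.arg(combine_series)
  ratios <- normalize_to_istd(peaks, panel)
  ratios$nominal <- samples$nominal_concentration[
    match(ratios$sample_id, samples$sample_id)]
  ratios$series <- samples$series[match(ratios$sample_id, samples$sample_id)]
  ents <- quantification_entities(panel)$entity

  curves <- list()
  failures <- character()
  for (e in ents) {
    re <- ratios[ratios$entity == e & !is.na(ratios$nominal), , drop = FALSE]
    mp <- if (length(min_points) > 1L && e %in% names(min_points)) {
      min_points[[e]]
    } else {
      min_points[[1]]
    }
    res <- tryCatch({
      lod <- determine_lod(re$nominal, re$signal_to_noise,
                           threshold = sn_threshold)
      fit <- determine_linear_range(re$nominal, re$ratio, min_points = mp,
                                    accuracy_band = accuracy_band, entity = e)
      if (combine_series == "average" && length(unique(re$series)) > 1L) {
        run <- fit$levels_used
        cfs <- sapply(unique(re$series), function(s) {
          rs <- re[re$series == s & re$nominal %in% run, , drop = FALSE]
          stats::coef(stats::lm(ratio ~ nominal, data = rs,
                                weights = 1 / rs$nominal))
        })
        fit$intercept <- mean(cfs[1, ])
        fit$slope <- mean(cfs[2, ])
      }
      fit$lod <- lod
      fit
    }, srmquant_no_linear_range = function(c) conditionMessage(c),
       srmquant_calibration_error = function(c) conditionMessage(c))
    if (inherits(res, "calibration_fit")) {
      curves[[e]] <- res
    } else {
      failures[[e]] <- res
    }
  }
  structure(curves, failures = failures, class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat("Calibration set:", length(x), "entities fitted")
  f <- attr(x, "failures")
  if (length(f)) cat(",", length(f), "failed:", paste(names(f), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Method-validation style calibration report
#'
#' Summarizes a [calibrate_panel()] result as one row per entity:
#' weighted R-squared, linear range (LLOQ-ULOQ), LOD (with below-lowest /
#' above-highest rendering), and the number of levels used.
#'
#' @param curves a `calibration_set`.
#' @return data frame with columns `entity`, `r_squared`, `lloq`, `uloq`,
#'   `lod`, `n_levels`, `normalized`.
#' @export
calibration_report <- function(curves) {
  stopifnot(inherits(curves, "calibration_set"))
  do.call(rbind, lapply(names(curves), function(e) {
    cv <- curves[[e]]
    data.frame(entity = e, r_squared = cv$r_squared,
               lloq = cv$lloq, uloq = cv$uloq,
               lod = format_lod(cv$lod), n_levels = length(cv$levels_used),
               stringsAsFactors = FALSE)
  }))
}

#' Quantify study samples against a calibration set
#'
#' Applies [normalize_to_istd()] and [apply_calibration()] entity-wise,
#' concatenating the per-entity concentration tables.
#'
#' @param peaks study-sample peak table.
#' @param panel an `analyte_panel`.
#' @param curves a `calibration_set` from [calibrate_panel()].
#' @return concentration table (`sample_id`, `injection_index`, `entity`,
#'   `concentration`, `flag`), with per-row error records in the
#'   `errors` attribute.
#' @export
quantify_samples <- function(peaks, panel, curves) {
  ratios <- normalize_to_istd(peaks, panel)
  out <- list()
  errs <- list()
  for (e in intersect(unique(ratios$entity), names(curves))) {
    ct <- apply_calibration(ratios[ratios$entity == e, , drop = FALSE],
                            curves[[e]])
    out[[e]] <- ct
    errs[[e]] <- attr(ct, "errors")
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  attr(res, "errors") <- do.call(rbind, c(errs, make.row.names = FALSE))
  res
}
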