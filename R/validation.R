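#' Relative standard deviation (%RSD)
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation, the
#' repeatability metric of bioanalytical method validation.
#'
#' @param values numeric vector, at least two finite values with non-zero
#'   mean.
#' @return percent RSD.
#' @export
rsd <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    stop_srm("%RSD needs at least two finite values",
             class = "srmquant_argument_error")
  }
  m <- mean(values)
  if (m == 0) {
    stop_srm("%RSD undefined for zero mean", class = "srmquant_argument_error")
  }
  100 * stats::sd(values) / m
}

#' Intra- and inter-day repeatability report
#'
#' Computes per (entity, QC level) the %RSD of retention time and of the
#' quantitation response over the intra-day block (consecutive runs on
#' one day) and the inter-day block (all runs across days, pooled). The
#' response is the ISTD-normalized area ratio where the entity has an
#' ISTD, and the raw analyte area otherwise (`normalized = FALSE` in the
#' report). Retention-time %RSD always uses the analyte channel.
#'
#' @param peaks QC peak table (analyte + istd channels).
#' @param samples QC sample metadata with `sample_id`, `qc_level`,
#'   `block` (`intra`/`inter`), `day`, `run` (as produced by
#'   [simulate_qc_replicates()]).
#' @param panel an `analyte_panel`.
#' @return data frame of class `repeatability_report` with columns
#'   `entity`, `qc_level`, `rsd_rt_intra`, `rsd_area_intra`,
#'   `rsd_rt_inter`, `rsd_area_inter`, `n_intra`, `n_inter`,
#'   `normalized`. Entities missing a QC level are omitted with a
#'   warning, never silently.
#' @export
repeatability_report <- function(peaks, samples, panel) {
  stopifnot(inherits(panel, "analyte_panel"))
  ratios <- normalize_to_istd(peaks, panel)
  idx <- match(ratios$sample_id, samples$sample_id)
  ratios$qc_level <- samples$qc_level[idx]
  ratios$block <- samples$block[idx]
  ents <- quantification_entities(panel)
  rows <- list()
  for (e in ents$entity) {
    for (lv in sort(unique(samples$qc_level))) {
      re <- ratios[ratios$entity == e & !is.na(ratios$qc_level) &
                     ratios$qc_level == lv, , drop = FALSE]
      intra <- re[re$block == "intra", , drop = FALSE]
      inter <- re[re$block == "inter", , drop = FALSE]
      if (nrow(intra) < 2L || nrow(inter) < 2L) {
        warning("entity ", e, " lacks QC data at level ", lv,
                "; omitted from repeatability report", call. = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        entity = e, qc_level = lv,
        rsd_rt_intra = rsd(intra$retention_time_min),
        rsd_area_intra = rsd(intra$ratio),
        rsd_rt_inter = rsd(inter$retention_time_min),
        rsd_area_inter = rsd(inter$ratio),
        n_intra = nrow(intra), n_inter = nrow(inter),
        normalized = ents$normalized[ents$entity == e],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("repeatability_report", "data.frame")
  out
}

#' @export
print.repeatability_report <- function(x, digits = 3, ...) {
  cat("Repeatability report:", length(unique(x$entity)), "entities x",
      length(unique(x$qc_level)), "QC levels\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
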