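# Fixture builders: panels are constructed in code and loaded through the
# CSV reader so the documented schema is exercised.

panel_from_tables <- function(analytes, istds = NULL) {
  apath <- withr::local_tempfile(fileext = ".csv",
                                 .local_envir = parent.frame())
  write.csv(analytes, apath, row.names = FALSE)
  ipath <- NULL
  if (!is.null(istds)) {
    ipath <- withr::local_tempfile(fileext = ".csv",
                                   .local_envir = parent.frame())
    write.csv(istds, ipath, row.names = FALSE)
  }
  load_panel(apath, ipath)
}

analyte_row <- function(abbreviation, role = "quantifier",
                        istd = "", grp = "",
                        precursor = 300, product = 150,
                        polarity = "negative") {
  data.frame(abbreviation = abbreviation, name = abbreviation,
             group = "other", precursor_mz = precursor,
             product_mz = product, polarity = polarity, role = role,
             istd_abbreviation = istd, co_quantified_group = grp,
             stringsAsFactors = FALSE)
}

istd_row <- function(abbreviation, conc = 1000) {
  data.frame(abbreviation = abbreviation,
             mix_concentration_ng_per_ml = conc, stringsAsFactors = FALSE)
}

# 4-analyte panel: A stand-alone with ISTD, B+C merged sharing one ISTD,
# D quantified on raw area.
small_panel <- function() {
  analytes <- rbind(
    analyte_row("A", istd = "ISA"),
    analyte_row("B", istd = "ISB", grp = "B and C"),
    analyte_row("C", istd = "ISB", grp = "B and C"),
    analyte_row("D")
  )
  panel_from_tables(analytes, rbind(istd_row("ISA", 500), istd_row("ISB", 2000)))
}

# Concentration table with a controlled per-sample detection pattern.
conc_with_detection <- function(entity, n_detected, n_total) {
  data.frame(
    sample_id = sprintf("P%03d", seq_len(n_total)),
    injection_index = 1L, entity = entity,
    concentration = c(rep(100, n_detected), rep(NA_real_, n_total - n_detected)),
    flag = c(rep("ok", n_detected), rep("below_lod", n_total - n_detected)),
    stringsAsFactors = FALSE
  )
}

noise_free_models <- function(panel, response_factor = 50) {
  default_response_models(panel, response_factor = response_factor,
                          proportional_cv = 0, baseline_noise_sd = 0,
                          istd_cv = 0)
}
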