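#' Default fixed-effect terms of the metabolite models
#'
#' Albuminuria group, age, BMI, eGFR (kidney function), HbA1c (glycemic
#' control), sex, systolic blood pressure, total cholesterol and total
#' triglycerides. Smoking, statin and antihypertensive medication can be
#' added as optional extra terms.
#'
#' @return character vector of clinical column names.
#' @export
association_terms <- function() {
  c("group", "age", "bmi", "egfr", "hba1c", "sex", "sbp",
    "total_cholesterol", "total_triglycerides")
}

#' Filter metabolites by detection rate
#'
#' A participant sample counts as detected for an entity when any of its
#' replicate injections has a flag other than `below_lod`. An entity is
#' retained when its detected fraction of samples is strictly greater
#' than the threshold (detection in more than 70% of samples by
#' default).
#'
#' @param conc concentration table (`sample_id`, `injection_index`,
#'   `entity`, `concentration`, `flag`).
#' @param threshold detection fraction that must be exceeded.
#' @return character vector of retained entities, with the per-entity
#'   detected fractions in attribute `detection_fraction`.
#' @export
detection_filter <- function(conc, threshold = 0.70) {
  stopifnot(threshold >= 0, threshold <= 1)
  frac <- vapply(split(conc, conc$entity), function(ce) {
    det <- tapply(ce$flag != "below_lod", ce$sample_id, any)
    mean(det)
  }, numeric(1))
  retained <- names(frac)[frac > threshold]
  attr(retained, "detection_fraction") <- frac
  retained
}

#' Fit the mixed-effects model for one metabolite
#'
#' Linear mixed model of (log10) concentration on the clinical fixed
#' effects with a random intercept per participant capturing the
#' correlation between technical replicate injections, fitted by REML;
#' per-coefficient two-sided tests use Satterthwaite degrees of freedom.
#' Rows flagged `below_lod` are excluded; `below_lloq` values enter with
#' their reported concentrations.
#'
#' @param conc concentration table for one entity; `sample_id` must match
#'   `participant_id` in `clinical`.
#' @param clinical clinical covariate table.
#' @param terms fixed-effect columns; defaults to [association_terms()].
#' @param log10_response model log10 concentration (default) or the raw
#'   scale.
#' @return data frame with one row per fixed-effect term: `term`,
#'   `estimate`, `std_error`, `df`, `p_value`; attribute `converged`.
#' @export
fit_metabolite_model <- function(conc, clinical,
                                 terms = association_terms(),
                                 log10_response = TRUE) {
  check_cols <- setdiff(c("participant_id", terms), names(clinical))
  if (length(check_cols)) {
    stop_srm("clinical table lacks columns: ",
             paste(check_cols, collapse = ", "),
             class = "srmquant_schema_error")
  }
  d <- conc[conc$flag != "below_lod" & !is.na(conc$concentration), ,
            drop = FALSE]
  if (!nrow(d)) {
    stop_srm("no quantifiable rows for model fitting",
             class = "srmquant_model_error")
  }
  d <- merge(d, clinical, by.x = "sample_id", by.y = "participant_id")
  d$participant_id <- d$sample_id
  if (max(table(d$participant_id)) < 2L) {
    stop_srm("random intercept needs >= 2 replicates for some participant",
             class = "srmquant_model_error")
  }
  d$.response <- if (log10_response) log10(d$concentration) else d$concentration

  fixed <- stats::reformulate(terms, response = ".response")
  mm <- stats::model.matrix(fixed, data = d)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1L):ncol(mm)]]
    stop_srm("rank-deficient fixed-effect design; aliased terms: ",
             paste(aliased, collapse = ", "),
             class = "srmquant_model_error")
  }

  form <- stats::as.formula(
    paste(".response ~", paste(terms, collapse = " + "), "+ (1 | participant_id)")
  )
  converged <- TRUE
  fit <- withCallingHandlers(
    lmerTest::lmer(form, data = d, REML = TRUE,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular =
                                                 lme4::.makeCC(action = "ignore",
                                                               tol = 1e-4))),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    }
  )
  ct <- stats::coef(summary(fit))
  rows <- match(terms, rownames(ct))
  out <- data.frame(
    term = terms,
    estimate = ct[rows, "Estimate"],
    std_error = ct[rows, "Std. Error"],
    df = ct[rows, "df"],
    p_value = ct[rows, "Pr(>|t|)"],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "converged") <- converged
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: sort ascending, take
#' `min_{j >= i} m p_(j) / j` capped at 1, and map back to input order.
#' Applied across metabolites within one fixed-effect term.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
adjust_bh <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop_srm("p-values must be finite and within [0, 1]",
             class = "srmquant_argument_error")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Metabolite-phenotype association analysis
#'
#' The cohort analysis stage: applies the detection filter, fits the
#' per-metabolite mixed-effects model ([fit_metabolite_model()]) for each
#' retained entity, and corrects each fixed-effect term's p-values across
#' metabolites with the Benjamini-Hochberg method. Metabolites whose
#' model does not converge are flagged and excluded from the adjustment
#' universe.
#'
#' @inheritParams fit_metabolite_model
#' @param conc concentration table for all entities.
#' @param alpha significance level on adjusted p-values.
#' @param detection_threshold passed to [detection_filter()].
#' @return data frame of class `metabolite_associations`: one row per
#'   (entity, term) with `estimate`, `std_error`, `p_value`,
#'   `adj_p_value`, `significant`, `converged`. Attributes: `alpha`,
#'   `m` (number of metabolites in the adjustment universe),
#'   `retained`, `detection_fraction`.
#' @export
associate_metabolites <- function(conc, clinical,
                                  terms = association_terms(),
                                  alpha = 0.05,
                                  detection_threshold = 0.70,
                                  log10_response = TRUE) {
  retained <- detection_filter(conc, threshold = detection_threshold)
  if (!length(retained)) {
    stop_srm("no entity passes the detection filter",
             class = "srmquant_model_error")
  }
  fits <- list()
  for (e in retained) {
    res <- fit_metabolite_model(conc[conc$entity == e, , drop = FALSE],
                                clinical, terms = terms,
                                log10_response = log10_response)
    res$entity <- e
    res$converged <- attr(res, "converged")
    fits[[e]] <- res
  }
  out <- do.call(rbind, c(fits, make.row.names = FALSE))
  out$adj_p_value <- NA_real_
  conv_ent <- unique(out$entity[out$converged])
  for (tm in terms) {
    sel <- out$term == tm & out$entity %in% conv_ent
    out$adj_p_value[sel] <- adjust_bh(out$p_value[sel])
  }
  out$significant <- !is.na(out$adj_p_value) & out$adj_p_value < alpha
  out <- out[, c("entity", "term", "estimate", "std_error", "df",
                 "p_value", "adj_p_value", "significant", "converged")]
  structure(out,
            alpha = alpha, m = length(conv_ent), retained = retained,
            detection_fraction = attr(retained, "detection_fraction"),
            class = c("metabolite_associations", "data.frame"))
}

#' @export
print.metabolite_associations <- function(x, ...) {
  cat("Metabolite associations:", attr(x, "m"),
      "metabolites in the FDR universe,",
      sum(x$significant), "significant (entity, term) pairs at alpha =",
      attr(x, "alpha"), "\n")
  sig <- x[x$significant, c("entity", "term", "estimate", "adj_p_value")]
  if (nrow(sig)) print.data.frame(sig, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
summary.metabolite_associations <- function(object, ...) {
  tab <- table(term = object$term[object$significant])
  list(alpha = attr(object, "alpha"), m = attr(object, "m"),
       significant_by_term = tab,
       n_not_converged = length(unique(object$entity[!object$converged])))
}

#' Bipartite association network edges
#'
#' One edge per significant (clinical term, metabolite) association.
#' Edge sign follows the coefficient sign; strength is the
#' log10-transformed absolute coefficient, rescaled to a positive line
#' width; edges for the albuminuria-group and eGFR terms - the key
#' kidney-disease variables - are flagged highlighted.
#'
#' @param results a `metabolite_associations` object.
#' @param alpha significance threshold on adjusted p-values.
#' @param highlight_terms terms whose edges are highlighted.
#' @return data frame of class `association_network` with columns `term`,
#'   `metabolite`, `coefficient`, `sign`, `strength`, `width`, `adj_p`,
#'   `highlighted`.
#' @export
build_network <- function(results, alpha = 0.05,
                          highlight_terms = c("group", "egfr")) {
  sig <- results[!is.na(results$adj_p_value) & results$adj_p_value < alpha, ,
                 drop = FALSE]
  if (!nrow(sig)) {
    out <- data.frame(term = character(), metabolite = character(),
                      coefficient = numeric(), sign = character(),
                      strength = numeric(), width = numeric(),
                      adj_p = numeric(), highlighted = logical(),
                      stringsAsFactors = FALSE)
    class(out) <- c("association_network", "data.frame")
    return(out)
  }
  strength <- log10(abs(sig$estimate))
  width <- if (nrow(sig) == 1L || diff(range(strength)) == 0) {
    rep(1.75, nrow(sig))
  } else {
    0.5 + 2.5 * (strength - min(strength)) / diff(range(strength))
  }
  out <- data.frame(
    term = sig$term, metabolite = sig$entity,
    coefficient = sig$estimate,
    sign = ifelse(sig$estimate >= 0, "positive", "negative"),
    strength = strength, width = width, adj_p = sig$adj_p_value,
    highlighted = sig$term %in% highlight_terms,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("association_network", "data.frame")
  out
}

#' @export
plot.association_network <- function(x, ...) {
  if (!nrow(x)) {
    graphics::plot.new()
    graphics::title("No significant associations")
    return(invisible(x))
  }
  terms <- sort(unique(x$term))
  mets <- sort(unique(x$metabolite))
  yt <- stats::setNames(seq_along(terms) / (length(terms) + 1), terms)
  ym <- stats::setNames(seq_along(mets) / (length(mets) + 1), mets)
  graphics::plot(NA, xlim = c(-0.4, 1.4), ylim = c(0, 1), axes = FALSE,
                 xlab = "", ylab = "", main = "Clinical-metabolite associations")
  base_col <- ifelse(x$sign == "positive", "firebrick", "steelblue")
  # highlighted edges opaque, others translucent
  edge_col <- mapply(function(col, hi) {
    rgb <- grDevices::col2rgb(col)[, 1] / 255
    grDevices::rgb(rgb[1], rgb[2], rgb[3], alpha = if (hi) 1 else 0.35)
  }, base_col, x$highlighted)
  for (i in seq_len(nrow(x))) {
    graphics::segments(0, yt[x$term[i]], 1, ym[x$metabolite[i]],
                       lwd = x$width[i], col = edge_col[i])
  }
  graphics::text(-0.02, yt, labels = terms, adj = 1, cex = 0.8)
  graphics::text(1.02, ym, labels = mets, adj = 0, cex = 0.8)
  invisible(x)
}
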