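#' Load and validate an SRM analyte panel
#'
#' Reads a transition-level analyte table and an internal-standard (ISTD)
#' table, validates them, and resolves co-quantified analytes (isobaric or
#' chromatographically unresolved pairs reported as a single concentration)
#' into merged quantification entities.
#'
#' The analyte CSV has one row per ion transition with columns
#' `abbreviation`, `name`, `group`, `precursor_mz`, `product_mz`,
#' `polarity` (`positive`/`negative`), `role` (`quantifier`/`qualifier`),
#' `istd_abbreviation` (empty for analytes quantified without ISTD
#' normalization) and `co_quantified_group` (empty for stand-alone
#' analytes). Optional acquisition-voltage columns are carried through as
#' opaque metadata and play no computational role. The ISTD CSV has columns
#' `abbreviation`, optional `name`, and `mix_concentration_ng_per_ml`.
#'
#' The built-in fixture `"diabetes_t1d_34"` encodes a 34-analyte /
#' 33-ISTD plasma panel of amino acids and related metabolites, bile
#' acids, small organic acids and other polar metabolites, with four
#' merged pairs (Leu+Ile, ADMA+SDMA, GCDCA+GDCA, TDCA+TCDCA) and three
#' analytes (Crea, GBB, b-OHB) quantified on raw peak area because their
#' ISTD signal is not repeatable.
#'
#' @param path path to the analyte CSV, or the name of a built-in fixture
#'   (currently `"diabetes_t1d_34"`).
#' @param istd_path path to the ISTD CSV. Defaults to the fixture's ISTD
#'   table when `path` names a built-in fixture; may be `NULL` for panels
#'   in which no analyte references an ISTD.
#' @return An object of class `analyte_panel`: a list with elements
#'   `analytes` (transition-level data frame), `istds`, and `entities`
#'   (one row per quantification entity, see [quantification_entities()]).
#' @seealso [quantification_entities()], [write_panel()]
#' @examples
#' panel <- load_panel()
#' panel
#' head(quantification_entities(panel))
#' @export
load_panel <- function(path = "diabetes_t1d_34", istd_path = NULL) {
  builtin <- !file.exists(path) && grepl("^[A-Za-z0-9_]+$", path)
  if (builtin) {
    apath <- system.file("extdata", paste0(path, "_analytes.csv"),
                         package = "srmquant")
    if (!nzchar(apath)) {
      stop_srm("unknown panel fixture or missing file: ", path,
               class = "srmquant_schema_error")
    }
    if (is.null(istd_path)) {
      istd_path <- system.file("extdata", paste0(path, "_istds.csv"),
                               package = "srmquant")
    }
    path <- apath
  }
  analytes <- utils::read.csv(path, stringsAsFactors = FALSE)
  istds <- if (!is.null(istd_path) && nzchar(istd_path)) {
    utils::read.csv(istd_path, stringsAsFactors = FALSE)
  } else {
    data.frame(abbreviation = character(),
               mix_concentration_ng_per_ml = numeric())
  }
  build_panel(analytes, istds)
}

# Validate raw tables and assemble the classed panel object.
build_panel <- function(analytes, istds) {
  req <- c("abbreviation", "name", "group", "precursor_mz", "product_mz",
           "polarity", "role", "istd_abbreviation", "co_quantified_group")
  missing_cols <- setdiff(req, names(analytes))
  if (length(missing_cols)) {
    stop_srm("analyte table lacks columns: ",
             paste(missing_cols, collapse = ", "),
             class = "srmquant_schema_error")
  }
  if (nrow(analytes) == 0) {
    stop_srm("panel is empty", class = "srmquant_schema_error")
  }
  analytes$istd_abbreviation[is.na(analytes$istd_abbreviation)] <- ""
  analytes$co_quantified_group[is.na(analytes$co_quantified_group)] <- ""

  if (!all(analytes$polarity %in% c("positive", "negative"))) {
    stop_srm("polarity must be 'positive' or 'negative'",
             class = "srmquant_schema_error")
  }
  if (!all(analytes$role %in% c("quantifier", "qualifier"))) {
    stop_srm("role must be 'quantifier' or 'qualifier'",
             class = "srmquant_schema_error")
  }
  if (any(!is.finite(analytes$precursor_mz)) || any(analytes$precursor_mz <= 0) ||
      any(!is.finite(analytes$product_mz)) || any(analytes$product_mz <= 0)) {
    stop_srm("transition m/z values must be positive and finite",
             class = "srmquant_schema_error")
  }
  # + 1.0 Da tolerance admits pseudo-fragmentation entries (precursor passed
  # through the collision cell intact, e.g. CDCA 391.3 -> 391.3)
  bad_mz <- analytes$product_mz > analytes$precursor_mz + 1.0
  if (any(bad_mz)) {
    stop_srm("product m/z exceeds precursor m/z for: ",
             paste(unique(analytes$abbreviation[bad_mz]), collapse = ", "),
             class = "srmquant_schema_error")
  }

  # duplicate-transition check: (abbreviation, precursor, product) unique
  key <- paste(analytes$abbreviation, analytes$precursor_mz,
               analytes$product_mz, analytes$role)
  if (anyDuplicated(key)) {
    stop_srm("duplicate transition rows for: ",
             paste(unique(analytes$abbreviation[duplicated(key)]), collapse = ", "),
             class = "srmquant_schema_error")
  }

  # per-analyte consistency and exactly one quantifier
  for (ab in unique(analytes$abbreviation)) {
    rows <- analytes[analytes$abbreviation == ab, , drop = FALSE]
    for (col in c("name", "group", "istd_abbreviation", "co_quantified_group")) {
      if (length(unique(rows[[col]])) != 1L) {
        stop_srm("inconsistent '", col, "' across transitions of analyte ", ab,
                 class = "srmquant_schema_error")
      }
    }
    nq <- sum(rows$role == "quantifier")
    if (nq != 1L) {
      stop_srm("analyte ", ab, " has ", nq,
               " quantifier transitions (exactly one required)",
               class = "srmquant_schema_error")
    }
  }

  if (nrow(istds)) {
    if (!all(c("abbreviation", "mix_concentration_ng_per_ml") %in% names(istds))) {
      stop_srm("ISTD table lacks required columns",
               class = "srmquant_schema_error")
    }
    if (anyDuplicated(istds$abbreviation)) {
      stop_srm("duplicate ISTD abbreviations",
               class = "srmquant_schema_error")
    }
    if (any(!is.finite(istds$mix_concentration_ng_per_ml)) ||
        any(istds$mix_concentration_ng_per_ml <= 0)) {
      stop_srm("ISTD mix concentrations must be positive",
               class = "srmquant_schema_error")
    }
  }

  used_istd <- setdiff(unique(analytes$istd_abbreviation), "")
  unresolved <- setdiff(used_istd, istds$abbreviation)
  if (length(unresolved)) {
    bad <- unique(analytes$abbreviation[analytes$istd_abbreviation %in% unresolved])
    stop_srm("ISTD reference(s) not in ISTD table for analyte(s): ",
             paste(bad, collapse = ", "),
             class = "srmquant_schema_error")
  }

  # one ISTD per co-quantified group
  adef <- unique(analytes[, c("abbreviation", "istd_abbreviation",
                              "co_quantified_group")])
  for (grp in setdiff(unique(adef$co_quantified_group), "")) {
    members <- adef[adef$co_quantified_group == grp, , drop = FALSE]
    if (length(unique(members$istd_abbreviation)) != 1L) {
      stop_srm("co-quantified group '", grp,
               "' members do not share a single ISTD",
               class = "srmquant_schema_error")
    }
  }

  panel <- structure(
    list(analytes = analytes, istds = istds, entities = NULL),
    class = "analyte_panel"
  )
  panel$entities <- resolve_entities(adef)
  panel
}

# One quantification entity per stand-alone analyte plus one per merged
# group; deterministic (sorted by entity id), independent of file row order.
resolve_entities <- function(adef) {
  singles <- adef[adef$co_quantified_group == "", , drop = FALSE]
  groups <- setdiff(unique(adef$co_quantified_group), "")
  ent <- data.frame(
    entity = singles$abbreviation,
    members = singles$abbreviation,
    n_members = 1L,
    istd_abbreviation = singles$istd_abbreviation,
    stringsAsFactors = FALSE
  )
  if (length(groups)) {
    grp_rows <- do.call(rbind, lapply(groups, function(g) {
      m <- adef[adef$co_quantified_group == g, , drop = FALSE]
      data.frame(
        entity = g,
        members = paste(sort(m$abbreviation), collapse = ";"),
        n_members = nrow(m),
        istd_abbreviation = m$istd_abbreviation[1],
        stringsAsFactors = FALSE
      )
    }))
    ent <- rbind(ent, grp_rows)
  }
  ent$normalized <- nzchar(ent$istd_abbreviation)
  ent <- ent[order(ent$entity), , drop = FALSE]
  rownames(ent) <- NULL
  ent
}

#' Quantification entities of a panel
#'
#' Returns one descriptor per quantification entity: stand-alone analytes
#' plus merged co-quantified groups, each with the ISTD (if any) used for
#' normalization downstream.
#'
#' @param panel an `analyte_panel` from [load_panel()].
#' @return data frame with columns `entity`, `members` (semicolon-joined
#'   analyte abbreviations), `n_members`, `istd_abbreviation` (empty string
#'   when the entity is quantified on raw area) and `normalized`.
#' @export
quantification_entities <- function(panel) {
  stopifnot(inherits(panel, "analyte_panel"))
  panel$entities
}

#' Write a panel back to CSV
#'
#' Serializes the analyte and ISTD tables in the same schema accepted by
#' [load_panel()], so that a written panel re-parses to an equal object.
#'
#' @param panel an `analyte_panel`.
#' @param path output path for the analyte CSV.
#' @param istd_path output path for the ISTD CSV.
#' @return invisibly, `path`.
#' @export
write_panel <- function(panel, path, istd_path) {
  stopifnot(inherits(panel, "analyte_panel"))
  utils::write.csv(panel$analytes, path, row.names = FALSE)
  utils::write.csv(panel$istds, istd_path, row.names = FALSE)
  invisible(path)
}

#' @export
print.analyte_panel <- function(x, ...) {
  n_an <- length(unique(x$analytes$abbreviation))
  cat("SRM analyte panel:", n_an, "analytes,",
      nrow(x$istds), "internal standards,",
      nrow(x$entities), "quantification entities\n")
  merged <- x$entities[x$entities$n_members > 1, , drop = FALSE]
  if (nrow(merged)) {
    cat("Co-quantified:", paste(merged$entity, collapse = "; "), "\n")
  }
  bare <- x$entities$entity[!x$entities$normalized]
  if (length(bare)) {
    cat("Quantified without ISTD normalization:",
        paste(bare, collapse = ", "), "\n")
  }
  invisible(x)
}
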