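#' Construct a CytokinePanel from matrices and tables
#'
#' Lower-level constructor used by [readPanel()] and [simulateCohort()].
#' The concentration matrix is oriented analytes x subjects (the on-disk
#' CSV convention is the transpose: subjects as rows).  Detection status
#' is derived by comparing each raw value to the analyte's detection
#' window unless a `status` matrix is supplied.
#'
#' @param conc numeric matrix, analytes x subjects, pg/mL; `NA` for cells
#'   with no quantifiable value.
#' @param lods data.frame with columns `analyte`, `lower_lod`,
#'   `upper_lod` and optionally `curve_min` (lowest standard-curve
#'   point), one row per panel analyte.
#' @param clinical data.frame of per-subject covariates with an `id`
#'   column matching `colnames(conc)`; see [readPanel()] for the
#'   controlled vocabularies.
#' @param status optional character matrix over
#'   `below`/`within`/`above`/`missing`; derived from `conc` when absent.
#' @return a [CytokinePanel].
#' @export
CytokinePanel <- function(conc, lods, clinical = NULL, status = NULL) {
  if (is.null(rownames(conc)))
    stop("concentration matrix must carry analyte rownames")
  if (is.null(colnames(conc)))
    stop("concentration matrix must carry subject ids as colnames")
  missing_lod <- setdiff(rownames(conc), lods$analyte)
  if (length(missing_lod))
    stop("LOD table is missing analyte(s): ",
         paste(missing_lod, collapse = ", "))
  lods <- lods[match(rownames(conc), lods$analyte), , drop = FALSE]
  if (is.null(lods$curve_min)) lods$curve_min <- NA_real_
  if (is.null(status)) {
    lo <- matrix(lods$lower_lod, nrow(conc), ncol(conc))
    hi <- matrix(lods$upper_lod, nrow(conc), ncol(conc))
    status <- matrix("missing", nrow(conc), ncol(conc))
    status[!is.na(conc) & conc < lo] <- "below"
    status[!is.na(conc) & conc >= lo & conc <= hi] <- "within"
    status[!is.na(conc) & conc > hi] <- "above"
  }
  dimnames(status) <- dimnames(conc)
  cd <- S4Vectors::DataFrame(row.names = colnames(conc))
  if (!is.null(clinical)) {
    if (anyDuplicated(clinical$id))
      stop("duplicate subject id(s) in clinical table: ",
           paste(unique(clinical$id[duplicated(clinical$id)]), collapse = ", "))
    unmatched <- setdiff(colnames(conc), clinical$id)
    if (length(unmatched))
      stop("clinical table is missing subject(s): ",
           paste(utils::head(unmatched, 5), collapse = ", "))
    clinical <- clinical[match(colnames(conc), clinical$id), , drop = FALSE]
    cd <- S4Vectors::DataFrame(clinical[setdiff(names(clinical), "id")],
                               row.names = colnames(conc))
  }
  rd <- S4Vectors::DataFrame(lower_lod = lods$lower_lod,
                             upper_lod = lods$upper_lod,
                             curve_min = lods$curve_min,
                             row.names = rownames(conc))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(conc = conc, status = status),
    rowData = rd, colData = cd)
  methods::new("CytokinePanel", se)
}

#' Read a panel, its LOD sidecar and the clinical table
#'
#' Reads the three on-disk tables of a trauma panel study and assembles a
#' validated [CytokinePanel].  The panel file has subjects as rows and
#' analytes as columns (header row of analyte names, first column the
#' subject id, units pg/mL).  Below-LOD cells may arrive either as
#' explicit small values or as the sentinel string `"<LOD"` (vendor
#' exports vary); both map to status `below`.  Empty cells are `missing`
#' and are excluded from every analysis, never imputed.
#'
#' The LOD sidecar is a CSV with columns
#' `analyte,lower_lod,upper_lod,curve_min`.  The clinical CSV carries one
#' row per subject with columns `id`, `group` (`trauma`/`control`),
#' `age`, `sex` (`female`/`male`/`unknown`), `trauma_level` (1-4, empty
#' for controls), `outcome` (`discharged_home`, `other_discharge`, `icu`,
#' `or_`, `deceased`, `unknown`), `mechanism`
#' (`fall`/`gsw`/`mvc`/`stab`/`other`/`unknown`), `locations` and
#' `wound_type` (`|`-separated subsets of the location/wound
#' vocabularies) and `covid` (`positive`/`negative`/`untested`).
#'
#' @param panel_path,lod_path,clinical_path file paths (CSV, or TSV for
#'   the panel if the name ends in `.tsv`).
#' @return a [CytokinePanel] with clinical covariates in `colData`.
#' @export
readPanel <- function(panel_path, lod_path, clinical_path = NULL) {
  for (p in c(panel_path, lod_path, clinical_path))
    if (!is.null(p) && !file.exists(p)) stop("file not found: ", p)
  sep <- if (grepl("\\.tsv$", panel_path)) "\t" else ","
  raw <- utils::read.table(panel_path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop("duplicate subject id(s) in panel: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  sentinel <- !is.na(vals) & grepl("^\\s*<\\s*LOD\\s*$", vals, ignore.case = TRUE)
  blank <- is.na(vals) | grepl("^\\s*$", vals)
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- !blank & !sentinel & is.na(num)
  if (any(bad))
    stop("non-numeric panel value(s), e.g. '", vals[which(bad)[1]], "'")
  conc <- t(num)                      # analytes x subjects
  rownames(conc) <- colnames(vals)
  colnames(conc) <- ids
  lods <- utils::read.csv(lod_path, stringsAsFactors = FALSE)
  if (!all(c("analyte", "lower_lod", "upper_lod") %in% names(lods)))
    stop("LOD sidecar must have columns analyte, lower_lod, upper_lod")
  clinical <- NULL
  if (!is.null(clinical_path)) {
    clinical <- utils::read.csv(clinical_path, stringsAsFactors = FALSE,
                                colClasses = c(id = "character"))
    if ("trauma_level" %in% names(clinical))
      clinical$trauma_level <- suppressWarnings(as.integer(clinical$trauma_level))
  }
  panel <- CytokinePanel(conc, lods, clinical)
  ## sentinel "<LOD" cells: no numeric value, but censored, not missing
  if (any(sentinel)) {
    st <- panelStatus(panel)
    st[t(sentinel)] <- "below"
    SummarizedExperiment::assay(panel, "status") <- st
    methods::validObject(panel)
  }
  panel
}

#' Write a panel back to the on-disk formats
#'
#' Inverse of [readPanel()]: writes the panel CSV (subjects as rows;
#' below-LOD cells without a stored value as `"<LOD"`, missing cells
#' empty), the LOD sidecar and the clinical table.  A write/read
#' round-trip reproduces raw values and statuses exactly.
#'
#' @param panel a [CytokinePanel].
#' @param panel_path,lod_path,clinical_path output file paths
#'   (`clinical_path` optional).
#' @return invisibly, the paths written.
#' @export
writePanel <- function(panel, panel_path, lod_path, clinical_path = NULL) {
  conc <- panelConc(panel)
  st <- panelStatus(panel)
  out <- matrix("", ncol(conc), nrow(conc))        # subjects x analytes
  chr <- format(t(conc), trim = TRUE, digits = 15)
  keep <- t(!is.na(conc))
  out[keep] <- chr[keep]
  out[t(st == "below" & is.na(conc))] <- "<LOD"
  df <- data.frame(id = colnames(conc), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("id", rownames(conc))
  utils::write.csv(df, panel_path, row.names = FALSE, quote = FALSE)
  rd <- as.data.frame(analyteInfo(panel))
  utils::write.csv(data.frame(analyte = rownames(rd),
                              rd[c("lower_lod", "upper_lod", "curve_min")]),
                   lod_path, row.names = FALSE, quote = FALSE)
  if (!is.null(clinical_path)) {
    cd <- as.data.frame(subjectInfo(panel))
    utils::write.csv(cbind(id = rownames(cd), cd), clinical_path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(c(panel_path, lod_path, clinical_path))
}

#' Apply the study's limit-of-detection rules
#'
#' Implements the preprocessing conventions of the panel analysis.  In
#' every mode, above-LOD cells are set to the analyte-specific upper LOD
#' plus 10\% (`upper_lod * 1.1`) on the concentration scale before any
#' transform.  Below-LOD cells depend on the mode:
#' \describe{
#'   \item{`analysis`}{cells are flagged left-censored at the lower LOD;
#'     the `value` assay holds natural-log concentration with censored
#'     cells at the threshold `log(lower_lod)`, for Tobit regression.}
#'   \item{`display`}{cells are set to zero before within-marker 0--100
#'     normalization (heavily censored analytes therefore pin at 0, as in
#'     heatmap visualization); detected cells are natural-log.}
#'   \item{`ratio`}{cells are substituted with the concentration of the
#'     lowest point on the standard curve or the lowest detected sample
#'     of that analyte, whichever is smaller; `value` stays on the
#'     concentration scale for ratio computation.}
#' }
#' Missing cells stay `NA` in every mode.  The operation is idempotent:
#' applying it to an already-processed panel recomputes from the retained
#' raw assays.
#'
#' @param panel a [CytokinePanel] (or [ProcessedPanel]).
#' @param mode `"analysis"`, `"display"` or `"ratio"`.
#' @return a [ProcessedPanel].
#' @export
applyLodRules <- function(panel, mode = c("analysis", "display", "ratio")) {
  mode <- match.arg(mode)
  stopifnot(is(panel, "CytokinePanel"))
  conc <- panelConc(panel)
  st <- panelStatus(panel)
  rd <- analyteInfo(panel)
  lo <- matrix(rd$lower_lod, nrow(conc), ncol(conc))
  hi <- matrix(rd$upper_lod, nrow(conc), ncol(conc))
  obs <- conc
  obs[st == "above"] <- 1.1 * hi[st == "above"]
  value <- matrix(NA_real_, nrow(conc), ncol(conc), dimnames = dimnames(conc))
  det <- st %in% c("within", "above")
  if (mode == "analysis") {
    value[det] <- log(obs[det])
    value[st == "below"] <- log(lo[st == "below"])
    censored <- st == "below"
    censored[st == "missing"] <- NA
  } else if (mode == "display") {
    value[det] <- log(obs[det])
    value[st == "below"] <- 0
  } else {
    value[det] <- obs[det]
    sub <- .ratioSubstitutes(panel)
    value[st == "below"] <- matrix(sub, nrow(conc), ncol(conc))[st == "below"]
  }
  assays <- S4Vectors::SimpleList(conc = conc, status = st, value = value)
  if (mode == "analysis") assays$censored <- censored
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowData = rd, colData = subjectInfo(panel))
  methods::new("ProcessedPanel", se, mode = mode)
}

## Per-analyte below-LOD substitution for ratio mode:
## min(curve_min, lowest detected concentration), per analyte.
.ratioSubstitutes <- function(panel) {
  conc <- panelConc(panel)
  st <- panelStatus(panel)
  rd <- analyteInfo(panel)
  det <- conc
  det[!(st %in% c("within", "above"))] <- NA
  low_det <- suppressWarnings(apply(det, 1, min, na.rm = TRUE))
  low_det[!is.finite(low_det)] <- NA
  sub <- pmin(rd$curve_min, low_det, na.rm = TRUE)
  need <- rowSums(st == "below", na.rm = TRUE) > 0
  if (any(need & is.na(sub)))
    stop("no substitution value for analyte(s) with below-LOD cells: ",
         paste(rownames(conc)[need & is.na(sub)], collapse = ", "),
         " (no detected values and no curve_min)")
  if (any(need & !is.na(sub) & sub <= 0))
    stop("non-positive ratio substitution value")
  sub
}

#' Normalize values 0-100 within each marker
#'
#' Affine within-analyte rescaling sending the observed minimum to 0 and
#' maximum to 100, as used for heatmap display of log concentrations.
#' Constant vectors map to all zeros with a warning.
#'
#' @param x numeric vector (one analyte across subjects) or matrix
#'   (analytes x subjects, normalized row-wise).
#' @return object of the same shape with finite values in `[0, 100]`;
#'   `NA`s are preserved.
#' @export
normalizeWithinMarker <- function(x) {
  if (is.matrix(x)) return(t(apply(x, 1, normalizeWithinMarker)))
  fin <- is.finite(x)
  if (sum(fin) < 2) {
    warning("fewer than 2 finite values; returning zeros")
    x[fin] <- 0
    return(x)
  }
  rng <- range(x[fin])
  if (rng[1] == rng[2]) {
    warning("constant vector; returning zeros")
    x[fin] <- 0
    return(x)
  }
  x[fin] <- (x[fin] - rng[1]) / (rng[2] - rng[1]) * 100
  x
}
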