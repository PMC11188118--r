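#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @import SummarizedExperiment
NULL

## Per-cell detection status codes used throughout the package.
.STATUS_LEVELS <- c("below", "within", "above", "missing")

## Controlled vocabularies for the clinical annotation (colData).
.GROUP_LEVELS     <- c("trauma", "control")
.SEX_LEVELS       <- c("female", "male", "unknown")
.OUTCOME_LEVELS   <- c("discharged_home", "other_discharge", "icu", "or_",
                       "deceased", "unknown")
.MECHANISM_LEVELS <- c("fall", "gsw", "mvc", "stab", "other", "unknown")
.LOCATION_LEVELS  <- c("head_neck", "torso", "peripheral", "unknown")
.WOUND_LEVELS     <- c("internal", "penetrating", "bone", "soft_tissue")
.COVID_LEVELS     <- c("positive", "negative", "untested")

#' CytokinePanel: a subject-by-analyte concentration panel
#'
#' `CytokinePanel` extends [SummarizedExperiment::SummarizedExperiment] to
#' hold a multiplex immunoassay panel: analytes as rows, subjects as
#' columns.  Two assays are always present: `"conc"`, the raw concentration
#' in pg/mL (`NA` where the instrument reported nothing quantifiable), and
#' `"status"`, a character matrix over `below`/`within`/`above`/`missing`
#' recording each cell's position relative to the analyte's limits of
#' detection (LOD).  Per-analyte detection windows (`lower_lod`,
#' `upper_lod`, `curve_min`) live in `rowData`; clinical covariates
#' (group, age, sex, trauma activation level, discharge outcome, injury
#' mechanism/location/wound type, SARS-CoV-2 status) live in `colData`.
#'
#' `below` cells may carry an extrapolated concentration (below the lower
#' LOD) or `NA`; `missing` cells are always `NA` and are excluded from all
#' analyses -- missing is never treated as below-LOD.
#'
#' @slot mode unused here; see [ProcessedPanel].
#' @seealso [readPanel()], [applyLodRules()], [simulateCohort()]
#' @export
setClass("CytokinePanel", contains = "SummarizedExperiment")

#' ProcessedPanel: a CytokinePanel after LOD-rule preprocessing
#'
#' Produced by [applyLodRules()].  Retains the raw `conc` and `status`
#' assays (so the preprocessing is idempotent and auditable) and adds a
#' `value` assay whose meaning depends on `mode`:
#' \describe{
#'   \item{analysis}{natural-log concentration; above-LOD cells at
#'     `log(1.1 * upper_lod)`; below-LOD cells carry the censoring
#'     threshold `log(lower_lod)` and are flagged in the logical
#'     `censored` assay.}
#'   \item{display}{natural-log concentration with below-LOD cells set to
#'     0, ready for within-marker 0--100 normalization.}
#'   \item{ratio}{concentration scale; below-LOD cells substituted with
#'     `min(curve_min, lowest detected concentration)` for ratio work.}
#' }
#'
#' @slot mode character, one of `"analysis"`, `"display"`, `"ratio"`.
#' @export
setClass("ProcessedPanel",
         contains = "CytokinePanel",
         representation(mode = "character"))

#' TobitFit: one left-censored regression fit
#'
#' Maximum-likelihood fit of the left-censored Gaussian (Tobit) model for a
#' single analyte.  Coefficients are on the natural-log concentration
#' scale; `percentChange()` converts them to the percent-change reporting
#' convention \eqn{(e^\beta - 1) \times 100}.
#'
#' @slot analyte character name.
#' @slot terms coefficient names.
#' @slot beta numeric coefficient vector (log-concentration units).
#' @slot se numeric Wald standard errors.
#' @slot sigma residual SD on the log scale.
#' @slot vcov coefficient covariance (observed information inverse),
#'   including the `log(sigma)` parameter as last row/column.
#' @slot loglik maximized log-likelihood.
#' @slot converged logical; gradient-tolerance convergence flag.
#' @slot nObs,nCensored observation counts.
#' @export
setClass("TobitFit",
         representation(analyte = "character", terms = "character",
                        beta = "numeric", se = "numeric", sigma = "numeric",
                        vcov = "matrix", loglik = "numeric",
                        converged = "logical", nObs = "integer",
                        nCensored = "integer"))

#' RocResult: an empirical ROC curve with AUC and operating point
#'
#' @slot thresholds score thresholds (decreasing; first is `Inf` so the
#'   curve starts at (0,0)); a subject is called positive when
#'   `score >= threshold`.
#' @slot tpr,fpr true/false positive rates along `thresholds`.
#' @slot auc trapezoidal area under the curve (ties count 1/2; identical
#'   to the normalized Mann-Whitney statistic).
#' @slot aucCi 95\% CI (DeLong variance; stratified bootstrap fallback for
#'   degenerate tiny classes).
#' @slot nPos,nNeg class sizes.
#' @slot flipped TRUE when the score orientation was reversed so that
#'   higher score = positive class (AUC >= 0.5).
#' @slot operating list with the selected threshold, sensitivity and
#'   specificity and their Wilson intervals (see [operatingPoint()]).
#' @export
setClass("RocResult",
         representation(thresholds = "numeric", tpr = "numeric",
                        fpr = "numeric", auc = "numeric", aucCi = "numeric",
                        nPos = "integer", nNeg = "integer",
                        flipped = "logical", operating = "list"))

#' ViperModel: a fitted (or transcribed) multi-analyte survival score
#'
#' @slot analytes panel analyte names (five for the default VIPER panel).
#' @slot form `"logistic_linear_on_logs"` or `"custom_expression"`.
#' @slot coefficients named numeric: intercept plus one weight per analyte
#'   (log-concentration units) for the logistic-linear form.
#' @slot expressionText serialized formula for `custom_expression` mode,
#'   evaluated on ratio-mode concentrations with analyte names as
#'   variables.
#' @slot trainingMeta list: n, class counts, seed, exclusions, ridge flag.
#' @export
setClass("ViperModel",
         representation(analytes = "character", form = "character",
                        coefficients = "numeric",
                        expressionText = "character",
                        trainingMeta = "list"))

setValidity("CytokinePanel", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("conc", "status") %in% an))
    msg <- c(msg, "assays 'conc' and 'status' are required")
  else {
    conc <- SummarizedExperiment::assay(object, "conc")
    status <- SummarizedExperiment::assay(object, "status")
    if (!identical(dim(conc), dim(status)))
      msg <- c(msg, "'conc' and 'status' must have identical shape")
    bad <- setdiff(unique(as.vector(status)), c(.STATUS_LEVELS, NA))
    if (length(bad))
      msg <- c(msg, paste0("unknown status code(s): ",
                           paste(bad, collapse = ", ")))
    if (any(status == "missing" & !is.na(conc), na.rm = TRUE))
      msg <- c(msg, "'missing' cells must have NA concentration")
    rd <- SummarizedExperiment::rowData(object)
    need <- c("lower_lod", "upper_lod")
    if (!all(need %in% colnames(rd)))
      msg <- c(msg, "rowData must contain 'lower_lod' and 'upper_lod'")
    else {
      lo <- rd$lower_lod; hi <- rd$upper_lod
      if (any(!is.finite(lo)) || any(!is.finite(hi)) ||
          any(lo <= 0) || any(lo >= hi))
        msg <- c(msg, "LODs must satisfy 0 < lower_lod < upper_lod")
      if ("curve_min" %in% colnames(rd)) {
        cm <- rd$curve_min
        if (any(!is.na(cm) & cm <= 0))
          msg <- c(msg, "curve_min must be > 0 when present")
      }
      ## within-status cells must lie inside the detection window
      if (identical(dim(conc), dim(status)) && nrow(conc) > 0) {
        within <- status == "within"
        if (any(within & is.na(conc)))
          msg <- c(msg, "'within' cells must carry a concentration")
        lom <- matrix(lo, nrow(conc), ncol(conc))
        him <- matrix(hi, nrow(conc), ncol(conc))
        viol <- within & !is.na(conc) &
          (conc < lom - 1e-9 * lom | conc > him + 1e-9 * him)
        if (any(viol, na.rm = TRUE))
          msg <- c(msg, "'within' cells must satisfy lower_lod <= conc <= upper_lod")
        bel <- status == "below" & !is.na(conc)
        if (any(bel & conc >= lom, na.rm = TRUE))
          msg <- c(msg, "'below' cells with a value must have conc < lower_lod")
      }
    }
    if (anyDuplicated(colnames(object)))
      msg <- c(msg, "duplicate subject ids")
    if (anyDuplicated(rownames(object)))
      msg <- c(msg, "duplicate analyte names")
  }
  if (length(msg)) msg else TRUE
})

setValidity("ProcessedPanel", function(object) {
  msg <- character()
  if (length(object@mode) != 1L ||
      !object@mode %in% c("analysis", "display", "ratio"))
    msg <- c(msg, "mode must be one of 'analysis', 'display', 'ratio'")
  if (!"value" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'value' is required")
  if (identical(object@mode, "analysis")) {
    if (!"censored" %in% SummarizedExperiment::assayNames(object))
      msg <- c(msg, "analysis mode requires a 'censored' assay")
    else {
      status <- SummarizedExperiment::assay(object, "status")
      cens <- SummarizedExperiment::assay(object, "censored")
      if (sum(status == "below", na.rm = TRUE) !=
          sum(cens, na.rm = TRUE))
        msg <- c(msg, "censored flags must mark exactly the below-LOD cells")
    }
  }
  if (length(msg)) msg else TRUE
})

setValidity("TobitFit", function(object) {
  msg <- character()
  if (length(object@beta) != length(object@terms) ||
      length(object@se) != length(object@terms))
    msg <- c(msg, "beta/se/terms lengths differ")
  if (isTRUE(object@converged) && object@sigma <= 0)
    msg <- c(msg, "sigma must be > 0 for a converged fit")
  if (length(msg)) msg else TRUE
})

setValidity("RocResult", function(object) {
  msg <- character()
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc outside [0,1]")
  if (is.unsorted(object@tpr) || is.unsorted(object@fpr))
    msg <- c(msg, "tpr/fpr must be nondecreasing along thresholds")
  if (length(object@aucCi) == 2 && object@aucCi[1] > object@aucCi[2])
    msg <- c(msg, "CI bounds out of order")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CytokinePanel", function(object) {
  st <- SummarizedExperiment::assay(object, "status")
  cat(sprintf("%s: %d analytes x %d subjects\n", class(object),
              nrow(object), ncol(object)))
  grp <- SummarizedExperiment::colData(object)$group
  if (!is.null(grp))
    cat(sprintf("  groups: %s\n",
                paste(sprintf("%s=%d", names(table(grp)), table(grp)),
                      collapse = ", ")))
  tab <- table(factor(as.vector(st), levels = .STATUS_LEVELS))
  cat(sprintf("  cells: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  if (is(object, "ProcessedPanel"))
    cat(sprintf("  LOD rules applied: mode '%s'\n", object@mode))
})

setMethod("show", "TobitFit", function(object) {
  cat(sprintf("TobitFit '%s': n=%d (%d left-censored), sigma=%.4g, %s\n",
              object@analyte, object@nObs, object@nCensored, object@sigma,
              if (object@converged) "converged" else "NOT converged"))
  pc <- percentChange(object@beta, object@se)
  df <- data.frame(term = object@terms, beta = object@beta, se = object@se,
                   percent = pc$point, lo = pc$lo, hi = pc$hi)
  print(df, row.names = FALSE, digits = 4)
})

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult: AUC %.4f (95%% CI %.4f-%.4f), %d pos / %d neg%s\n",
              object@auc, object@aucCi[1], object@aucCi[2],
              object@nPos, object@nNeg,
              if (object@flipped) " [score orientation flipped]" else ""))
  if (length(object@operating))
    cat(sprintf("  operating point (%s): threshold %.4g, sens %.3f (%.3f-%.3f), spec %.3f (%.3f-%.3f)\n",
                object@operating$rule, object@operating$threshold,
                object@operating$sensitivity, object@operating$sens_ci[1],
                object@operating$sens_ci[2], object@operating$specificity,
                object@operating$spec_ci[1], object@operating$spec_ci[2]))
})

setMethod("show", "ViperModel", function(object) {
  cat(sprintf("ViperModel (%s) on %d analytes: %s\n", object@form,
              length(object@analytes),
              paste(object@analytes, collapse = ", ")))
  if (object@form == "logistic_linear_on_logs") {
    print(round(object@coefficients, 4))
  } else cat("  expression:", object@expressionText, "\n")
})

#' Accessors for panel objects
#'
#' `panelConc()`, `panelStatus()` and `panelValue()` return the raw
#' concentration, detection-status and processed-value matrices;
#' `analyteInfo()` the per-analyte LOD table; `subjectInfo()` the clinical
#' covariates; `panelMode()` the preprocessing mode of a
#' [ProcessedPanel].
#'
#' @param x a [CytokinePanel] or [ProcessedPanel].
#' @return matrix, `DataFrame` or character as appropriate.
#' @export
panelConc <- function(x) SummarizedExperiment::assay(x, "conc")

#' @rdname panelConc
#' @export
panelStatus <- function(x) SummarizedExperiment::assay(x, "status")

#' @rdname panelConc
#' @export
panelValue <- function(x) {
  stopifnot(is(x, "ProcessedPanel"))
  SummarizedExperiment::assay(x, "value")
}

#' @rdname panelConc
#' @export
analyteInfo <- function(x) SummarizedExperiment::rowData(x)

#' @rdname panelConc
#' @export
subjectInfo <- function(x) SummarizedExperiment::colData(x)

#' @rdname panelConc
#' @export
panelMode <- function(x) {
  stopifnot(is(x, "ProcessedPanel"))
  x@mode
}
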