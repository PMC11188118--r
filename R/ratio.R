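## All-pairs analyte ratio screening for survival prediction.
##
## All outcome analyses in this module dichotomize discharge disposition
## as discharged-to-home vs deceased; subjects discharged anywhere else
## (rehab, other facility, ICU/OR disposition codes, unknown) are
## excluded.

.survivalSubset <- function(panel) {
  oc <- subjectInfo(panel)$outcome
  which(oc %in% c("discharged_home", "deceased"))
}

#' Per-subject concentration ratio of two analytes
#'
#' Elementwise `numerator / denominator` on the concentration scale
#' (pg/mL : pg/mL) of a ratio-mode [ProcessedPanel], in which below-LOD
#' cells have already been substituted with the lower of the standard
#' curve minimum and the lowest detected sample.  Subjects missing either
#' analyte are returned as `NA`.
#'
#' @param processed a ratio-mode [ProcessedPanel].
#' @param numerator,denominator analyte names.
#' @return named numeric vector of per-subject ratios.
#' @export
computeRatio <- function(processed, numerator, denominator) {
  stopifnot(is(processed, "ProcessedPanel"), panelMode(processed) == "ratio")
  v <- panelValue(processed)
  for (a in c(numerator, denominator))
    if (!a %in% rownames(v)) stop("analyte not in panel: ", a)
  den <- v[denominator, ]
  if (any(!is.na(den) & den <= 0))
    stop("non-positive denominator value for ", denominator)
  v[numerator, ] / den
}

#' All-pairs ratio fold-change screen, deceased vs discharged
#'
#' For every ordered analyte pair (numerator, denominator), computes the
#' per-subject concentration ratio and summarizes the fold change of the
#' deceased group over the discharged-to-home group:
#' `fold = summary(ratio | deceased) / summary(ratio | discharged_home)`,
#' with the group summary the median by default (robust to the heavy
#' right skew of cytokine data; a geometric-mean option is provided).
#' The matrix is antisymmetric on the log scale:
#' `log fold(a:b) = -log fold(b:a)`.
#'
#' @param processed a ratio-mode [ProcessedPanel] whose `colData` carries
#'   `outcome`.
#' @param summary `"median"` (default) or `"geometric_mean"`.
#' @return a list of class `RatioTable`: `fold` (k x k matrix, rows =
#'   numerator, columns = denominator, `NA` diagonal), `pairs` (tidy
#'   data.frame of ordered pairs with `fold`, `log_fold` and descending
#'   `|log fold|` rank), `n_deceased`, `n_discharged`, `summary`.
#' @export
foldChangeMatrix <- function(processed, summary = c("median",
                                                    "geometric_mean")) {
  summary <- match.arg(summary)
  stopifnot(is(processed, "ProcessedPanel"), panelMode(processed) == "ratio")
  idx <- .survivalSubset(processed)
  oc <- subjectInfo(processed)$outcome[idx]
  dead <- oc == "deceased"
  if (!any(dead) || !any(!dead))
    stop("both outcome groups (deceased, discharged_home) must be non-empty")
  v <- panelValue(processed)[, idx, drop = FALSE]
  k <- nrow(v)
  nm <- rownames(v)
  smry <- function(m) {
    if (summary == "median") apply(m, 1, stats::median, na.rm = TRUE)
    else exp(rowMeans(log(m), na.rm = TRUE))
  }
  fold <- matrix(NA_real_, k, k, dimnames = list(numerator = nm,
                                                 denominator = nm))
  for (j in seq_len(k)) {
    den <- v[j, ]
    r <- sweep(v, 2, den, "/")          # ratios with denominator j
    fa <- smry(r[, dead, drop = FALSE])
    fb <- smry(r[, !dead, drop = FALSE])
    f <- fa / fb
    f[fb == 0 | fa == 0 | !is.finite(f)] <- NA    # undefined pairs
    fold[, j] <- f
    fold[j, j] <- NA
  }
  iu <- which(upper.tri(fold) | lower.tri(fold), arr.ind = TRUE)
  pairs <- data.frame(numerator = nm[iu[, 1]], denominator = nm[iu[, 2]],
                      fold = fold[iu], log_fold = log(fold[iu]),
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(-abs(pairs$log_fold)), ]
  pairs$rank <- seq_len(nrow(pairs))
  rownames(pairs) <- NULL
  structure(list(fold = fold, pairs = pairs, n_deceased = sum(dead),
                 n_discharged = sum(!dead), summary = summary),
            class = "RatioTable")
}

#' @export
print.RatioTable <- function(x, ...) {
  cat(sprintf("RatioTable: %d analytes, %d ordered pairs (%s summary); %d deceased vs %d discharged\n",
              nrow(x$fold), nrow(x$pairs), x$summary, x$n_deceased,
              x$n_discharged))
  cat("top pairs by |log fold|:\n")
  print(utils::head(x$pairs, 5), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Evaluate a two-analyte ratio as a survival predictor
#'
#' Computes the per-subject concentration ratio, restricts to the
#' requested trauma-activation stratum, dichotomizes the outcome as
#' deceased (positive class) vs discharged-to-home, and evaluates the
#' ratio as a continuous score by ROC.  Score orientation is chosen so
#' that AUC >= 0.5 (a low protective ratio flags high risk); the flip is
#' recorded on the result.
#'
#' @param processed a ratio-mode [ProcessedPanel].
#' @param numerator,denominator analyte names.
#' @param level trauma activation level(s) to keep, or `NULL` for all
#'   trauma patients.
#' @param rule operating-point rule passed to [operatingPoint()].
#' @return a [RocResult-class] with operating point filled.
#' @export
ratioPredictorEval <- function(processed, numerator, denominator,
                               level = NULL,
                               rule = c("youden", "max_sens_then_spec")) {
  rule <- match.arg(rule)
  r <- computeRatio(processed, numerator, denominator)
  cd <- as.data.frame(subjectInfo(processed))
  keep <- cd$outcome %in% c("discharged_home", "deceased")
  if (!is.null(level))
    keep <- keep & !is.na(cd$trauma_level) & cd$trauma_level %in% level
  keep <- keep & !is.na(r)
  labs <- cd$outcome[keep] == "deceased"
  if (!any(labs) || !any(!labs))
    stop("a class is empty after filtering to stratum: ",
         if (is.null(level)) "all" else paste(level, collapse = ","))
  operatingPoint(rocCurve(r[keep], labs, orient = TRUE), rule = rule)
}
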