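## Random-forest permutation importance with per-iteration 0-100
## normalization.

#' Build the classifier feature matrix from a processed panel
#'
#' Tree ensembles need complete features, so this module departs from the
#' censored-likelihood treatment: each analyte feature is the analysis
#' log value for detected cells with below-LOD cells at the display value
#' 0 *before* z-score standardization; missing cells are mean-imputed
#' (0 after standardization).  Age is standardized, sex one-hot encoded
#' as `sex_female`.
#'
#' @param processed an analysis-mode [ProcessedPanel].
#' @param includeAge,includeSex add clinical covariates as features.
#' @param subset optional column (subject) index.
#' @return numeric matrix, subjects x features.
#' @export
featureMatrix <- function(processed, includeAge = FALSE, includeSex = FALSE,
                          subset = NULL) {
  stopifnot(is(processed, "ProcessedPanel"),
            panelMode(processed) == "analysis")
  v <- panelValue(processed)
  cen <- SummarizedExperiment::assay(processed, "censored")
  v[which(cen)] <- 0
  if (!is.null(subset)) v <- v[, subset, drop = FALSE]
  X <- t(v)
  cd <- as.data.frame(subjectInfo(processed))
  if (!is.null(subset)) cd <- cd[subset, , drop = FALSE]
  if (includeAge) X <- cbind(X, age = cd$age)
  X <- scale(X)
  X[is.na(X)] <- 0                       # missing cells / constant columns
  if (includeSex)
    X <- cbind(X, sex_female = as.numeric(cd$sex == "female"))
  X
}

#' Per-iteration relative (0-100) importance normalization
#'
#' Divides each feature's permutation importance score by the largest
#' importance score of any feature in the same iteration, then multiplies
#' by 100, so the top feature of every iteration scores exactly 100.
#'
#' @param raw numeric matrix, features x iterations (or a vector for one
#'   iteration).
#' @return matrix (or vector) of the same shape on the 0-100 scale.
#' @examples
#' relativeImportance(c(5, 10, 20))   # 25, 50, 100
#' @export
relativeImportance <- function(raw) {
  if (is.null(dim(raw))) return(drop(relativeImportance(cbind(raw))))
  apply(raw, 2, function(col) {
    m <- max(col)
    if (!is.finite(m) || m <= 0) {
      warning("iteration with no positive importance; returning zeros")
      return(rep(0, length(col)))
    }
    col / m * 100
  })
}

#' Random-forest permutation importance over repeated iterations
#'
#' Fits a randomized tree ensemble per iteration (each with a fresh
#' sub-seed spawned deterministically from `seed`), computes each
#' feature's out-of-bag permutation importance (mean accuracy drop over
#' label-preserving permutations of that feature among out-of-bag
#' samples), and normalizes each iteration to the 0-100 relative scale
#' via [relativeImportance()].
#'
#' @param x feature matrix (subjects x features), e.g. from
#'   [featureMatrix()].
#' @param labels binary labels (logical, 0/1 or two-level factor);
#'   both classes must be present.
#' @param nIterations model iterations (default 10).
#' @param numTrees trees per forest (default 500).
#' @param permRepeats permutations per feature per iteration (default 5).
#' @param mtry features tried per split (default `floor(sqrt(p))`).
#' @param minNode minimal node size to attempt a split (default 5).
#' @param classWeight if `TRUE`, grow each tree Balanced-Random-Forest
#'   style (a bootstrap of the minority-class size drawn with
#'   replacement from each class, leaving ~37\% of each class
#'   out-of-bag) and measure importance as the drop in out-of-bag
#'   *balanced* accuracy, so a rare outcome class is neither absent from
#'   the out-of-bag rows nor drowned out by the majority; changes
#'   ranking behaviour only, never the normalization contract.
#' @param seed master seed.
#' @return an object of class `ImportanceResult`: list with `features`,
#'   `raw` and `relative` (features x iterations matrices),
#'   `median_relative`, `oob_accuracy` per iteration, and the call
#'   parameters.
#' @export
permutationImportance <- function(x, labels, nIterations = 10,
                                  numTrees = 500, permRepeats = 5,
                                  mtry = NULL, minNode = 5,
                                  classWeight = FALSE, seed = 1L) {
  x <- as.matrix(x)
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  y <- as.integer(labels)
  if (length(unique(y[!is.na(y)])) < 2)
    stop("both classes must be present in labels")
  stopifnot(nIterations >= 1)
  ok <- !is.na(y) & stats::complete.cases(x)
  x <- x[ok, , drop = FALSE]; y <- y[ok]
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  if (is.null(colnames(x)))
    colnames(x) <- paste0("feature", seq_len(ncol(x)))
  raw <- matrix(NA_real_, ncol(x), nIterations,
                dimnames = list(colnames(x), NULL))
  oobAcc <- numeric(nIterations)
  for (it in seq_len(nIterations)) {
    set.seed(.subSeed(seed, 9L, it))
    fit <- .rfImportanceCpp(x, y, as.integer(numTrees), as.integer(mtry),
                            as.integer(minNode), as.integer(permRepeats),
                            as.integer(classWeight))
    raw[, it] <- fit$importance
    oobAcc[it] <- fit$oob_accuracy
  }
  rel <- relativeImportance(raw)
  structure(list(features = colnames(x), raw = raw, relative = rel,
                 median_relative = apply(rel, 1, stats::median),
                 oob_accuracy = oobAcc,
                 params = list(nIterations = nIterations,
                               numTrees = numTrees,
                               permRepeats = permRepeats, mtry = mtry,
                               minNode = minNode,
                               classWeight = classWeight, seed = seed)),
            class = "ImportanceResult")
}

#' @export
print.ImportanceResult <- function(x, ...) {
  cat(sprintf("ImportanceResult: %d features, %d iterations (%d trees, mtry %d)\n",
              length(x$features), x$params$nIterations, x$params$numTrees,
              x$params$mtry))
  top <- sort(x$median_relative, decreasing = TRUE)
  cat("top features (median relative importance):\n")
  print(round(utils::head(top, 8), 1))
  invisible(x)
}

#' Select features by median relative importance
#'
#' Features whose median 0-100 relative permutation importance across
#' iterations is strictly greater than `threshold`, sorted descending.
#'
#' @param result an `ImportanceResult` from [permutationImportance()].
#' @param threshold selection cutoff on the relative scale (default 10).
#' @return character vector of selected feature names (possibly empty).
#' @export
selectFeatures <- function(result, threshold = 10) {
  stopifnot(inherits(result, "ImportanceResult"))
  med <- sort(result$median_relative, decreasing = TRUE)
  names(med)[med > threshold]
}

#' Permutation importance for a standard cohort contrast
#'
#' Convenience wrapper assembling features and labels for the three
#' classifications of interest: trauma vs control, level-1 vs level-4
#' trauma, and deceased vs discharged-to-home (other dispositions
#' excluded).  Trauma-vs-control uses analytes plus age and one-hot sex;
#' the within-trauma contrasts use analytes only.
#'
#' @param processed an analysis-mode [ProcessedPanel].
#' @param contrast one of `"trauma_vs_control"`, `"level1_vs_level4"`,
#'   `"deceased_vs_discharged"`.
#' @param ... passed to [permutationImportance()].
#' @return an `ImportanceResult`.
#' @export
importanceForContrast <- function(processed,
                                  contrast = c("trauma_vs_control",
                                               "level1_vs_level4",
                                               "deceased_vs_discharged"),
                                  ...) {
  contrast <- match.arg(contrast)
  cd <- as.data.frame(subjectInfo(processed))
  if (contrast == "trauma_vs_control") {
    subset <- seq_len(nrow(cd))
    labels <- cd$group == "trauma"
    x <- featureMatrix(processed, includeAge = TRUE, includeSex = TRUE,
                       subset = subset)
  } else if (contrast == "level1_vs_level4") {
    subset <- which(cd$group == "trauma" & cd$trauma_level %in% c(1L, 4L))
    labels <- cd$trauma_level[subset] == 1L
    x <- featureMatrix(processed, subset = subset)
  } else {
    subset <- which(cd$outcome %in% c("deceased", "discharged_home"))
    labels <- cd$outcome[subset] == "deceased"
    x <- featureMatrix(processed, subset = subset)
  }
  permutationImportance(x, labels, ...)
}
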