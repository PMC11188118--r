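## Derivation and evaluation of the five-analyte survival score (VIPER),
## plus end-to-end pipeline orchestration.

#' Derive a survival panel from ratio screening and importance
#'
#' Reproduces the panel-derivation procedure on deceased vs
#' discharged-to-home trauma patients:
#' \enumerate{
#'   \item ratio candidates: analytes appearing in the top pairs of the
#'     all-pairs fold-change screen (by descending `|log fold|`,
#'     unordered pairs);
#'   \item importance candidates: analytes selected by median relative
#'     permutation importance > `importanceThreshold` on the
#'     deceased-vs-discharged classification;
#'   \item intersection of the two candidate lists;
#'   \item per-analyte ROC refinement: candidates ranked by AUC (CI
#'     width breaking ties) and pruned from the bottom until
#'     `panelSize` remain.
#' }
#' If the intersection is already at or below `panelSize`, it is
#' returned as-is with a warning when smaller.
#'
#' @param panel a [CytokinePanel].
#' @param topPairs unordered ratio pairs to harvest analytes from
#'   (default 120, about the top 7\% of the 1711 unordered pairs of a
#'   59-analyte panel -- a deliberately wide first-pass screen; the
#'   selectivity comes from the intersection with the importance screen
#'   and the AUC pruning).
#' @param importanceThreshold selection cutoff (default 10).
#' @param panelSize target panel size (default 5).
#' @param nIterations,numTrees,permRepeats,classWeight forwarded to
#'   [permutationImportance()].
#' @param seed master seed for the importance iterations.
#' @return list of class `PanelDerivation`: `ratio_candidates`,
#'   `importance_candidates`, `intersection`, `auc` (named, per
#'   candidate), `final_panel`.
#' @export
derivePanel <- function(panel, topPairs = 120, importanceThreshold = 10,
                        panelSize = 5, nIterations = 10, numTrees = 500,
                        permRepeats = 5, classWeight = TRUE, seed = 1L) {
  ratioPanel <- applyLodRules(panel, "ratio")
  analysisPanel <- applyLodRules(panel, "analysis")
  cd <- as.data.frame(subjectInfo(panel))
  idx <- which(cd$outcome %in% c("deceased", "discharged_home"))
  if (!any(cd$outcome[idx] == "deceased") ||
      !any(cd$outcome[idx] == "discharged_home"))
    stop("both outcome classes (deceased, discharged_home) required")

  ## stage 1: ratio screen
  ft <- foldChangeMatrix(ratioPanel)
  pr <- ft$pairs
  key <- ifelse(pr$numerator < pr$denominator,
                paste(pr$numerator, pr$denominator),
                paste(pr$denominator, pr$numerator))
  pr <- pr[!duplicated(key), ]                      # unordered pairs
  top <- utils::head(pr, topPairs)
  ratio_candidates <- unique(c(rbind(top$numerator, top$denominator)))

  ## stage 2: importance screen
  imp <- importanceForContrast(analysisPanel, "deceased_vs_discharged",
                               nIterations = nIterations,
                               numTrees = numTrees,
                               permRepeats = permRepeats,
                               classWeight = classWeight, seed = seed)
  importance_candidates <- selectFeatures(imp, importanceThreshold)

  ## stage 3: intersection
  intersection <- intersect(ratio_candidates, importance_candidates)

  ## stage 4: per-analyte ROC refinement
  vals <- panelValue(analysisPanel)[, idx, drop = FALSE]
  dead <- cd$outcome[idx] == "deceased"
  auc <- vapply(intersection, function(a) {
    r <- rocCurve(vals[a, ], dead, orient = TRUE)
    c(r@auc, diff(r@aucCi))
  }, numeric(2))
  final <- intersection
  if (length(intersection) > panelSize) {
    ord <- order(-auc[1, ], auc[2, ])     # high AUC first, narrow CI ties
    final <- intersection[ord][seq_len(panelSize)]
  } else if (length(intersection) < panelSize) {
    warning("intersection smaller than panel size (",
            length(intersection), " < ", panelSize, "); returned as-is")
  }
  structure(list(ratio_candidates = ratio_candidates,
                 importance_candidates = importance_candidates,
                 intersection = intersection,
                 auc = if (length(intersection))
                   stats::setNames(auc[1, ], intersection) else numeric(),
                 final_panel = final,
                 importance = imp, ratio_table = ft),
            class = "PanelDerivation")
}

#' @export
print.PanelDerivation <- function(x, ...) {
  cat("PanelDerivation\n")
  cat("  ratio candidates:     ", paste(x$ratio_candidates, collapse = ", "),
      "\n")
  cat("  importance candidates:", paste(x$importance_candidates,
                                        collapse = ", "), "\n")
  cat("  intersection:         ", paste(x$intersection, collapse = ", "),
      "\n")
  cat("  final panel:          ", paste(x$final_panel, collapse = ", "),
      "\n")
  invisible(x)
}

## Assemble the log-concentration feature data.frame for a panel list.
.viperFeatures <- function(analysisPanel, analytes, idx = NULL) {
  vals <- panelValue(analysisPanel)
  miss <- setdiff(analytes, rownames(vals))
  if (length(miss)) stop("analyte(s) not in panel: ",
                         paste(miss, collapse = ", "))
  m <- t(vals[analytes, , drop = FALSE])
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

#' Fit (or transcribe) a VIPER survival score
#'
#' Default form is a logistic-linear model of death on the natural-log
#' concentrations of the panel analytes (analysis-mode LOD values:
#' below-LOD cells at the lower-LOD threshold), fitted by maximum
#' likelihood on deceased vs discharged-to-home trauma patients.  When
#' quasi-separation is detected the fit is ridge-stabilized (small L2
#' penalty via glmnet) with a warning.  Alternatively,
#' `form = "custom_expression"` stores a user-supplied algebraic formula
#' (evaluated on ratio-mode concentrations with analyte names as
#' variables) without any fitting -- the slot intended for transcribing a
#' published score equation.
#'
#' @param panel a [CytokinePanel].
#' @param analytes character panel (default the five-analyte VIPER list
#'   if present in the panel).
#' @param form `"logistic_linear_on_logs"` or `"custom_expression"`.
#' @param expression_text formula text for custom mode; analyte names
#'   may be backtick-quoted.
#' @param seed stored in training metadata.
#' @return a [ViperModel-class].
#' @export
fitViper <- function(panel,
                     analytes = c("IL-6", "VEGF-A", "IL-10", "IL-29",
                                  "IL-21"),
                     form = c("logistic_linear_on_logs",
                              "custom_expression"),
                     expression_text = NULL, seed = 1L) {
  form <- match.arg(form)
  if (form == "custom_expression") {
    if (is.null(expression_text)) stop("custom mode needs expression_text")
    return(methods::new("ViperModel", analytes = analytes, form = form,
                        coefficients = numeric(0),
                        expressionText = expression_text,
                        trainingMeta = list(fitted = FALSE)))
  }
  analysisPanel <- if (is(panel, "ProcessedPanel") &&
                       panelMode(panel) == "analysis") panel
  else applyLodRules(panel, "analysis")
  cd <- as.data.frame(subjectInfo(analysisPanel))
  idx <- which(cd$outcome %in% c("deceased", "discharged_home"))
  y <- as.numeric(cd$outcome[idx] == "deceased")
  if (!any(y == 1) || !any(y == 0))
    stop("both outcome classes required to fit")
  X <- .viperFeatures(analysisPanel, analytes, idx)
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  fit <- suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                         family = stats::binomial()))
  cf <- fit$coefficients
  ridge <- !fit$converged || any(!is.finite(cf)) || any(abs(cf) > 15)
  if (ridge) {
    warning("separation detected; ridge-stabilized logistic fit used")
    g <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = 0.01, standardize = TRUE)
    cf <- c(as.numeric(g$a0), as.numeric(g$beta))
  }
  names(cf) <- c("(Intercept)", analytes)
  methods::new("ViperModel", analytes = analytes,
               form = "logistic_linear_on_logs", coefficients = cf,
               expressionText = "",
               trainingMeta = list(fitted = TRUE, n = length(y),
                                   n_deceased = sum(y), seed = seed,
                                   ridge = ridge,
                                   exclusions = "non-home, non-deceased dispositions"))
}

#' Score subjects with a VIPER model
#'
#' Deterministic per-subject risk score; higher means higher predicted
#' death risk.  The fitted logistic-linear form returns the linear
#' predictor on analysis-mode log concentrations; custom expressions are
#' evaluated on ratio-mode concentrations (below-LOD cells substituted)
#' with analyte names bound as variables.  Subjects missing any panel
#' analyte score `NA` and are reported in a message.
#'
#' @param model a [ViperModel-class].
#' @param panel a [CytokinePanel] (or the matching [ProcessedPanel]).
#' @return named numeric vector of scores (one per subject).
#' @export
viperScore <- function(model, panel) {
  stopifnot(is(model, "ViperModel"))
  if (model@form == "logistic_linear_on_logs") {
    analysisPanel <- if (is(panel, "ProcessedPanel") &&
                         panelMode(panel) == "analysis") panel
    else applyLodRules(panel, "analysis")
    X <- .viperFeatures(analysisPanel, model@analytes)
    sc <- drop(cbind(1, X) %*% model@coefficients)
  } else {
    ratioPanel <- if (is(panel, "ProcessedPanel") &&
                      panelMode(panel) == "ratio") panel
    else applyLodRules(panel, "ratio")
    v <- panelValue(ratioPanel)
    env <- new.env(parent = baseenv())
    for (a in model@analytes) assign(a, v[a, ], envir = env)
    sc <- eval(str2lang(model@expressionText), envir = env)
    sc <- stats::setNames(rep_len(sc, ncol(v)), colnames(v))
  }
  if (anyNA(sc))
    message(sum(is.na(sc)), " subject(s) missing a panel analyte; scored NA")
  sc
}

## Stratified k-fold assignment preserving the outcome rate per fold.
.stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    i <- which(y == cls)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  fold
}

#' Evaluate a VIPER panel by trauma-activation stratum
#'
#' Scores deceased vs discharged-to-home trauma patients and evaluates
#' the ROC for all patients and within the requested trauma-level strata
#' (default levels 1 and 4).  By default the scores are out-of-sample:
#' the logistic model is refit within each fold of a stratified k-fold
#' split (folds preserve the death rate, so rare-death strata do not
#' collapse) and each subject is scored by the model that did not see
#' it.  `resubstitution = TRUE` instead scores with a single fit on all
#' subjects.  Strata with only one class are skipped with a message.
#'
#' @param panel a [CytokinePanel].
#' @param analytes panel analyte names.
#' @param levels trauma-activation strata to evaluate (default `c(1, 4)`).
#' @param nFolds cross-validation folds (default 5).
#' @param resubstitution if `TRUE`, no cross-validation.
#' @param seed seed for the fold split.
#' @return list of class `ViperEvaluation`: `roc` (named list of
#'   [RocResult-class] for `"all"` and each `"level<k>"`), `scores`,
#'   `model` (fit on all data), `cross_validated`.
#' @export
evaluateByLevel <- function(panel, analytes, levels = c(1L, 4L),
                            nFolds = 5, resubstitution = FALSE, seed = 1L) {
  analysisPanel <- applyLodRules(panel, "analysis")
  cd <- as.data.frame(subjectInfo(analysisPanel))
  idx <- which(cd$outcome %in% c("deceased", "discharged_home"))
  y <- as.numeric(cd$outcome[idx] == "deceased")
  model <- fitViper(analysisPanel, analytes, seed = seed)
  if (resubstitution) {
    sc <- viperScore(model, analysisPanel)[idx]
  } else {
    set.seed(.subSeed(seed, 17L))
    fold <- .stratifiedFolds(y, nFolds)
    sc <- rep(NA_real_, length(idx))
    X <- .viperFeatures(analysisPanel, analytes, idx)
    for (f in seq_len(nFolds)) {
      tr <- fold != f
      fit <- suppressWarnings(stats::glm.fit(cbind(1, X[tr, , drop = FALSE]),
                                             y[tr],
                                             family = stats::binomial()))
      cf <- fit$coefficients
      if (!fit$converged || any(!is.finite(cf)) || any(abs(cf) > 15)) {
        g <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr],
                            family = "binomial", alpha = 0, lambda = 0.01)
        cf <- c(as.numeric(g$a0), as.numeric(g$beta))
      }
      sc[fold == f] <- drop(cbind(1, X[fold == f, , drop = FALSE]) %*% cf)
    }
  }
  strata <- c(list(all = rep(TRUE, length(idx))),
              stats::setNames(lapply(levels, function(l)
                !is.na(cd$trauma_level[idx]) & cd$trauma_level[idx] == l),
                paste0("level", levels)))
  roc <- list()
  for (s in names(strata)) {
    keep <- strata[[s]] & !is.na(sc)
    if (length(unique(y[keep])) < 2) {
      message("stratum '", s, "' has a single class; skipped")
      next
    }
    roc[[s]] <- rocCurve(sc[keep], y[keep] == 1, orient = TRUE)
  }
  structure(list(roc = roc, scores = stats::setNames(sc, rownames(cd)[idx]),
                 model = model, cross_validated = !resubstitution,
                 nFolds = if (resubstitution) NA_integer_ else nFolds),
            class = "ViperEvaluation")
}

#' @export
print.ViperEvaluation <- function(x, ...) {
  cat(sprintf("ViperEvaluation (%s)\n",
              if (x$cross_validated)
                sprintf("%d-fold cross-validated", x$nFolds)
              else "resubstitution"))
  for (s in names(x$roc))
    cat(sprintf("  %-8s AUC %.4f (%.4f-%.4f)\n", s, x$roc[[s]]@auc,
                x$roc[[s]]@aucCi[1], x$roc[[s]]@aucCi[2]))
  invisible(x)
}

#' Run the full panel analysis pipeline
#'
#' Orchestrates the end-to-end analysis:
#' read (or simulate) the cohort, apply LOD rules, fit trauma-vs-control
#' Tobit models with directional FDR, compare below-LOD prevalence,
#' screen all-pairs ratios, compute deceased-vs-discharged permutation
#' importance, derive the survival panel, fit the VIPER score, and
#' evaluate it by trauma level.  All tidy outputs, a JSON summary and a
#' run log (seeds, versions, stage timings) are written under `outdir`.
#' A stage failure halts with a stage-named error; outputs written so
#' far are preserved.
#'
#' @param config a list, or path to a YAML file, with (all optional
#'   unless noted): `panel`, `lods`, `clinical` (input CSV paths) *or*
#'   `synthetic = TRUE` (default) to use [paperlikeConfig()]; `seed`
#'   (default 1); `outdir` (required); `top_pairs`, `importance_threshold`,
#'   `panel_size`, `iterations`, `trees`, `perm_repeats`, `folds`.
#' @return invisibly, a list with all stage results.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(synthetic = TRUE, seed = 1L, top_pairs = 120,
         importance_threshold = 10, panel_size = 5, iterations = 10,
         trees = 500, perm_repeats = 5, folds = 5), config)
  if (is.null(cfg$outdir)) stop("config must name an 'outdir'")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(cfg$outdir, "run_log.txt")
  logLine <- function(...) cat(sprintf("[%s] %s\n",
                                       format(Sys.time(), "%H:%M:%S"),
                                       sprintf(...)),
                               file = logPath, append = TRUE)
  stage <- function(name, expr) {
    logLine("stage %s: start", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cat(sprintf("traumaViper %s | R %s | seed %s\n",
              as.character(utils::packageVersion("traumaViper")),
              getRversion(), cfg$seed), file = logPath)

  panel <- stage("input", {
    if (isTRUE(cfg$synthetic)) {
      sim <- simulateCohort(paperlikeConfig(seed = cfg$seed))
      utils::write.csv(sim$truthAnalytes,
                       file.path(cfg$outdir, "truth_analytes.csv"),
                       row.names = FALSE)
      sim$panel
    } else {
      for (f in c(cfg$panel, cfg$lods, cfg$clinical))
        if (!file.exists(f)) stop("input file not found: ", f)
      readPanel(cfg$panel, cfg$lods, cfg$clinical)
    }
  })

  tob <- stage("tobit", {
    proc <- applyLodRules(panel, "analysis")
    res <- directionalFdr(fitPanel(proc, "univariable_group"))
    utils::write.csv(res, file.path(cfg$outdir, "tobit_group.csv"),
                     row.names = FALSE)
    res
  })
  prev <- stage("lod_prevalence", {
    res <- lodPrevalence(panel)
    utils::write.csv(res, file.path(cfg$outdir, "lod_prevalence.csv"),
                     row.names = FALSE)
    res
  })
  derivation <- stage("derive", {
    d <- derivePanel(panel, topPairs = cfg$top_pairs,
                     importanceThreshold = cfg$importance_threshold,
                     panelSize = cfg$panel_size,
                     nIterations = cfg$iterations, numTrees = cfg$trees,
                     permRepeats = cfg$perm_repeats, seed = cfg$seed)
    utils::write.csv(d$ratio_table$pairs,
                     file.path(cfg$outdir, "ratio_pairs.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(feature = d$importance$features,
                                median_relative = d$importance$median_relative,
                                selected = d$importance$features %in%
                                  d$importance_candidates),
                     file.path(cfg$outdir, "importance.csv"),
                     row.names = FALSE)
    d
  })
  evaluation <- stage("evaluate", {
    ev <- evaluateByLevel(panel, derivation$final_panel,
                          nFolds = cfg$folds, seed = cfg$seed)
    ev
  })
  stage("report", {
    summary <- list(
      seed = cfg$seed,
      n_subjects = ncol(panel), n_analytes = nrow(panel),
      n_significant_tobit = sum(tob$significant),
      n_more_below_lod_trauma = sum(prev$q_value < 0.01 &
                                      prev$difference > 0),
      final_panel = derivation$final_panel,
      viper_coefficients = as.list(evaluation$model@coefficients),
      auc = lapply(evaluation$roc, function(r)
        list(auc = r@auc, ci = r@aucCi)))
    jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  logLine("pipeline complete")
  invisible(list(panel = panel, tobit = tob, lod_prevalence = prev,
                 derivation = derivation, evaluation = evaluation))
}
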