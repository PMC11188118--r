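## Left-censored Gaussian (Tobit) maximum likelihood.
##
## Parameterization: theta = (beta, log sigma).  Observed cells contribute
## log phi((y - Xb)/s) - log s; left-censored cells contribute
## log Phi((c - Xb)/s) with c the censoring threshold (log lower LOD).

.tobitNll <- function(theta, X, y, cens, cthr) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  s <- exp(theta[p + 1L])
  xb <- drop(X %*% beta)
  zo <- (y[!cens] - xb[!cens]) / s
  zc <- (cthr[cens] - xb[cens]) / s
  -(sum(stats::dnorm(zo, log = TRUE) - log(s)) +
      sum(stats::pnorm(zc, log.p = TRUE)))
}

.tobitGrad <- function(theta, X, y, cens, cthr) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  s <- exp(theta[p + 1L])
  xb <- drop(X %*% beta)
  zo <- (y[!cens] - xb[!cens]) / s
  zc <- (cthr[cens] - xb[cens]) / s
  lam <- exp(stats::dnorm(zc, log = TRUE) - stats::pnorm(zc, log.p = TRUE))
  gb <- -crossprod(X[!cens, , drop = FALSE], zo) / s +
    crossprod(X[cens, , drop = FALSE], lam) / s
  gls <- sum(1 - zo^2) + sum(lam * zc)
  c(drop(gb), gls)
}

#' Fit a left-censored Gaussian (Tobit) regression
#'
#' Maximizes the censored-Gaussian log-likelihood for a log-concentration
#' response left-censored at the lower limit of detection.  Observed
#' observations contribute Gaussian density terms, censored observations
#' the Gaussian lower-tail probability at their threshold.  With zero
#' censored observations the likelihood reduces to ordinary least squares
#' and the estimates match OLS.
#'
#' Optimization is quasi-Newton (BFGS) on `(beta, log sigma)` with
#' analytic gradients, started from OLS on the threshold-filled response,
#' followed by Newton polishing to a gradient tolerance of `1e-8`
#' (relative to the log-likelihood magnitude).  Wald covariance comes
#' from the inverse observed information.
#'
#' @param y numeric response (natural-log concentration); censored
#'   entries hold their censoring threshold.
#' @param censored logical; `TRUE` for left-censored observations.
#' @param X design matrix (with intercept column); must be full rank.
#' @param analyte optional name carried into the result.
#' @return a [TobitFit-class].
#' @examples
#' set.seed(1)
#' x <- rnorm(100); y <- 1 + 0.5 * x + rnorm(100)
#' cens <- y < -0.2; y[cens] <- -0.2
#' tobitFit(y, cens, cbind(1, x))
#' @export
tobitFit <- function(y, censored, X, analyte = "") {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)",
                     if (ncol(X) > 1L) paste0("x", seq_len(ncol(X) - 1L)))
  keep <- !is.na(y) & !is.na(censored) & stats::complete.cases(X)
  y <- y[keep]; censored <- censored[keep]
  X <- X[keep, , drop = FALSE]
  if (!any(!censored))
    stop("all observations are censored; model not identifiable")
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient")
  cthr <- y                                   # censored cells hold threshold
  ## OLS start on the threshold-filled response
  ols <- stats::lm.fit(X, y)
  s0 <- sqrt(max(sum(ols$residuals^2) / max(1, nrow(X) - ncol(X)), 1e-6))
  theta <- c(ols$coefficients, log(s0))
  opt <- stats::optim(theta, .tobitNll, .tobitGrad, X = X, y = y,
                      cens = censored, cthr = cthr, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-14))
  theta <- opt$par
  ## Newton polish with finite-difference Hessian of the analytic gradient
  H <- NULL
  for (it in seq_len(25)) {
    g <- .tobitGrad(theta, X, y, censored, cthr)
    nll <- .tobitNll(theta, X, y, censored, cthr)
    if (max(abs(g)) < 1e-8 * max(1, abs(nll))) break
    H <- stats::optimHess(theta, .tobitNll, .tobitGrad, X = X, y = y,
                          cens = censored, cthr = cthr)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    cand <- theta - step
    ## step-halving to guarantee monotone improvement
    h <- 1
    while (h > 1e-4 &&
           (!is.finite(v <- .tobitNll(theta - h * step, X, y, censored,
                                      cthr)) || v > nll)) h <- h / 2
    if (h <= 1e-4) break
    theta <- theta - h * step
  }
  g <- .tobitGrad(theta, X, y, censored, cthr)
  nll <- .tobitNll(theta, X, y, censored, cthr)
  converged <- max(abs(g)) < 1e-8 * max(1, abs(nll)) ||
    max(abs(g)) < 1e-6
  if (!converged)
    warning("Tobit fit did not reach gradient tolerance",
            if (nzchar(analyte)) paste0(" for '", analyte, "'"))
  H <- stats::optimHess(theta, .tobitNll, .tobitGrad, X = X, y = y,
                        cens = censored, cthr = cthr)
  V <- tryCatch(solve(H), error = function(e)
    matrix(NA_real_, length(theta), length(theta)))
  p <- ncol(X)
  se <- sqrt(pmax(diag(V)[seq_len(p)], 0))
  methods::new("TobitFit", analyte = analyte, terms = colnames(X),
               beta = unname(theta[seq_len(p)]), se = unname(se),
               sigma = unname(exp(theta[p + 1L])), vcov = V, loglik = -nll,
               converged = converged, nObs = nrow(X),
               nCensored = sum(censored))
}

#' Percent-change reporting of log-scale coefficients
#'
#' Converts a log-concentration regression coefficient to the percent
#' change in concentration per unit increase of the predictor:
#' \eqn{(e^\beta - 1) \times 100}, with 95\% CI endpoints
#' \eqn{(e^{\beta \pm z_{0.975} \cdot se} - 1) \times 100}.
#'
#' @param beta,se numeric vectors of coefficients and standard errors.
#' @param level confidence level (default 0.95).
#' @return list with numeric vectors `point`, `lo`, `hi` (percent).
#' @examples
#' percentChange(log(2), 0.1)   # +100% point estimate
#' @export
percentChange <- function(beta, se, level = 0.95) {
  stopifnot(all(se >= 0, na.rm = TRUE))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(point = (exp(beta) - 1) * 100,
       lo = (exp(beta - z * se) - 1) * 100,
       hi = (exp(beta + z * se) - 1) * 100)
}

## Location category used for the injury-location model: reference is
## "peripheral_only".
.locationCategory <- function(loc) {
  parts <- strsplit(ifelse(is.na(loc), "", loc), "|", fixed = TRUE)
  vapply(parts, function(z) {
    z <- setdiff(z, "")
    if (!length(z) || "unknown" %in% z) return(NA_character_)
    if (length(z) == 3L) return("all")
    if (length(z) == 1L) return(paste0(z, "_only"))
    "combination"
  }, character(1))
}

#' Fit per-analyte Tobit models across a panel
#'
#' Runs one left-censored regression per analyte on an analysis-mode
#' [ProcessedPanel].  Models:
#' \describe{
#'   \item{`univariable_group`}{log concentration ~ group (trauma vs
#'     control reference); the trauma coefficient is the focal term.}
#'   \item{`age_adjusted`}{~ mean-centered age + group (age models
#'     control for patient type); focal term `age`.}
#'   \item{`sex_adjusted`}{~ sex (female vs male reference) + group;
#'     focal term `sexfemale`.}
#'   \item{`trauma_level`}{trauma patients only; one-hot levels 1-3
#'     against reference level 4.}
#'   \item{`mechanism`}{trauma only; reference `"other"`.}
#'   \item{`location`}{trauma only; location category (head_neck_only,
#'     torso_only, all, combination) against reference
#'     `"peripheral_only"`.}
#'   \item{`covid`}{tested trauma patients only; positive vs negative
#'     reference.}
#' }
#' Age is mean-centered over the fitted subjects.  Analytes whose cells
#' are all censored (or all missing) are skipped with a message.
#'
#' @param processed an analysis-mode [ProcessedPanel].
#' @param model model keyword (above).
#' @return a tidy `data.frame` with one row per analyte and focal term:
#'   `analyte`, `model`, `term`, `beta`, `se`, `sigma`, `n`,
#'   `n_censored`, `converged`, `percent_change`, `ci_lo`, `ci_hi`.  The
#'   full [TobitFit-class] objects are attached as attribute `"fits"`.
#' @export
fitPanel <- function(processed,
                     model = c("univariable_group", "age_adjusted",
                               "sex_adjusted", "trauma_level", "mechanism",
                               "location", "covid")) {
  model <- match.arg(model)
  stopifnot(is(processed, "ProcessedPanel"),
            panelMode(processed) == "analysis")
  cd <- as.data.frame(subjectInfo(processed))
  keep <- rep(TRUE, nrow(cd))
  if (model == "univariable_group") {
    X <- cbind("(Intercept)" = 1, grouptrauma = as.numeric(cd$group == "trauma"))
    focal <- "grouptrauma"
  } else if (model == "age_adjusted") {
    X <- cbind("(Intercept)" = 1, age = cd$age - mean(cd$age),
               grouptrauma = as.numeric(cd$group == "trauma"))
    focal <- "age"
  } else if (model == "sex_adjusted") {
    keep <- cd$sex %in% c("female", "male")
    X <- cbind("(Intercept)" = 1,
               sexfemale = as.numeric(cd$sex == "female"),
               grouptrauma = as.numeric(cd$group == "trauma"))[keep, ,
                                                               drop = FALSE]
    focal <- "sexfemale"
  } else if (model == "trauma_level") {
    keep <- cd$group == "trauma" & !is.na(cd$trauma_level)
    lv <- factor(cd$trauma_level[keep], levels = c(4, 1, 2, 3))
    X <- stats::model.matrix(~lv)
    colnames(X) <- c("(Intercept)", paste0("level", levels(lv)[-1]))
    focal <- colnames(X)[-1]
  } else if (model == "mechanism") {
    keep <- cd$group == "trauma" & cd$mechanism != "unknown"
    mech <- factor(cd$mechanism[keep],
                   levels = c("other", "fall", "gsw", "mvc", "stab"))
    X <- stats::model.matrix(~mech)
    colnames(X) <- c("(Intercept)", paste0("mechanism", levels(mech)[-1]))
    focal <- colnames(X)[-1]
  } else if (model == "location") {
    cat_ <- .locationCategory(cd$locations)
    keep <- cd$group == "trauma" & !is.na(cat_)
    lc <- factor(cat_[keep])
    lc <- stats::relevel(lc, ref = "peripheral_only")
    X <- stats::model.matrix(~lc)
    colnames(X) <- c("(Intercept)", paste0("location", levels(lc)[-1]))
    focal <- colnames(X)[-1]
  } else {                                    # covid
    keep <- cd$group == "trauma" & cd$covid %in% c("positive", "negative")
    X <- cbind("(Intercept)" = 1,
               covidpositive = as.numeric(cd$covid[keep] == "positive"))
    focal <- "covidpositive"
  }
  vals <- panelValue(processed)[, keep, drop = FALSE]
  cens <- SummarizedExperiment::assay(processed, "censored")[, keep,
                                                             drop = FALSE]
  fits <- list()
  rows <- list()
  for (a in rownames(vals)) {
    y <- vals[a, ]; cn <- cens[a, ]
    ok <- !is.na(y) & !is.na(cn)
    if (!any(ok) || all(cn[ok])) {
      message("skipping '", a, "': no uncensored observations")
      next
    }
    fit <- tryCatch(tobitFit(y[ok], cn[ok], X[ok, , drop = FALSE],
                             analyte = a),
                    error = function(e) {
                      message("skipping '", a, "': ", conditionMessage(e))
                      NULL
                    })
    if (is.null(fit)) next
    fits[[a]] <- fit
    i <- match(focal, fit@terms)
    pc <- percentChange(fit@beta[i], fit@se[i])
    rows[[a]] <- data.frame(
      analyte = a, model = model, term = focal, beta = fit@beta[i],
      se = fit@se[i], sigma = fit@sigma, n = fit@nObs,
      n_censored = fit@nCensored, converged = fit@converged,
      percent_change = pc$point, ci_lo = pc$lo, ci_hi = pc$hi,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "fits") <- fits
  out
}

#' Directional false-discovery-rate annotation
#'
#' For each coefficient, computes one-sided p-values from the Wald z
#' statistic in each direction (positive association, negative
#' association) and adjusts for multiplicity separately within the
#' positive-direction family and the negative-direction family (one
#' family per term, across analytes).  A coefficient is flagged
#' significant when its smaller directional q-value falls below `alpha`,
#' with the direction of the winning family.  Each directional family's
#' FDR is controlled at `alpha`.
#'
#' @param results data.frame from [fitPanel()] (needs `beta`, `se`, and
#'   optionally `term` to define families).
#' @param alpha directional FDR level (default 0.01).
#' @param method `"bh"` (Benjamini-Hochberg, default) or `"storey"` (BH
#'   scaled by the Storey `pi0` estimate at `lambda = 0.5`).
#' @return `results` with columns `p_pos`, `p_neg`, `q_pos`, `q_neg`,
#'   `significant`, `direction` appended.
#' @export
directionalFdr <- function(results, alpha = 0.01, method = c("bh", "storey")) {
  method <- match.arg(method)
  stopifnot(nrow(results) >= 1)
  z <- results$beta / results$se
  results$p_pos <- stats::pnorm(z, lower.tail = FALSE)
  results$p_neg <- stats::pnorm(z)
  fam <- if ("term" %in% names(results)) results$term else
    rep("all", nrow(results))
  adj <- function(p) {
    q <- stats::p.adjust(p, method = "BH")
    if (method == "storey") {
      pi0 <- min(1, mean(p > 0.5) / 0.5)
      q <- pmin(1, q * pi0)
    }
    q
  }
  results$q_pos <- stats::ave(results$p_pos, fam, FUN = adj)
  results$q_neg <- stats::ave(results$p_neg, fam, FUN = adj)
  qmin <- pmin(results$q_pos, results$q_neg)
  ## non-finite Wald statistics (e.g. one arm fully censored) can never
  ## support a directional claim
  results$significant <- !is.na(qmin) & qmin < alpha
  results$direction <- ifelse(!results$significant, NA_character_,
                              ifelse(results$q_pos <= results$q_neg,
                                     "positive", "negative"))
  results
}

#' Below-LOD prevalence comparison between trauma and control
#'
#' For each analyte, tabulates below-LOD vs detected (within or above
#' LOD; missing cells excluded) against trauma vs control and tests the
#' association with Fisher's exact conditional test.  Differences are
#' reported in percentage points (trauma minus control) with
#' Benjamini-Hochberg q-values across analytes.
#'
#' @param panel a [CytokinePanel] with a `group` column in `colData`.
#' @return data.frame: `analyte`, `frac_below_trauma`,
#'   `frac_below_control`, `difference` (percentage points), `p_value`,
#'   `q_value`.
#' @export
lodPrevalence <- function(panel) {
  st <- panelStatus(panel)
  grp <- subjectInfo(panel)$group
  stopifnot(all(c("trauma", "control") %in% grp))
  rows <- lapply(rownames(st), function(a) {
    s <- st[a, ]
    use <- s != "missing"
    if (!any(use & grp == "trauma") || !any(use & grp == "control")) {
      warning("analyte '", a, "' absent in one group; skipped")
      return(NULL)
    }
    below <- s == "below"
    bt <- sum(below[use & grp == "trauma"])
    nt <- sum(use & grp == "trauma")
    bc <- sum(below[use & grp == "control"])
    nc <- sum(use & grp == "control")
    tab <- matrix(c(bt, nt - bt, bc, nc - bc), 2,
                  dimnames = list(c("below", "detected"),
                                  c("trauma", "control")))
    p <- stats::fisher.test(tab)$p.value
    data.frame(analyte = a, frac_below_trauma = bt / nt,
               frac_below_control = bc / nc,
               difference = (bt / nt - bc / nc) * 100, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}
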