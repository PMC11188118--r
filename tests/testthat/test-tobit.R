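## Independent negative log-likelihood oracle used to audit the fitted
## optimum (kept deliberately separate from the package internals).
refNll <- function(beta, sigma, y, cens, X) {
  xb <- drop(X %*% beta)
  -sum(dnorm((y[!cens] - xb[!cens]) / sigma, log = TRUE) - log(sigma)) -
    sum(pnorm((y[cens] - xb[cens]) / sigma, log.p = TRUE))
}

test_that("with zero censoring the fit reduces to ordinary least squares", {
  set.seed(1)
  n <- 200
  X <- cbind(1, x1 = rnorm(n), x2 = runif(n))
  y <- drop(X %*% c(2, 0.7, -1.2)) + 0.6 * rnorm(n)
  fit <- tobitFit(y, rep(FALSE, n), X)
  ols <- lm.fit(X, y)
  expect_equal(fit@beta, unname(ols$coefficients), tolerance = 1e-7)
  ## Gaussian MLE scale: RSS / n (not the OLS n-p denominator)
  expect_equal(fit@sigma, sqrt(sum(ols$residuals^2) / n),
               tolerance = 1e-6)
  expect_true(fit@converged)
})

test_that("censored fits agree with the survreg oracle", {
  skip_if_not_installed("survival")
  set.seed(2)
  for (rep in 1:3) {
    d <- simTobitData(n = 300, beta1 = 0.5, sigma = 0.7, cens_q = 0.3)
    fit <- tobitFit(d$y, d$cens, d$X)
    sv <- survival::survreg(
      survival::Surv(d$y, !d$cens, type = "left") ~ d$X[, 2],
      dist = "gaussian")
    expect_equal(fit@beta, unname(coef(sv)), tolerance = 1e-5)
    expect_equal(fit@sigma, sv$scale, tolerance = 1e-5)
    expect_equal(fit@loglik, sv$loglik[2], tolerance = 1e-7)
    expect_equal(fit@se,
                 unname(sqrt(diag(vcov(sv))[1:2])), tolerance = 1e-4)
  }
})

test_that("optimum improves on the OLS start and is a local maximum", {
  set.seed(3)
  d <- simTobitData(n = 400, cens_q = 0.4)
  fit <- tobitFit(d$y, d$cens, d$X)
  ols <- lm.fit(d$X, d$y)
  ll_start <- -refNll(ols$coefficients,
                      sqrt(sum(ols$residuals^2) / length(d$y)),
                      d$y, d$cens, d$X)
  expect_gte(fit@loglik, ll_start)
  ## nudging any parameter lowers the likelihood
  for (j in 1:2) {
    b <- fit@beta; b[j] <- b[j] + 0.01
    expect_lt(-refNll(b, fit@sigma, d$y, d$cens, d$X), fit@loglik)
  }
  expect_lt(-refNll(fit@beta, fit@sigma * 1.02, d$y, d$cens, d$X),
            fit@loglik)
})

test_that("degenerate designs are rejected", {
  set.seed(4)
  y <- rnorm(30)
  expect_error(tobitFit(y, rep(TRUE, 30), matrix(1, 30, 1)), "censored")
  expect_error(tobitFit(y, rep(FALSE, 30), matrix(1, 30, 2)),
               "rank deficient")
})

test_that("percent change implements (e^b - 1) * 100 with ordered CI", {
  expect_equal(percentChange(0, 0.1)$point, 0)
  expect_equal(percentChange(log(2), 0.1)$point, 100)
  expect_equal(percentChange(log(0.022), 0.1)$point, -97.8)
  pc <- percentChange(c(-1, 0, 1), c(0.2, 0.2, 0.2))
  expect_true(all(pc$lo < pc$point & pc$point < pc$hi))
  ## order-preserving in beta
  expect_true(all(diff(pc$point) > 0))
  ## reproduces a CI on the percent scale: exp(b +- z se)
  expect_equal(pc$hi[2], (exp(qnorm(0.975) * 0.2) - 1) * 100)
})

test_that("directional q-values match a brute-force step-up oracle", {
  ## independent Benjamini-Hochberg implementation by enumeration
  bhEnum <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {    # step-up: q_i = min_{j >= i} m p_(j) / j
      q[o[i]] <- min(sapply(i:m, function(j) m * p[o[j]] / j))
    }
    pmin(q, 1)
  }
  set.seed(5)
  for (rep in 1:10) {
    k <- 10
    res <- data.frame(beta = rnorm(k, sd = 2), se = runif(k, 0.5, 2),
                      term = "grouptrauma")
    out <- directionalFdr(res, alpha = 0.01)
    z <- res$beta / res$se
    expect_equal(out$q_pos, bhEnum(pnorm(z, lower.tail = FALSE)))
    expect_equal(out$q_neg, bhEnum(pnorm(z)))
    expect_equal(out$significant,
                 pmin(out$q_pos, out$q_neg) < 0.01)
  }
  ## m = 1 identity: one-sided p 0.004 -> q 0.004, significant
  one <- directionalFdr(data.frame(beta = qnorm(1 - 0.004), se = 1))
  expect_equal(one$q_pos, 0.004, tolerance = 1e-10)
  expect_true(one$significant)
  expect_equal(one$direction, "positive")
  ## null z = 0 everywhere: both directional p = 0.5, no discoveries
  none <- directionalFdr(data.frame(beta = rep(0, 20), se = rep(1, 20)))
  expect_equal(sum(none$significant), 0)
})

test_that("below-LOD prevalence uses the exact conditional test", {
  ## 2x2 oracle: hypergeometric enumeration of the two-sided Fisher p
  fisherEnum <- function(a, b, c_, d) {
    m <- a + b; n <- c_ + d; k <- a + c_
    xs <- max(0, k - n):min(k, m)
    pr <- dhyper(xs, m, n, k)
    sum(pr[pr <= dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  conc <- rbind(A = c(rep(0.1, 8), rep(10, 2), 0.1, rep(10, 9)))
  colnames(conc) <- paste0("s", 1:20)
  lods <- data.frame(analyte = "A", lower_lod = 1, upper_lod = 100,
                     curve_min = 0.5)
  clinical <- data.frame(id = paste0("s", 1:20),
                         group = rep(c("trauma", "control"), each = 10),
                         stringsAsFactors = FALSE)
  p <- CytokinePanel(conc, lods, clinical)
  out <- lodPrevalence(p)
  expect_equal(out$frac_below_trauma, 0.8)
  expect_equal(out$frac_below_control, 0.1)
  expect_equal(out$difference, 70)
  expect_equal(out$p_value, fisherEnum(8, 2, 1, 9), tolerance = 1e-9)
  ## identical 50/50 proportions: difference 0, p = 1
  conc2 <- rbind(A = rep(c(0.1, 10), 10))
  colnames(conc2) <- paste0("s", 1:20)
  out2 <- lodPrevalence(CytokinePanel(conc2, lods, clinical))
  expect_equal(out2$difference, 0)
  expect_equal(out2$p_value, 1)
})

test_that("large censoring gaps are flagged as significant", {
  ## IL-2-like analyte: wide below-LOD difference between groups
  set.seed(6)
  cfg <- cohortConfig(nTrauma = 400, nControl = 50, mortalityRate = 0,
                      analytes = testAnalytes("IL2L", sigma = 1,
                                              delta_trauma = log(0.05),
                                              lod_q = 0.45),
                      outcomeModel = "marginal", seed = 6)
  sim <- simulateCohort(cfg)
  out <- lodPrevalence(sim$panel)
  expect_gt(out$difference, 30)
  expect_lt(out$q_value, 0.001)
})

test_that("panel fits expose focal terms and centred age", {
  sim <- simulateCohort(cohortConfig(
    nTrauma = 300, nControl = 60, mortalityRate = 0,
    analytes = testAnalytes(c("UP", "NULL0"), sigma = 0.4,
                            delta_trauma = c(0.5, 0), lod_q = 0.1),
    outcomeModel = "marginal", seed = 8))
  proc <- applyLodRules(sim$panel, "analysis")
  res <- directionalFdr(fitPanel(proc, "univariable_group"))
  up <- res[res$analyte == "UP", ]
  expect_true(up$significant && up$direction == "positive")
  expect_equal(up$percent_change, (exp(0.5) - 1) * 100, tolerance = 0.25)
  nul <- res[res$analyte == "NULL0", ]
  expect_true(nul$ci_lo < 0 && nul$ci_hi > 0)
  ## age model reports the age slope as focal term
  resa <- fitPanel(proc, "age_adjusted")
  expect_true(all(resa$term == "age"))
})

test_that("categorical trauma-level fits recover a graded effect", {
  ## build a panel directly with a monotone level effect (ref level 4)
  set.seed(9)
  n <- 400
  lev <- sample(1:4, n, replace = TRUE)
  y <- exp(3 + c(0.9, 0.6, 0.3, 0)[lev] + 0.5 * rnorm(n))
  conc <- rbind(X = y)
  colnames(conc) <- paste0("s", seq_len(n))
  lods <- data.frame(analyte = "X", lower_lod = exp(1.8),
                     upper_lod = exp(7), curve_min = 1)
  clinical <- data.frame(id = colnames(conc), group = "trauma",
                         age = 40, sex = "male", trauma_level = lev,
                         outcome = "discharged_home", mechanism = "fall",
                         locations = "torso", wound_type = "bone",
                         covid = "untested", stringsAsFactors = FALSE)
  proc <- applyLodRules(CytokinePanel(conc, lods, clinical), "analysis")
  res <- fitPanel(proc, "trauma_level")
  expect_equal(res$term, c("level1", "level2", "level3"))
  expect_true(all(diff(res$beta) < 0))           # monotone 1 > 2 > 3
  expect_equal(res$beta, c(0.9, 0.6, 0.3), tolerance = 0.35)
})
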