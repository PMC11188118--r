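## Compact outcome-linked cohort for score tests: three linked analytes
## plus noise, marginal outcome model (exact configured shifts).
viperCohort <- function(seed = 60, nT = 500, mortality = 0.1) {
  an <- testAnalytes(c("P1", "P2", "P3", "N1", "N2"), sigma = 0.6,
                     delta_deceased = c(1.2, 1.0, -1.2, 0, 0),
                     lod_q = 0.02)
  simulateCohort(cohortConfig(nT, 30, mortality, an, "marginal",
                              seed = seed))
}

test_that("logistic fit recovers generating coefficients at large n", {
  ## cohort whose deaths come from a known logistic model on log conc
  an <- testAnalytes(c("P1", "P2", "P3"), sigma = 1, lod_q = 0.001)
  cfg <- cohortConfig(4000, 10, 0.2, an, "logistic_on_analytes",
                      logisticCoefficients = c(P1 = 0.9, P2 = -0.7,
                                               P3 = 0.4), seed = 61)
  sim <- simulateCohort(cfg)
  m <- fitViper(sim$panel, c("P1", "P2", "P3"))
  cf <- m@coefficients[c("P1", "P2", "P3")]
  expect_equal(unname(cf), c(0.9, -0.7, 0.4), tolerance = 0.25)
  expect_false(m@trainingMeta$ridge)
})

test_that("custom expressions reduce to single-analyte ranking", {
  sim <- viperCohort()
  m <- fitViper(sim$panel, analytes = "P1", form = "custom_expression",
                expression_text = "log(P1)")
  sc <- viperScore(m, sim$panel)
  cd <- as.data.frame(subjectInfo(sim$panel))
  idx <- cd$outcome %in% c("deceased", "discharged_home")
  dead <- cd$outcome[idx] == "deceased"
  ## identical ROC ranking to the raw analyte concentration
  ratio_conc <- panelValue(applyLodRules(sim$panel, "ratio"))["P1", idx]
  expect_equal(aucRank(sc[idx], dead), aucRank(ratio_conc, dead),
               tolerance = 1e-12)
  ## an all-zero expression scores constant -> chance AUC
  m0 <- fitViper(sim$panel, analytes = "P1", form = "custom_expression",
                 expression_text = "0 * P1")
  expect_equal(aucRank(viperScore(m0, sim$panel)[idx], dead), 0.5)
})

test_that("scores are monotone in positively weighted analytes and batch-consistent", {
  sim <- viperCohort()
  m <- suppressWarnings(fitViper(sim$panel, c("P1", "P2", "P3")))
  expect_gt(unname(m@coefficients["P1"]), 0)
  expect_lt(unname(m@coefficients["P3"]), 0)
  sc <- viperScore(m, sim$panel)
  ## raising a positively weighted analyte strictly increases the score
  ## (rebuild the panel so statuses re-derive for the doubled values)
  conc2 <- panelConc(sim$panel)
  conc2["P1", ] <- conc2["P1", ] * 2
  lods <- data.frame(analyte = rownames(conc2),
                     as.data.frame(analyteInfo(sim$panel)))
  p2 <- CytokinePanel(conc2, lods,
                      cbind(id = colnames(conc2),
                            as.data.frame(subjectInfo(sim$panel))))
  sc2 <- viperScore(m, p2)
  det <- panelStatus(sim$panel)["P1", ] == "within" &
    panelStatus(p2)["P1", ] == "within"
  expect_true(all(sc2[det] > sc[det]))
  ## batch scoring equals per-subject scoring
  one <- viperScore(m, sim$panel[, 7])
  expect_equal(unname(one), unname(sc[7]), tolerance = 1e-12)
})

test_that("stratified evaluation fills strata correctly and detects signal", {
  sim <- viperCohort(seed = 62, nT = 600, mortality = 0.08)
  ev <- evaluateByLevel(sim$panel, c("P1", "P2", "P3"), seed = 62)
  expect_true(ev$cross_validated)
  expect_true(all(c("all", "level1", "level4") %in% names(ev$roc)))
  expect_gt(ev$roc$all@auc, 0.75)
  ## stratum filter selects exactly the level-4 deceased/discharged set
  cd <- as.data.frame(subjectInfo(sim$panel))
  idx <- which(cd$outcome %in% c("deceased", "discharged_home"))
  n4 <- sum(cd$trauma_level[idx] == 4, na.rm = TRUE)
  expect_equal(ev$roc$level4@nPos + ev$roc$level4@nNeg, n4)
  ## permuted outcomes give chance AUC
  perm <- sim$panel
  set.seed(63)
  SummarizedExperiment::colData(perm)$outcome <-
    sample(cd$outcome)
  evp <- evaluateByLevel(perm, c("P1", "P2", "P3"), seed = 63)
  expect_equal(evp$roc$all@auc, 0.5, tolerance = 0.07)
})

test_that("resubstitution is optimistic relative to cross-validation", {
  diffs <- sapply(1:4, function(s) {
    sim <- viperCohort(seed = 70 + s, nT = 300, mortality = 0.07)
    ## small fixtures can quasi-separate; the ridge fallback warns
    cv <- suppressWarnings(
      evaluateByLevel(sim$panel, c("P1", "P2", "P3"), seed = s))
    rs <- suppressWarnings(
      evaluateByLevel(sim$panel, c("P1", "P2", "P3"), seed = s,
                      resubstitution = TRUE))
    rs$roc$all@auc - cv$roc$all@auc
  })
  expect_gte(mean(diffs), -0.01)     # optimism non-negative on average
})

test_that("derivation degrades gracefully with no outcome-linked analytes", {
  an <- testAnalytes(paste0("Z", 1:8), sigma = 0.5, lod_q = 0.05)
  sim <- simulateCohort(cohortConfig(300, 20, 0.08, an, "marginal",
                                     seed = 80))
  expect_warning(
    d <- derivePanel(sim$panel, nIterations = 3, numTrees = 80,
                     permRepeats = 1, seed = 80),
    "intersection smaller")
  expect_lt(length(d$final_panel), 5)
})

test_that("derivation keeps the linked analytes and prunes the weakest", {
  ## five strong linked analytes + one weakly linked: stage 4 must prune
  ## the weak one when all six survive the screens
  an <- testAnalytes(c("S1", "S2", "S3", "S4", "S5", "WEAK"),
                     sigma = 0.6,
                     delta_deceased = c(1.3, 1.2, -1.3, 1.2, -1.2, 0.25),
                     lod_q = 0.02)
  sim <- simulateCohort(cohortConfig(800, 20, 0.06, an, "marginal",
                                     seed = 81))
  d <- suppressWarnings(derivePanel(sim$panel, nIterations = 5,
                                    numTrees = 200, permRepeats = 2,
                                    seed = 81))
  expect_setequal(d$final_panel, c("S1", "S2", "S3", "S4", "S5"))
  expect_false("WEAK" %in% d$final_panel)
})

test_that("pipeline runs end to end, deterministically, writing outputs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- list(synthetic = TRUE, seed = 5, iterations = 3, trees = 80,
              perm_repeats = 1)
  r1 <- suppressWarnings(runPipeline(c(cfg, outdir = d1)))
  r2 <- suppressWarnings(runPipeline(c(cfg, outdir = d2)))
  for (f in c("tobit_group.csv", "lod_prevalence.csv", "ratio_pairs.csv",
              "importance.csv", "summary.json", "run_log.txt",
              "truth_analytes.csv"))
    expect_true(file.exists(file.path(d1, f)))
  expect_identical(readLines(file.path(d1, "summary.json")),
                   readLines(file.path(d2, "summary.json")))
  expect_identical(r1$derivation$final_panel, r2$derivation$final_panel)
  ## stage-named error with the offending path
  expect_error(
    runPipeline(list(synthetic = FALSE, panel = "nope.csv",
                     lods = "nope2.csv", clinical = "nope3.csv",
                     outdir = withr::local_tempdir())),
    "stage 'input'.*nope")
})
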