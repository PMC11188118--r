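## Small panel with a known outcome split for ratio tests:
## 3 deceased + 3 discharged subjects, 3 analytes, no censoring.
ratioToy <- function() {
  conc <- rbind(N = c(10, 20, 30, 5, 10, 15),
                D = c(5, 5, 5, 5, 5, 5),
                E = c(2, 4, 8, 16, 32, 64))
  colnames(conc) <- paste0("s", 1:6)
  lods <- data.frame(analyte = c("N", "D", "E"), lower_lod = 0.1,
                     upper_lod = 1000, curve_min = 0.05)
  clinical <- data.frame(
    id = colnames(conc), group = "trauma", age = 40, sex = "male",
    trauma_level = 4L,
    outcome = rep(c("deceased", "discharged_home"), each = 3),
    mechanism = "fall", locations = "torso", wound_type = "bone",
    covid = "untested", stringsAsFactors = FALSE)
  applyLodRules(CytokinePanel(conc, lods, clinical), "ratio")
}

test_that("per-subject ratios follow the substitution rules", {
  rp <- ratioToy()
  r <- computeRatio(rp, "N", "D")
  expect_equal(unname(r), c(2, 4, 6, 1, 2, 3))
  ## reciprocal identity for every subject
  expect_equal(computeRatio(rp, "D", "N"), 1 / r, tolerance = 1e-12)
  expect_error(computeRatio(rp, "N", "Zed"), "not in panel")
})

test_that("both-censored cells divide to their substitute ratio", {
  conc <- rbind(A = c(0.05, 8), B = c(0.01, 4))
  colnames(conc) <- c("s1", "s2")
  lods <- data.frame(analyte = c("A", "B"), lower_lod = c(1, 1),
                     upper_lod = c(100, 100), curve_min = c(0.5, 0.5))
  rp <- applyLodRules(CytokinePanel(conc, lods), "ratio")
  ## s1: both analytes below LOD; both substituted with
  ## min(curve_min = 0.5, lowest detected) = 0.5 -> ratio exactly 1
  expect_equal(unname(computeRatio(rp, "A", "B")["s1"]), 1)
})

test_that("fold-change matrix matches hand-enumerated medians", {
  rp <- ratioToy()
  ft <- foldChangeMatrix(rp)
  ## N:D ratios -- deceased (2,4,6) median 4; discharged (1,2,3)
  ## median 2 -> fold 2
  expect_equal(ft$fold["N", "D"], 2)
  expect_equal(ft$fold["D", "N"], 1 / 2, tolerance = 1e-12)
  ## N:E deceased (5, 5, 3.75) median 5; discharged (0.3125, 0.3125,
  ## 0.234375) median 0.3125 -> fold 16
  expect_equal(ft$fold["N", "E"], 16)
  ## antisymmetry on the log scale over every pair
  lf <- log(ft$fold)
  expect_equal(unname(lf), unname(-t(lf)), tolerance = 1e-12)
  expect_true(all(is.na(diag(ft$fold))))
  ## k(k-1) ordered pairs in the tidy table
  expect_equal(nrow(ft$pairs), 3 * 2)
  expect_equal(ft$pairs$rank, seq_len(6))
  expect_equal(ft$n_deceased, 3)
  expect_equal(ft$n_discharged, 3)
})

test_that("identical outcome groups give unit folds", {
  ## both outcome groups observe identical concentration multisets
  conc <- rbind(A = rep(c(3, 7, 11, 5), 2), B = rep(c(2, 9, 4, 6), 2))
  colnames(conc) <- paste0("s", 1:8)
  lods <- data.frame(analyte = c("A", "B"), lower_lod = 0.1,
                     upper_lod = 100, curve_min = 0.05)
  clinical <- data.frame(
    id = colnames(conc), group = "trauma",
    outcome = rep(c("deceased", "discharged_home"), each = 4),
    trauma_level = 4L, stringsAsFactors = FALSE)
  rp <- applyLodRules(CytokinePanel(conc, lods, clinical), "ratio")
  ft <- foldChangeMatrix(rp)
  expect_equal(ft$fold["A", "B"], 1)
  expect_equal(ft$fold["B", "A"], 1)
})

test_that("geometric-mean summary is available and antisymmetric", {
  rp <- ratioToy()
  ft <- foldChangeMatrix(rp, summary = "geometric_mean")
  ## N:D deceased gm = (2*4*6)^(1/3); discharged gm = (1*2*3)^(1/3)
  expect_equal(ft$fold["N", "D"], (48 / 6)^(1 / 3))
  lf <- log(ft$fold)
  expect_equal(unname(lf), unname(-t(lf)), tolerance = 1e-12)
})

test_that("ratio predictor ROC behaves at the null and the oracle", {
  ## constant ratio -> AUC exactly 0.5
  conc <- rbind(A = rep(6, 40), B = rep(3, 40))
  colnames(conc) <- paste0("s", 1:40)
  lods <- data.frame(analyte = c("A", "B"), lower_lod = 0.1,
                     upper_lod = 100, curve_min = 0.05)
  clinical <- data.frame(
    id = colnames(conc), group = "trauma", trauma_level = 4L,
    outcome = rep(c("deceased", "discharged_home"), c(5, 35)),
    stringsAsFactors = FALSE)
  rp <- applyLodRules(CytokinePanel(conc, lods, clinical), "ratio")
  r <- ratioPredictorEval(rp, "A", "B", level = 4)
  expect_equal(r@auc, 0.5)
  ## stratum filtering errors when a class empties
  expect_error(ratioPredictorEval(rp, "A", "B", level = 1), "stratum")
})

test_that("opposed effects reproduce the binormal log-ratio AUC", {
  ## marginal outcome model, no censoring: log ratio UP/DOWN is normal
  ## in both classes with between-class shift 1.2 - (-0.8) = 2.0 and
  ## class SD sqrt(0.6^2 + 0.7^2); binormal equal-variance AUC =
  ## Phi(shift / sqrt(2 * (0.6^2 + 0.7^2)))
  cfg <- cohortConfig(
    nTrauma = 3000, nControl = 10, mortalityRate = 0.3,
    analytes = testAnalytes(c("UP", "DOWN"), sigma = c(0.6, 0.7),
                            delta_deceased = c(1.2, -0.8)),
    outcomeModel = "marginal", seed = 15)
  sim <- simulateCohort(cfg)
  rp <- applyLodRules(sim$panel, "ratio")
  r <- ratioPredictorEval(rp, "UP", "DOWN")
  theory <- pnorm(2.0 / sqrt(2 * (0.6^2 + 0.7^2)))
  expect_equal(r@auc, theory, tolerance = 0.02)
  expect_false(r@flipped)
  ## permuting outcome labels collapses the AUC to chance
  cd <- as.data.frame(subjectInfo(sim$panel))
  set.seed(16)
  perm <- sim$panel
  SummarizedExperiment::colData(perm)$outcome <- sample(cd$outcome)
  rperm <- ratioPredictorEval(applyLodRules(perm, "ratio"), "UP", "DOWN")
  expect_equal(rperm@auc, 0.5, tolerance = 0.05)
})
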