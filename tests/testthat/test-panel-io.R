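test_that("status derivation and reading handle all cell kinds", {
  p <- toyPanel()
  st <- panelStatus(p)
  expect_equal(st["A", ], c(s1 = "within", s2 = "below", s3 = "above",
                            s4 = "within"))
  expect_equal(st["B", ], c(s1 = "within", s2 = "within", s3 = "missing",
                            s4 = "below"))
  ## round-trip through the on-disk formats reproduces values and status
  d <- withr::local_tempdir()
  writePanel(p, file.path(d, "panel.csv"), file.path(d, "lods.csv"),
             file.path(d, "clinical.csv"))
  p2 <- readPanel(file.path(d, "panel.csv"), file.path(d, "lods.csv"),
                  file.path(d, "clinical.csv"))
  expect_equal(panelConc(p2), panelConc(p))
  expect_equal(panelStatus(p2), panelStatus(p))
  expect_equal(subjectInfo(p2)$outcome, subjectInfo(p)$outcome)
})

test_that("sentinel '<LOD' cells map to status below without a value", {
  d <- withr::local_tempdir()
  writeLines(c("id,A,B", "s1,10,<LOD", "s2,,20"),
             file.path(d, "panel.csv"))
  writeLines(c("analyte,lower_lod,upper_lod,curve_min",
               "A,1,100,0.8", "B,5,500,4"), file.path(d, "lods.csv"))
  p <- readPanel(file.path(d, "panel.csv"), file.path(d, "lods.csv"))
  expect_equal(panelStatus(p)["B", "s1"], "below")
  expect_true(is.na(panelConc(p)["B", "s1"]))
  expect_equal(panelStatus(p)["A", "s2"], "missing")
})

test_that("schema violations raise named errors", {
  d <- withr::local_tempdir()
  writeLines(c("id,A,Mystery", "s1,10,3"), file.path(d, "panel.csv"))
  writeLines(c("analyte,lower_lod,upper_lod,curve_min", "A,1,100,0.8"),
             file.path(d, "lods.csv"))
  expect_error(readPanel(file.path(d, "panel.csv"),
                         file.path(d, "lods.csv")), "Mystery")
  writeLines(c("id,A", "s1,10", "s1,20"), file.path(d, "dup.csv"))
  writeLines(c("analyte,lower_lod,upper_lod,curve_min", "A,1,100,0.8"),
             file.path(d, "lods.csv"))
  expect_error(readPanel(file.path(d, "dup.csv"),
                         file.path(d, "lods.csv")), "duplicate")
  expect_error(readPanel(file.path(d, "absent.csv"),
                         file.path(d, "lods.csv")), "not found")
})

test_that("LOD rules: above-LOD replacement and per-mode below handling", {
  p <- toyPanel()
  ## analysis: above cell at upper_lod 100 -> value 110 on conc scale
  an <- applyLodRules(p, "analysis")
  expect_equal(panelValue(an)["A", "s3"], log(110))
  ## below cells censored at log(lower_lod)
  expect_equal(panelValue(an)["A", "s2"], log(1))
  cens <- SummarizedExperiment::assay(an, "censored")
  expect_identical(sum(cens, na.rm = TRUE),
                   sum(panelStatus(p) == "below"))
  expect_true(is.na(panelValue(an)["B", "s3"]))   # missing stays NA
  ## display: below -> 0
  di <- applyLodRules(p, "display")
  expect_equal(panelValue(di)["A", "s2"], 0)
  expect_equal(panelValue(di)["A", "s3"], log(110))
  ## ratio: min(curve_min, lowest detected); A lowest detected 10 vs
  ## curve_min 0.8 -> 0.8; B lowest detected 30 vs curve_min 4 -> 4
  ra <- applyLodRules(p, "ratio")
  expect_equal(panelValue(ra)["A", "s2"], 0.8)
  expect_equal(panelValue(ra)["B", "s4"], 4)
  expect_equal(panelValue(ra)["A", "s3"], 110)
})

test_that("ratio substitution prefers the lowest detected sample", {
  conc <- rbind(A = c(0.5, 0.4, 2))      # below, below, within
  colnames(conc) <- paste0("s", 1:3)
  lods <- data.frame(analyte = "A", lower_lod = 1, upper_lod = 100,
                     curve_min = 3)      # curve minimum above detected
  p <- CytokinePanel(conc, lods)
  expect_equal(panelValue(applyLodRules(p, "ratio"))["A", "s1"], 2)
  ## no detected value and no curve_min -> no substitution value
  conc2 <- rbind(A = c(0.5, 0.4))
  colnames(conc2) <- paste0("s", 1:2)
  lods2 <- data.frame(analyte = "A", lower_lod = 1, upper_lod = 100,
                      curve_min = NA_real_)
  p2 <- CytokinePanel(conc2, lods2)
  expect_error(applyLodRules(p2, "ratio"), "no substitution value")
})

test_that("applyLodRules is idempotent in every mode", {
  p <- toyPanel()
  for (mode in c("analysis", "display", "ratio")) {
    once <- applyLodRules(p, mode)
    twice <- applyLodRules(once, mode)
    expect_equal(panelValue(twice), panelValue(once))
    expect_equal(panelStatus(twice), panelStatus(once))
  }
})

test_that("within-marker normalization maps min to 0 and max to 100", {
  expect_equal(normalizeWithinMarker(c(1, 2, 3)), c(0, 50, 100))
  expect_equal(normalizeWithinMarker(c(5, 5, 10)), c(0, 0, 100))
  expect_warning(z <- normalizeWithinMarker(c(7, 7, 7)), "constant")
  expect_equal(z, c(0, 0, 0))
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(sample(3:30, 1)) * 10^sample(-2:2, 1)
    y <- normalizeWithinMarker(x)
    expect_equal(min(y), 0)
    expect_equal(max(y), 100)
    expect_equal(order(x), order(y))     # affine: order preserved
  }
  ## matrix form normalizes each analyte (row) independently
  m <- normalizeWithinMarker(rbind(a = c(1, 2, 3), b = c(10, 0, 5)))
  expect_equal(m["a", ], c(0, 50, 100))
  expect_equal(m["b", ], c(100, 0, 50))
})

test_that("validity catches malformed panels", {
  conc <- rbind(A = c(10, 50)); colnames(conc) <- c("s1", "s2")
  lods <- data.frame(analyte = "A", lower_lod = 1, upper_lod = 100,
                     curve_min = 0.8)
  expect_error(CytokinePanel(conc,
                             transform(lods, lower_lod = 200)),
               "lower_lod < upper_lod")
  bad_status <- matrix(c("within", "nonsense"), 1,
                       dimnames = list("A", c("s1", "s2")))
  expect_error(CytokinePanel(conc, lods, status = bad_status),
               "unknown status")
})
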