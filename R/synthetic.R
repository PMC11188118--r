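#' CohortConfig: parameters of a synthetic trauma cohort
#'
#' Describes the statistical world a synthetic cohort is drawn from: group
#' sizes, in-hospital mortality, one row of distributional parameters per
#' analyte, and the outcome-generating model.
#'
#' @slot nTrauma,nControl group sizes.
#' @slot mortalityRate probability a trauma patient dies in hospital.
#' @slot analytes data.frame, one row per analyte, with columns `name`,
#'   `mu_control` (control-group mean natural-log concentration, log pg/mL),
#'   `sigma` (log-scale SD), `delta_trauma` (additive log shift in trauma),
#'   `delta_deceased` (additive log shift in deceased trauma subjects, used
#'   by the `marginal` outcome model), `age_slope` (log shift per
#'   mean-centered year), `sex_effect` (log shift for female),
#'   `sex_trauma_interaction` (additional female shift within trauma),
#'   `lower_lod`, `upper_lod`, `curve_min` (pg/mL).
#' @slot outcomeModel `"marginal"` (death drawn independently, analyte
#'   shifts applied via `delta_deceased`) or `"logistic_on_analytes"`
#'   (death drawn from a logistic model on latent log concentrations with
#'   the intercept solved numerically to hit `mortalityRate`).
#' @slot logisticCoefficients named per-analyte weights for the logistic
#'   outcome model (log-concentration units).
#' @slot latentFactorSd SD of an optional shared latent factor added to
#'   every analyte (inter-analyte correlation); 0 disables it (default).
#' @slot seed integer master seed; all randomness flows from it.
#' @export
setClass("CohortConfig",
         representation(nTrauma = "integer", nControl = "integer",
                        mortalityRate = "numeric", analytes = "data.frame",
                        outcomeModel = "character",
                        logisticCoefficients = "numeric",
                        latentFactorSd = "numeric", seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@mortalityRate < 0 || object@mortalityRate > 1)
    msg <- c(msg, "mortalityRate must be in [0, 1]")
  if (object@nControl < 2L) msg <- c(msg, "nControl must be >= 2")
  if (object@nTrauma < 1L) msg <- c(msg, "nTrauma must be >= 1")
  need <- c("name", "mu_control", "sigma", "delta_trauma", "delta_deceased",
            "age_slope", "sex_effect", "sex_trauma_interaction",
            "lower_lod", "upper_lod", "curve_min")
  miss <- setdiff(need, names(object@analytes))
  if (length(miss))
    msg <- c(msg, paste0("analytes table missing column(s): ",
                         paste(miss, collapse = ", ")))
  else {
    if (any(object@analytes$sigma <= 0)) msg <- c(msg, "sigma must be > 0")
    if (anyDuplicated(object@analytes$name))
      msg <- c(msg, "duplicate analyte names")
  }
  if (!object@outcomeModel %in% c("marginal", "logistic_on_analytes"))
    msg <- c(msg, "unknown outcomeModel")
  if (object@outcomeModel == "logistic_on_analytes") {
    if (!length(object@logisticCoefficients))
      msg <- c(msg, "logistic_on_analytes requires logisticCoefficients")
    else if (!length(miss) &&
             !all(names(object@logisticCoefficients) %in%
                  object@analytes$name))
      msg <- c(msg, "logisticCoefficients name(s) not in analyte table")
  }
  if (length(msg)) msg else TRUE
})

#' Build a cohort configuration
#'
#' @param nTrauma,nControl group sizes.
#' @param mortalityRate in-hospital death probability for trauma patients.
#' @param analytes per-analyte parameter table; see [CohortConfig-class].
#' @param outcomeModel `"logistic_on_analytes"` (default) or `"marginal"`.
#' @param logisticCoefficients named per-analyte logistic weights.
#' @param latentFactorSd shared latent factor SD (0 = independent analytes).
#' @param seed integer master seed.
#' @return a validated [CohortConfig-class] object.
#' @export
cohortConfig <- function(nTrauma, nControl, mortalityRate, analytes,
                         outcomeModel = c("logistic_on_analytes", "marginal"),
                         logisticCoefficients = numeric(),
                         latentFactorSd = 0, seed = 1L) {
  outcomeModel <- match.arg(outcomeModel)
  methods::new("CohortConfig", nTrauma = as.integer(nTrauma),
               nControl = as.integer(nControl),
               mortalityRate = as.numeric(mortalityRate),
               analytes = as.data.frame(analytes),
               outcomeModel = outcomeModel,
               logisticCoefficients = logisticCoefficients,
               latentFactorSd = as.numeric(latentFactorSd),
               seed = as.integer(seed))
}

## Fixed 59-analyte parameter table emulating the study panel:
## 9 trauma-up analytes (largest increase 23.1%, smallest 1.46%),
## 23 trauma-down (smallest decrease 29.1%, largest 97.8%), 27 null;
## five outcome-linked analytes (IL-6, VEGF-A, IL-10 up in deceased;
## IL-29, IL-21 up in survivors), one sex-flip analyte (IL-8), two
## age-linked analytes (YKL-40 up, Gro-a down with age); IL-10, IL-2,
## IL-5, IL-23 and IFNb heavily (>75%) censored in at least one group.
.paperlikeAnalyteTable <- function() {
  up <- data.frame(
    name  = c("IL-10", "MIF", "IL-29", "TRAIL", "IL-23", "IL-16", "IL-6",
              "IL-1Ra", "MIP-5"),
    delta = log(c(1.231, 1.18, 1.20, 1.12, 1.10, 1.08, 1.18, 1.12, 1.0146)),
    sigma = c(0.9, 0.30, 1.0, 0.40, 0.50, 0.35, 1.0, 0.40, 0.30),
    role  = "up", stringsAsFactors = FALSE)
  down <- data.frame(
    name  = c("MCP-4", "IP-10", "MDC", "FLT3L", "Eotaxin-3", "CTACK",
              "TARC", "MCP-1", "Eotaxin", "IL-3", "TPO", "MIP-1b",
              "ENA-78", "MIP-3b", "I-309", "IL-21", "IL-12/IL-23p40",
              "IL-17E/IL-25", "MIP-1a", "VEGF-A", "IL-7", "IL-8", "IL-2"),
    delta = log(c(0.709, 0.65, 0.60, 0.55, 0.50, 0.45, 0.42, 0.40, 0.38,
                  0.35, 0.33, 0.30, 0.28, 0.26, 0.24, 0.30, 0.20, 0.18,
                  0.15, 0.50, 0.12, 0.30, 0.022)),
    sigma = c(0.6, 0.7, 0.6, 0.8, 0.9, 0.7, 0.8, 0.6, 0.7, 0.9, 0.6, 0.8,
              0.7, 0.9, 0.8, 1.0, 0.7, 0.9, 0.8, 1.0, 0.7, 0.8, 1.2),
    role  = "down", stringsAsFactors = FALSE)
  null <- data.frame(
    name  = c("IFNb", "IFNg", "I-TAC", "IL-4", "IL-5", "IL-9", "IL-13",
              "IL-15", "IL-17A/F", "IL-17F", "IL-22", "IL-31", "IL-33",
              "MIP-3a", "IL-27", "IL-17B", "SDF-1a", "TNFa", "M-CSF",
              "YKL-40", "Gro-a", "IL-2Ra", "MCP-2", "IL-28A", "IL-1b",
              "IL-12p70", "GM-CSF"),
    delta = 0,
    sigma = rep_len(c(0.6, 0.9, 0.7, 1.0, 0.8, 0.5, 1.1), 27),
    role  = "null", stringsAsFactors = FALSE)
  tab <- rbind(up, down, null)
  n <- nrow(tab)                                   # 59
  ## baseline log concentrations spread over ~5-3000 pg/mL; kept above
  ## 1 pg/mL so every log lower LOD is positive and the display-zero
  ## convention for censored cells stays below all detected log values
  tab$mu_control <- seq(log(5), log(3000), length.out = n)
  tab$delta_trauma <- tab$delta
  ## deceased-vs-survivor shifts (marginal outcome model only)
  tab$delta_deceased <- 0
  tab$delta_deceased[tab$name == "IL-6"]   <-  1.4
  tab$delta_deceased[tab$name == "VEGF-A"] <-  1.2
  tab$delta_deceased[tab$name == "IL-10"]  <-  1.3
  tab$delta_deceased[tab$name == "IL-29"]  <- -1.2
  tab$delta_deceased[tab$name == "IL-21"]  <- -1.5
  tab$age_slope <- 0
  tab$age_slope[tab$name == "YKL-40"] <-  0.020
  tab$age_slope[tab$name == "Gro-a"]  <- -0.012
  tab$sex_effect <- 0
  tab$sex_trauma_interaction <- 0
  tab$sex_effect[tab$name == "IL-8"] <- -0.30     # lower in healthy women
  tab$sex_trauma_interaction[tab$name == "IL-8"] <- 0.60  # flips in trauma
  ## lower LOD placed at a control-distribution quantile:
  ## default ~15% of control cells below; heavier for the five
  ## poorly-detected analytes
  zlod <- rep(stats::qnorm(0.15), n)
  zlod[tab$name %in% c("IL-10")] <- stats::qnorm(0.78)
  zlod[tab$name %in% c("IL-2")]  <- stats::qnorm(0.50)
  zlod[tab$name %in% c("IL-5", "IL-23", "IFNb")] <- stats::qnorm(0.80)
  tab$lower_lod <- exp(tab$mu_control + zlod * tab$sigma)
  tab$upper_lod <- exp(tab$mu_control + 3.5 * tab$sigma +
                         pmax(tab$delta_trauma, 0))
  tab$curve_min <- 0.7 * tab$lower_lod
  ## exercise the lowest-detected-sample fallback for two analytes
  tab$curve_min[tab$name %in% c("TNFa", "MCP-2")] <- NA_real_
  tab$delta <- NULL
  rownames(tab) <- NULL
  tab[c("name", "role", "mu_control", "sigma", "delta_trauma",
        "delta_deceased", "age_slope", "sex_effect",
        "sex_trauma_interaction", "lower_lod", "upper_lod", "curve_min")]
}

#' Default study-like cohort configuration
#'
#' Returns the configuration of the package's reference synthetic world:
#' 59 analytes (9 trauma-up, 23 trauma-down, 27 null), 1000 trauma
#' patients and 50 healthy controls, 2.5\% in-hospital mortality, five
#' outcome-linked analytes (IL-6, VEGF-A and IL-10 higher in deceased;
#' IL-29 and IL-21 higher in survivors) driving death through a logistic
#' model on latent log concentrations, one sex-flip analyte (IL-8), two
#' age-linked analytes, and heavy (>75\%) left-censoring for a handful of
#' poorly detected analytes.
#'
#' @param seed integer master seed.
#' @return a [CohortConfig-class].
#' @export
paperlikeConfig <- function(seed = 1L) {
  cohortConfig(nTrauma = 1000L, nControl = 50L, mortalityRate = 0.025,
               analytes = .paperlikeAnalyteTable(),
               outcomeModel = "logistic_on_analytes",
               logisticCoefficients = c("IL-6" = 2.2, "VEGF-A" = 2.2,
                                        "IL-10" = 2.6, "IL-29" = -2.2,
                                        "IL-21" = -2.6),
               seed = seed)
}

## Deterministic per-purpose sub-seeds derived from the master seed.
## Per-analyte draws use their own sub-stream (keyed by analyte index),
## so adding analytes never perturbs earlier ones.
.subSeed <- function(seed, stream, index = 0L) {
  s <- (as.double(seed) * 48271 + stream * 30269 + index * 7919) %%
    2147483647
  as.integer(s)
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort from a [CohortConfig-class]: clinical covariates
#' (age, sex, trauma activation level 1-4, injury mechanism, locations,
#' wound types, SARS-CoV-2 status), latent lognormal analyte
#' concentrations with group/age/sex shifts, a discharge outcome, and
#' per-cell censoring statuses derived from the configured LODs
#' (censoring is applied after covariate shifts, so censoring fractions
#' differ by group).  Identical seeds give bitwise-identical cohorts.
#'
#' @param config a [CohortConfig-class].
#' @return a list with elements
#'   \describe{
#'     \item{panel}{a [CytokinePanel] with clinical covariates in
#'       `colData`.}
#'     \item{truthAnalytes}{the analyte parameter table augmented with
#'       the logistic weight actually used.}
#'     \item{truthSubjects}{per-subject latent death probability and
#'       linear predictor (logistic model), or the marginal rate.}
#'     \item{truthConfig}{seed, group sizes, outcome model and the
#'       numerically solved logistic intercept.}
#'   }
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  methods::validObject(config)
  tab <- config@analytes
  nT <- config@nTrauma; nC <- config@nControl
  n <- nT + nC
  trauma <- c(rep(TRUE, nT), rep(FALSE, nC))
  ids <- c(sprintf("TR%04d", seq_len(nT)), sprintf("HC%04d", seq_len(nC)))

  ## --- covariates -------------------------------------------------------
  set.seed(.subSeed(config@seed, 1L))
  age <- numeric(n)
  age[trauma] <- pmin(round(18 + stats::rgamma(nT, shape = 2, scale = 11)),
                      101)
  age[!trauma] <- round(stats::runif(nC, 21, 65))
  sex <- ifelse(stats::runif(n) < ifelse(trauma, 0.282, 0.5),
                "female", "male")
  trauma_level <- rep(NA_integer_, n)
  trauma_level[trauma] <- sample(1:4, nT, replace = TRUE,
                                 prob = c(0.177, 0.170, 0.163, 0.490))
  mechanism <- rep("unknown", n)
  mechanism[trauma] <- sample(c("fall", "gsw", "mvc", "stab", "other"),
                              nT, replace = TRUE,
                              prob = c(0.211, 0.112, 0.420, 0.050, 0.207))
  loc_ind <- cbind(head_neck = stats::runif(n) < 0.35,
                   torso = stats::runif(n) < 0.40,
                   peripheral = stats::runif(n) < 0.55)
  locations <- apply(loc_ind, 1, function(z)
    paste(colnames(loc_ind)[z], collapse = "|"))
  locations[locations == ""] <- "unknown"
  locations[!trauma] <- ""
  wt_ind <- cbind(internal = stats::runif(n) < 0.35,
                  penetrating = stats::runif(n) < 0.45,
                  bone = stats::runif(n) < 0.58,
                  soft_tissue = stats::runif(n) < 0.50)
  wound_type <- apply(wt_ind, 1, function(z)
    paste(colnames(wt_ind)[z], collapse = "|"))
  wound_type[!trauma] <- ""
  covid <- rep("untested", n)
  tested <- trauma & stats::runif(n) < 0.66
  covid[tested] <- ifelse(stats::runif(sum(tested)) < 0.04,
                          "positive", "negative")

  ## --- latent log concentrations ---------------------------------------
  latent <- if (config@latentFactorSd > 0) {
    set.seed(.subSeed(config@seed, 2L))
    stats::rnorm(n, 0, config@latentFactorSd)
  } else rep(0, n)
  agec <- age - mean(age)
  female <- sex == "female"
  k <- nrow(tab)
  Y <- matrix(NA_real_, k, n, dimnames = list(tab$name, ids))
  for (j in seq_len(k)) {
    set.seed(.subSeed(config@seed, 3L, j))
    mu <- tab$mu_control[j] + tab$delta_trauma[j] * trauma +
      tab$age_slope[j] * agec + tab$sex_effect[j] * female +
      tab$sex_trauma_interaction[j] * (female & trauma)
    Y[j, ] <- mu + latent + tab$sigma[j] * stats::rnorm(n)
  }

  ## --- outcome ----------------------------------------------------------
  set.seed(.subSeed(config@seed, 4L))
  deceased <- rep(FALSE, n)
  lp <- rep(NA_real_, n)
  intercept <- NA_real_
  if (config@outcomeModel == "logistic_on_analytes") {
    w <- config@logisticCoefficients
    idx <- match(names(w), tab$name)
    ## weights act on latent log concentrations centered at the trauma mean
    cen <- tab$mu_control[idx] + tab$delta_trauma[idx]
    eta <- as.vector(crossprod(Y[idx, , drop = FALSE] - cen, w))
    f <- function(a) mean(stats::plogis(a + eta[trauma])) -
      config@mortalityRate
    intercept <- stats::uniroot(f, c(-60, 60), tol = 1e-10)$root
    lp <- intercept + eta
    deceased[trauma] <- stats::runif(nT) < stats::plogis(lp[trauma])
  } else {
    deceased[trauma] <- stats::runif(nT) < config@mortalityRate
    ## deceased shifts re-drawn per analyte sub-stream stay untouched;
    ## shifts are additive on the latent scale
    dd <- tab$delta_deceased
    if (any(dd != 0) && any(deceased))
      Y[, deceased] <- Y[, deceased] + matrix(dd, k, sum(deceased))
  }
  outcome <- rep("unknown", n)
  surv <- trauma & !deceased
  outcome[deceased] <- "deceased"
  outcome[surv] <- sample(c("discharged_home", "other_discharge", "icu",
                            "or_"),
                          sum(surv), replace = TRUE,
                          prob = c(0.565, 0.050, 0.126, 0.259))

  ## --- censor and assemble ---------------------------------------------
  conc <- exp(Y)
  clinical <- data.frame(
    id = ids, group = ifelse(trauma, "trauma", "control"), age = age,
    sex = sex, trauma_level = trauma_level, outcome = outcome,
    mechanism = mechanism, locations = locations, wound_type = wound_type,
    covid = covid, stringsAsFactors = FALSE)
  lods <- data.frame(analyte = tab$name, lower_lod = tab$lower_lod,
                     upper_lod = tab$upper_lod, curve_min = tab$curve_min,
                     stringsAsFactors = FALSE)
  panel <- CytokinePanel(conc, lods, clinical)
  truthAnalytes <- tab
  truthAnalytes$logistic_weight <- 0
  if (config@outcomeModel == "logistic_on_analytes")
    truthAnalytes$logistic_weight[match(names(config@logisticCoefficients),
                                        tab$name)] <-
      config@logisticCoefficients
  truthSubjects <- data.frame(
    id = ids, deceased = deceased,
    linear_predictor = lp,
    p_death = ifelse(trauma,
                     if (config@outcomeModel == "logistic_on_analytes")
                       stats::plogis(lp) else config@mortalityRate,
                     0), stringsAsFactors = FALSE)
  list(panel = panel, truthAnalytes = truthAnalytes,
       truthSubjects = truthSubjects,
       truthConfig = list(seed = config@seed, nTrauma = nT, nControl = nC,
                          mortalityRate = config@mortalityRate,
                          outcomeModel = config@outcomeModel,
                          logisticIntercept = intercept,
                          latentFactorSd = config@latentFactorSd))
}
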