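## Shared fixtures: tiny panels built in code, plus a compact cohort
## configuration helper for simulation-based tests.

## 2-analyte, 4-subject panel exercising every detection status:
## A: s1 within, s2 below (explicit small value), s3 above, s4 within
## B: s1 within, s2 within, s3 missing, s4 below (value)
toyPanel <- function() {
  conc <- rbind(A = c(10, 0.5, 250, 40),
                B = c(80, 30, NA, 2))
  colnames(conc) <- paste0("s", 1:4)
  lods <- data.frame(analyte = c("A", "B"),
                     lower_lod = c(1, 5), upper_lod = c(100, 500),
                     curve_min = c(0.8, 4))
  clinical <- data.frame(
    id = paste0("s", 1:4),
    group = c("trauma", "trauma", "trauma", "control"),
    age = c(30, 45, 60, 35),
    sex = c("female", "male", "male", "female"),
    trauma_level = c(1L, 4L, 4L, NA),
    outcome = c("deceased", "discharged_home", "discharged_home",
                "unknown"),
    mechanism = c("mvc", "fall", "gsw", "unknown"),
    locations = c("torso", "peripheral", "head_neck|torso", ""),
    wound_type = c("bone", "soft_tissue", "internal|bone", ""),
    covid = c("negative", "untested", "positive", "untested"),
    stringsAsFactors = FALSE)
  CytokinePanel(conc, lods, clinical)
}

## Minimal analyte spec table for custom cohort configurations.
testAnalytes <- function(names, mu = 4, sigma = 0.5, delta_trauma = 0,
                         delta_deceased = 0, age_slope = 0, sex_effect = 0,
                         sex_trauma_interaction = 0, lod_q = 0.001,
                         upper_q = 0.9999) {
  k <- length(names)
  rep_k <- function(x) rep_len(x, k)
  mu <- rep_k(mu); sigma <- rep_k(sigma)
  data.frame(name = names, mu_control = mu, sigma = sigma,
             delta_trauma = rep_k(delta_trauma),
             delta_deceased = rep_k(delta_deceased),
             age_slope = rep_k(age_slope), sex_effect = rep_k(sex_effect),
             sex_trauma_interaction = rep_k(sex_trauma_interaction),
             lower_lod = exp(mu + stats::qnorm(rep_k(lod_q)) * sigma),
             upper_lod = exp(mu + stats::qnorm(rep_k(upper_q)) * sigma +
                               pmax(rep_k(delta_trauma), 0) +
                               pmax(rep_k(delta_deceased), 0)),
             curve_min = exp(mu + stats::qnorm(rep_k(lod_q)) * sigma) * 0.7,
             stringsAsFactors = FALSE)
}

## Draw one left-censored regression dataset: two balanced groups, true
## group effect `beta1`, censoring threshold at the `cens_q` quantile of
## the marginal response.
simTobitData <- function(n = 1000, beta0 = 2, beta1 = log(1.231),
                         sigma = 0.8, cens_q = 0.3) {
  g <- rep(c(0, 1), length.out = n)
  y <- beta0 + beta1 * g + sigma * rnorm(n)
  thr <- as.numeric(stats::quantile(y, cens_q))
  cens <- y < thr
  y[cens] <- thr
  list(y = y, cens = cens, X = cbind("(Intercept)" = 1, group = g),
       beta = c(beta0, beta1), sigma = sigma, threshold = thr)
}
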