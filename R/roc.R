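## ROC curves, AUC with DeLong confidence intervals, Wilson score
## intervals and operating-point selection.

.asLabels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(labels == 1)
  }
  ## character: "deceased" is the positive class convention
  if (all(labels %in% c("deceased", "discharged_home")))
    return(labels == "deceased")
  stop("cannot interpret labels; supply logical TRUE = positive")
}

#' Rank-based (Mann-Whitney) AUC
#'
#' The probability that a random positive outscores a random negative,
#' ties counting one half: the Mann-Whitney U statistic divided by
#' `n_pos * n_neg`.  Exactly equals the trapezoidal area of the
#' empirical ROC curve computed by [rocCurve()].
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels logical (TRUE = positive class), 0/1, or
#'   `deceased`/`discharged_home` strings.
#' @return AUC in `[0, 1]`.
#' @export
aucRank <- function(scores, labels) {
  pos <- .asLabels(labels)
  ok <- !is.na(scores) & !is.na(pos)
  scores <- scores[ok]; pos <- pos[ok]
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0 || nN == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
}

## DeLong variance of the AUC via placement values.
.delongVar <- function(scores, pos) {
  x <- scores[pos]; y <- scores[!pos]
  m <- length(x); n <- length(y)
  ## placement of each positive among negatives and vice versa
  v10 <- vapply(x, function(xi) (sum(xi > y) + 0.5 * sum(xi == y)) / n,
                numeric(1))
  v01 <- vapply(y, function(yi) (sum(x > yi) + 0.5 * sum(x == yi)) / m,
                numeric(1))
  stats::var(v10) / m + stats::var(v01) / n
}

#' Empirical ROC curve with AUC confidence interval
#'
#' Computes the empirical ROC over all distinct score thresholds (call
#' positive when `score >= threshold`), the trapezoidal AUC (ties
#' contribute one half; identical to [aucRank()]), and a 95\% AUC CI from
#' the DeLong asymptotic variance.  When either class has fewer than two
#' members, or the DeLong variance is degenerate, a stratified bootstrap
#' CI is used instead.
#'
#' @param scores numeric scores.
#' @param labels positive-class labels (see [aucRank()]).
#' @param orient if `TRUE`, flip the score sign when the raw AUC is below
#'   0.5 so that higher score = higher risk; the flip is recorded in the
#'   result.
#' @param level CI level (default 0.95).
#' @param bootSamples bootstrap replicates for the fallback CI.
#' @return a [RocResult-class].
#' @examples
#' rocCurve(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE))  # AUC 0.75
#' @export
rocCurve <- function(scores, labels, orient = FALSE, level = 0.95,
                     bootSamples = 2000) {
  pos <- .asLabels(labels)
  ok <- !is.na(scores) & !is.na(pos)
  scores <- scores[ok]; pos <- pos[ok]
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0 || nN == 0) stop("both classes must be present")
  flipped <- FALSE
  if (orient && aucRank(scores, pos) < 0.5) {
    scores <- -scores
    flipped <- TRUE
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  ## collapse tied scores: one ROC vertex per distinct threshold
  last <- !duplicated(s, fromLast = TRUE) # last index of each tie group
  tp <- cumsum(p)[last]; fp <- cumsum(!p)[last]
  thresholds <- c(Inf, s[last])
  tpr <- c(0, tp / nP); fpr <- c(0, fp / nN)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  z <- stats::qnorm(1 - (1 - level) / 2)
  v <- if (nP >= 2 && nN >= 2) .delongVar(scores, pos) else NA_real_
  if (is.finite(v) && v > 0) {
    ci <- c(max(0, auc - z * sqrt(v)), min(1, auc + z * sqrt(v)))
  } else {
    ## stratified bootstrap fallback for tiny/degenerate classes
    ip <- which(pos); in_ <- which(!pos)
    bauc <- vapply(seq_len(bootSamples), function(b) {
      i <- c(ip[sample.int(nP, nP, replace = TRUE)],
             in_[sample.int(nN, nN, replace = TRUE)])
      aucRank(scores[i], pos[i])
    }, numeric(1))
    ci <- unname(stats::quantile(bauc, c((1 - level) / 2,
                                         1 - (1 - level) / 2)))
  }
  methods::new("RocResult", thresholds = thresholds, tpr = tpr, fpr = fpr,
               auc = auc, aucCi = ci, nPos = as.integer(nP),
               nNeg = as.integer(nN), flipped = flipped, operating = list())
}

#' Wilson score interval for a binomial proportion
#'
#' The score-test-inverted CI for a proportion; always inside `[0, 1]`
#' and containing the point estimate.  Reproduces the conventional
#' 70.09\% lower bound for a 9/9 sensitivity at 95\%.
#'
#' @param successes,n counts with `0 <= successes <= n`, `n >= 1`.
#' @param level confidence level (default 0.95).
#' @return numeric `c(lo, hi)`.
#' @examples
#' wilsonInterval(9, 9)   # lower bound 0.7009
#' @export
wilsonInterval <- function(successes, n, level = 0.95) {
  if (n < 1) stop("n must be >= 1")
  stopifnot(successes >= 0, successes <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z / den * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(lo = center - half, hi = center + half)
}

#' Select an operating point on a ROC curve
#'
#' Chooses a threshold and reports sensitivity and specificity with 95\%
#' Wilson intervals.  Rules: `"youden"` maximizes TPR - FPR;
#' `"max_sens_then_spec"` takes, among thresholds with maximal
#' sensitivity, the one with maximal specificity.  Ties resolve to the
#' lower threshold.
#'
#' @param roc a [RocResult-class].
#' @param rule `"youden"` (default) or `"max_sens_then_spec"`.
#' @param level CI level for the Wilson intervals.
#' @return the [RocResult-class] with its `operating` slot filled
#'   (`rule`, `threshold`, `sensitivity`, `specificity`, `sens_ci`,
#'   `spec_ci`).
#' @export
operatingPoint <- function(roc, rule = c("youden", "max_sens_then_spec"),
                           level = 0.95) {
  rule <- match.arg(rule)
  stopifnot(is(roc, "RocResult"))
  sens <- roc@tpr; spec <- 1 - roc@fpr
  if (rule == "youden") {
    crit <- sens - (1 - spec)
    best <- which(crit == max(crit))
  } else {
    smax <- max(sens)
    cand <- which(sens == smax)
    best <- cand[spec[cand] == max(spec[cand])]
  }
  i <- best[which.min(roc@thresholds[best])]   # ties -> lower threshold
  nP <- roc@nPos; nN <- roc@nNeg
  roc@operating <- list(
    rule = rule, threshold = roc@thresholds[i],
    sensitivity = sens[i], specificity = spec[i],
    sens_ci = unname(wilsonInterval(round(sens[i] * nP), nP, level)),
    spec_ci = unname(wilsonInterval(round(spec[i] * nN), nN, level)))
  roc
}
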