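## From-scratch diagnostic statistics: empirical ROC/AUC, DeLong variance
## and paired comparison, Youden-index cutoff selection and the full 2x2
## metric row.  Positivity is strict (`value > cutoff`) throughout.

## Mann-Whitney kernel: mean over controls of I(case > control) + 1/2
## I(case == control), one component per case (V10) or control (V01).
.delongComponents <- function(cases, controls) {
  cmp <- outer(cases, controls,
               function(x, y) (x > y) + 0.5 * (x == y))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp),
       auc = mean(cmp))
}

#' Empirical ROC curve
#'
#' Builds the tie-grouped empirical ROC of a marker where larger values
#' are more disease-like and positivity is strict (`value > threshold`).
#' Thresholds are the unique observed values plus `+Inf`/`-Inf`
#' sentinels, so the curve runs from (0, 0) to (1, 1); the trapezoidal
#' area equals the Mann-Whitney statistic with ties counted one half.
#'
#' @param cases,controls numeric concentration vectors (>= 1 value each).
#' @return A [RocCurve-class].
#' @export
#' @examples
#' auc(empiricalRoc(c(2, 3), c(0, 1)))  # 1
empiricalRoc <- function(cases, controls) {
  cases <- cases[!is.na(cases)]; controls <- controls[!is.na(controls)]
  if (length(cases) < 1 || length(controls) < 1)
    stop("need at least one case and one control value")
  thr <- c(Inf, sort(unique(c(cases, controls)), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(cases > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(controls > t), numeric(1))
  a <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  new("RocCurve", thresholds = thr, fpr = fpr, tpr = tpr,
      auc = a, ci = c(NA_real_, NA_real_),
      nCases = length(cases), nControls = length(controls))
}

#' DeLong AUC variance, confidence interval and null test
#'
#' Estimates the AUC with its DeLong structural-component variance, a
#' Wald 95\% confidence interval truncated to [0, 1], and a two-sided
#' test of the null AUC = 0.5.  Perfect separation (AUC exactly 0 or 1)
#' collapses the variance; the result is then flagged `boundary` and the
#' p-value is reported as `NA`.
#'
#' @param cases,controls numeric vectors (>= 2 values each).
#' @param conf confidence level (default 0.95).
#' @return list with `auc`, `se`, `ci` (length 2), `p` (vs AUC = 0.5),
#'   `boundary` (logical).
#' @export
aucCiDelong <- function(cases, controls, conf = 0.95) {
  cases <- cases[!is.na(cases)]; controls <- controls[!is.na(controls)]
  if (length(cases) < 2 || length(controls) < 2)
    stop("need at least two cases and two controls")
  d <- .delongComponents(cases, controls)
  v <- var(d$v10) / length(cases) + var(d$v01) / length(controls)
  se <- sqrt(v)
  z <- qnorm(1 - (1 - conf) / 2)
  boundary <- v <= 0 || d$auc %in% c(0, 1)
  ci <- pmin(pmax(d$auc + c(-1, 1) * z * se, 0), 1)
  p <- if (boundary && v <= 0) NA_real_ else
    2 * pnorm(-abs(d$auc - 0.5) / se)
  list(auc = d$auc, se = se, ci = ci, p = p, boundary = boundary)
}

#' Paired DeLong comparison of two markers' AUCs
#'
#' Compares the AUCs of two markers measured on the same subjects
#' (paired DeLong test).  The difference is `AUC(A) - AUC(B)`; swapping
#' the markers negates the difference and leaves the p-value unchanged.
#'
#' @param valuesA,valuesB numeric marker values, parallel over subjects.
#' @param labels logical (or 0/1) case indicator, parallel to values.
#' @return list with `aucA`, `aucB`, `delta`, `se`, `z`, `p`.
#' @export
compareAucPaired <- function(valuesA, valuesB, labels) {
  labels <- as.logical(labels)
  if (length(valuesA) != length(valuesB) ||
      length(valuesA) != length(labels))
    stop("values and labels must be parallel over the same subjects")
  keep <- !is.na(valuesA) & !is.na(valuesB) & !is.na(labels)
  if (!all(keep))
    stop("missing values present; subset to complete subjects first")
  if (sum(labels) < 2 || sum(!labels) < 2)
    stop("need at least two cases and two controls")
  dA <- .delongComponents(valuesA[labels], valuesA[!labels])
  dB <- .delongComponents(valuesB[labels], valuesB[!labels])
  m <- sum(labels); n <- sum(!labels)
  s10 <- stats::cov(cbind(dA$v10, dB$v10))
  s01 <- stats::cov(cbind(dA$v01, dB$v01))
  vDelta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- dA$auc - dB$auc
  if (vDelta <= 0) {
    z <- if (delta == 0) 0 else sign(delta) * Inf
  } else {
    z <- delta / sqrt(vDelta)
  }
  list(aucA = dA$auc, aucB = dB$auc, delta = delta,
       se = sqrt(max(vDelta, 0)), z = z, p = 2 * pnorm(-abs(z)))
}

#' Youden-optimal cutoff from an ROC curve
#'
#' Selects the threshold maximizing the Youden index `J = sensitivity +
#' specificity - 1` over the curve's finite operating points, ties broken
#' toward higher specificity (and then the higher threshold).  When every
#' threshold gives `J = 0` the curve is flagged uninformative.  An
#' alternative closest-to-(0,1) criterion is available.
#'
#' @param curve a [RocCurve-class].
#' @param marker marker name recorded in the result.
#' @param criterion `"youden"` (default) or `"closest01"`.
#' @return list with `marker`, `cutoff`, `direction = ">"`,
#'   `sensitivity`, `specificity`, `j`, `uninformative`.
#' @export
optimalCutoff <- function(curve, marker = NA_character_,
                          criterion = c("youden", "closest01")) {
  criterion <- match.arg(criterion)
  stopifnot(is(curve, "RocCurve"))
  keep <- is.finite(curve@thresholds)
  if (!any(keep)) stop("degenerate curve without finite thresholds")
  thr <- curve@thresholds[keep]
  sens <- curve@tpr[keep]
  spec <- 1 - curve@fpr[keep]
  score <- if (criterion == "youden") sens + spec - 1 else
    -sqrt((1 - sens)^2 + (1 - spec)^2)
  best <- which(score >= max(score) - 1e-12)
  best <- best[order(-spec[best], -thr[best])][1]
  j <- sens[best] + spec[best] - 1
  list(marker = marker, cutoff = thr[best], direction = ">",
       sensitivity = sens[best], specificity = spec[best], j = j,
       uninformative = max(score) <= 1e-12 && criterion == "youden")
}

#' 2x2 confusion table at a cutoff
#'
#' Classifies each subject positive when `value > cutoff` and tabulates
#' against case/control labels.  Missing values are rejected: mask or
#' subset first.
#'
#' @param values numeric marker values.
#' @param labels logical (or 0/1) case indicator, parallel to values.
#' @param cutoff positive concentration cutoff.
#' @return A [ConfusionCounts-class].
#' @export
confusionAtCutoff <- function(values, labels, cutoff) {
  labels <- as.logical(labels)
  if (length(values) != length(labels))
    stop("values and labels must be parallel")
  if (anyNA(values) || anyNA(labels))
    stop("missing values present; mask before scoring")
  pos <- values > cutoff
  new("ConfusionCounts",
      TP = as.integer(sum(pos & labels)),
      FN = as.integer(sum(!pos & labels)),
      FP = as.integer(sum(pos & !labels)),
      TN = as.integer(sum(!pos & !labels)))
}

#' Construct ConfusionCounts from cell counts
#'
#' @param TP,FN,FP,TN nonnegative integer cells.
#' @return A [ConfusionCounts-class].
#' @export
confusionCounts <- function(TP, FN, FP, TN) {
  new("ConfusionCounts", TP = as.integer(TP), FN = as.integer(FN),
      FP = as.integer(FP), TN = as.integer(TN))
}

#' Reconstruct a 2x2 table from printed sensitivity/specificity
#'
#' Recovers integer cell counts from percentage sensitivity and
#' specificity with known group sizes, rounding to the nearest count —
#' the reconstruction used when checking published diagnostic tables.
#'
#' @param sensPct,specPct sensitivity and specificity in percent.
#' @param nCases,nControls group sizes.
#' @return A [ConfusionCounts-class].
#' @export
reconstructConfusion <- function(sensPct, specPct, nCases, nControls) {
  tp <- round(sensPct / 100 * nCases)
  tn <- round(specPct / 100 * nControls)
  confusionCounts(TP = tp, FN = nCases - tp, FP = nControls - tn, TN = tn)
}

#' Diagnostic metrics of a 2x2 table
#'
#' Computes the full diagnostic metric row from a confusion table:
#' sensitivity, specificity, accuracy, PPV and NPV (percent), positive
#' and negative likelihood ratios, diagnostic odds ratio
#' `(TP*TN)/(FP*FN)` and relative risk `[TP/(TP+FP)] / [FN/(FN+TN)]`.
#' Divisions by zero yield `Inf`/`NaN` flagged in `flags`; the
#' Haldane-Anscombe +0.5 continuity correction is available behind
#' `correction`.
#'
#' @param x a [ConfusionCounts-class].
#' @param correction `"none"` (default) or `"haldane"` (+0.5 on every
#'   cell for ratio-type metrics).
#' @return One-row data.frame with columns `sensitivity`, `specificity`,
#'   `accuracy`, `ppv`, `npv` (percent, full precision), `plr`, `nlr`,
#'   `oddsRatio`, `relativeRisk`, `flags`.
#' @export
#' @examples
#' metricsFromConfusion(confusionCounts(106, 27, 7, 79))
metricsFromConfusion <- function(x, correction = c("none", "haldane")) {
  correction <- match.arg(correction)
  stopifnot(is(x, "ConfusionCounts"))
  tp <- x@TP; fn <- x@FN; fp <- x@FP; tn <- x@TN
  if (tp + fn < 1 || fp + tn < 1)
    stop("need at least one case and one control")
  sens <- tp / (tp + fn)
  spec <- tn / (fp + tn)
  acc <- (tp + tn) / (tp + fn + fp + tn)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NaN
  npv <- if (tn + fn > 0) tn / (tn + fn) else NaN
  r <- if (correction == "haldane") 0.5 else 0
  ct <- c(tp, fn, fp, tn) + r
  plr <- (ct[1] / (ct[1] + ct[2])) / (ct[3] / (ct[3] + ct[4]))
  nlr <- (ct[2] / (ct[1] + ct[2])) / (ct[4] / (ct[3] + ct[4]))
  or <- (ct[1] * ct[4]) / (ct[3] * ct[2])
  rr <- (ct[1] / (ct[1] + ct[3])) / (ct[2] / (ct[2] + ct[4]))
  if (correction == "none") {
    plr <- if (spec < 1) sens / (1 - spec) else if (sens > 0) Inf else NaN
    nlr <- if (spec > 0) (1 - sens) / spec else NaN
    or <- if (fp * fn > 0) (tp * tn) / (fp * fn) else
      if (tp * tn > 0) Inf else NaN
    rr <- if (tp + fp > 0 && fn + tn > 0) {
      den <- fn / (fn + tn)
      if (den > 0) (tp / (tp + fp)) / den else if (tp > 0) Inf else NaN
    } else NaN
  }
  flags <- character()
  if (tp + fp == 0) flags <- c(flags, "ppv-undefined")
  if (tn + fn == 0) flags <- c(flags, "npv-undefined")
  if (correction == "none" && fp * fn == 0)
    flags <- c(flags, "or-boundary")
  data.frame(sensitivity = 100 * sens, specificity = 100 * spec,
             accuracy = 100 * acc, ppv = 100 * ppv, npv = 100 * npv,
             plr = plr, nlr = nlr, oddsRatio = or, relativeRisk = rr,
             flags = if (length(flags)) paste(flags, collapse = ";")
                     else NA_character_,
             stringsAsFactors = FALSE)
}

#' Full diagnostic row for a marker at a cutoff
#'
#' Convenience wrapper producing a published-table-style row for one
#' marker and one case/control comparison: AUC with DeLong CI plus the
#' cutoff metrics of [metricsFromConfusion()].
#'
#' @param cohort a [SerumCohort-class].
#' @param marker marker name.
#' @param cutoff positive cutoff (ng/mL).
#' @param caseStages,controlStages stage labels defining the comparison.
#' @return One-row data.frame: `marker`, `cutoff`, `auc`, `aucLo`,
#'   `aucHi`, `aucP`, then the metric columns.
#' @export
markerDiagnostics <- function(cohort, marker, cutoff,
                              caseStages = c("eHCC", "aHCC"),
                              controlStages = c("NL", "CH", "LC")) {
  cc <- caseControlValues(cohort, marker, caseStages, controlStages)
  d <- aucCiDelong(cc$cases, cc$controls)
  conf <- confusionAtCutoff(c(cc$cases, cc$controls),
                            rep(c(TRUE, FALSE),
                                c(length(cc$cases), length(cc$controls))),
                            cutoff)
  cbind(data.frame(marker = marker, cutoff = cutoff, auc = d$auc,
                   aucLo = d$ci[1], aucHi = d$ci[2], aucP = d$p,
                   stringsAsFactors = FALSE),
        metricsFromConfusion(conf))
}
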