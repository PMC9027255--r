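## Kaplan-Meier product-limit estimation and the two-group log-rank
## test, implemented directly from the estimating equations.  Ties
## between censoring and events at the same time follow the standard
## convention: events first (censored subjects remain at risk through
## the event time).

#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival step function `S(t) = prod_{t_i <= t} (1 -
#' d_i / n_i)` over the distinct event times, with the Greenwood
#' variance `S(t)^2 * sum d_i / (n_i (n_i - d_i))`.
#'
#' @param time nonnegative event/censoring times.
#' @param event 1 = event, 0 = censored (logical accepted).
#' @return data.frame with one row per distinct event time: `time`,
#'   `nRisk`, `nEvent`, `surv`, `greenwoodVar`.
#' @export
#' @examples
#' kmEstimate(c(1, 2, 3), c(1, 1, 1))  # steps 2/3, 1/3, 0
kmEstimate <- function(time, event) {
  event <- as.integer(event)
  if (length(time) < 1) stop("need at least one record")
  if (any(time < 0)) stop("negative survival times")
  if (!all(event %in% c(0L, 1L))) stop("event must be 0/1")
  eventTimes <- sort(unique(time[event == 1]))
  surv <- 1
  gsum <- 0
  rows <- lapply(eventTimes, function(t) {
    nRisk <- sum(time >= t)
    nEvent <- sum(time == t & event == 1)
    surv <<- surv * (1 - nEvent / nRisk)
    gsum <<- gsum + if (nRisk > nEvent)
      nEvent / (nRisk * (nRisk - nEvent)) else NA_real_
    data.frame(time = t, nRisk = nRisk, nEvent = nEvent, surv = surv,
               greenwoodVar = surv^2 * gsum)
  })
  if (length(rows) == 0)
    return(data.frame(time = numeric(), nRisk = integer(),
                      nEvent = integer(), surv = numeric(),
                      greenwoodVar = numeric()))
  do.call(rbind, rows)
}

#' Two-group log-rank test
#'
#' The standard observed-minus-expected log-rank chi-square with one
#' degree of freedom: at each distinct event time the events expected in
#' group 1 under the null are `d_j n_{1j} / n_j` with hypergeometric
#' variance `d_j (n_{1j}/n_j) (1 - n_{1j}/n_j) (n_j - d_j) / (n_j - 1)`.
#'
#' @param time nonnegative event/censoring times.
#' @param event 1 = event, 0 = censored.
#' @param group two-level group labels.
#' @return list with `observed`, `expected` (named per group),
#'   `variance`, `chisq`, `df = 1`, `p`, and `flag` (`"degenerate"` when
#'   the variance is zero, e.g. one group never at risk at event times).
#' @export
logrankTest <- function(time, event, group) {
  event <- as.integer(event)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2)
    stop("exactly two groups required")
  group <- droplevels(group)
  if (any(time < 0)) stop("negative survival times")
  g1 <- levels(group)[1]
  eventTimes <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in eventTimes) {
    atRisk <- time >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  obs <- c(o1, sum(event == 1) - o1)
  exp <- c(e1, sum(event == 1) - e1)
  names(obs) <- names(exp) <- levels(group)
  if (v <= 0)
    return(list(observed = obs, expected = exp, variance = v,
                chisq = NA_real_, df = 1L, p = NA_real_,
                flag = "degenerate"))
  chisq <- (o1 - e1)^2 / v
  list(observed = obs, expected = exp, variance = v, chisq = chisq,
       df = 1L, p = pchisq(chisq, 1, lower.tail = FALSE),
       flag = NA_character_)
}

#' Dichotomize expression for survival contrasts
#'
#' Splits samples into high/low expression of one gene relative to the
#' healthy-group mean: high when FPKM exceeds `fold` times the mean NL
#' value (the overexpression convention used for survival contrasts).
#'
#' @param se `SummarizedExperiment` with an FPKM assay and
#'   `colData$stage`.
#' @param gene gene id.
#' @param fold fold-change threshold over the NL mean (default 2).
#' @return Character vector (`"high"`/`"low"`) named by sample.
#' @export
dichotomizeExpression <- function(se, gene, fold = 2) {
  if (!gene %in% rownames(se)) stop(sprintf("unknown gene '%s'", gene))
  st <- .stageOf(se)
  if (!"NL" %in% st) stop("matrix contains no NL reference samples")
  vals <- .assayFpkm(se)[gene, ]
  ref <- mean(vals[st == "NL"])
  setNames(ifelse(vals > fold * ref, "high", "low"), colnames(se))
}
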