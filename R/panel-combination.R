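## Multi-marker panel evaluation.  The default combination logic is the
## OR-rule — a panel is positive when any member exceeds its cutoff —
## which trades specificity for sensitivity and is the natural reading of
## positive-rate panel analyses.  An AND-rule is available for
## specificity-oriented use.

#' Construct a PanelRule
#'
#' @param markers distinct member marker names.
#' @param cutoffs positive ng/mL cutoffs, parallel to `markers` (a named
#'   vector may be given alone).
#' @param logic `"OR"` (default) or `"AND"`.
#' @return A [PanelRule-class].
#' @export
#' @examples
#' panelRule(c("AFP", "HMMR"), c(20, 0.8))
panelRule <- function(markers, cutoffs = NULL, logic = c("OR", "AND")) {
  logic <- match.arg(logic)
  if (is.null(cutoffs)) {
    cutoffs <- as.numeric(markers)
    markers <- names(markers)
  }
  new("PanelRule", markers = as.character(markers),
      cutoffs = unname(as.numeric(cutoffs)), logic = logic)
}

.memberValues <- function(x, rule) {
  if (is(x, "SerumCohort")) {
    missing <- setdiff(rule@markers, markerNames(x))
    if (length(missing))
      stop(sprintf("cohort lacks panel marker(s): %s",
                   paste(missing, collapse = ", ")))
    x@concentrations[, rule@markers, drop = FALSE]
  } else {
    vals <- as.matrix(x)[, rule@markers, drop = FALSE]
    vals
  }
}

#' Panel positivity per subject
#'
#' Applies a panel rule to each subject: positive when any member (OR)
#' or every member (AND) exceeds its cutoff.  Subjects missing any member
#' value are rejected; exclude them first (see [completeForMarkers()]).
#'
#' @param x a [SerumCohort-class] or subjects x markers matrix.
#' @param rule a [PanelRule-class].
#' @return Logical vector, one entry per subject.
#' @export
panelPositive <- function(x, rule) {
  stopifnot(is(rule, "PanelRule"))
  vals <- .memberValues(x, rule)
  if (anyNA(vals))
    stop("missing member measurements; exclude incomplete subjects first")
  exceeds <- sweep(vals, 2, rule@cutoffs, ">")
  if (rule@logic == "OR") apply(exceeds, 1, any) else
    apply(exceeds, 1, all)
}

#' Continuous panel score
#'
#' The maximum over members of `log(value / cutoff)`: positive exactly
#' when the OR-rule panel is positive, and for a single-member panel a
#' strictly increasing transform of the raw value (so the panel ROC
#' equals the single-marker ROC).  Zero concentrations are floored at
#' `floor` ng/mL before taking logs.
#'
#' @param x a [SerumCohort-class] or subjects x markers matrix.
#' @param rule a [PanelRule-class].
#' @param floor positive lower bound applied to concentrations.
#' @return Numeric score per subject.
#' @export
combinedScore <- function(x, rule, floor = 1e-6) {
  stopifnot(is(rule, "PanelRule"), floor > 0)
  vals <- .memberValues(x, rule)
  if (anyNA(vals))
    stop("missing member measurements; exclude incomplete subjects first")
  vals <- pmax(vals, floor)
  scores <- sweep(log(vals), 2, log(rule@cutoffs), "-")
  apply(scores, 1, max)
}

#' Subjects with complete measurements for a marker set
#'
#' @param cohort a [SerumCohort-class].
#' @param markers marker names that must all be measured.
#' @return The cohort restricted to complete subjects.
#' @export
completeForMarkers <- function(cohort, markers) {
  stopifnot(is(cohort, "SerumCohort"))
  vals <- cohort@concentrations[, markers, drop = FALSE]
  cohort[complete.cases(vals)]
}

.asRuleList <- function(rules) {
  if (is(rules, "PanelRule")) rules <- list(rules)
  nms <- vapply(rules, function(r) paste(r@markers, collapse = "-"),
                character(1))
  if (is.null(names(rules))) names(rules) <- nms
  blank <- names(rules) == ""
  names(rules)[blank] <- nms[blank]
  rules
}

#' Positive-rate table by disease stage
#'
#' Per stage and per rule (single markers are one-member rules), the
#' number of evaluable subjects, the number panel-positive and the
#' positive rate in percent.  Stages without evaluable subjects are
#' emitted with `NA` rates.
#'
#' @param cohort a [SerumCohort-class].
#' @param rules a [PanelRule-class] or list of them (optionally named).
#' @return data.frame with columns `stage`, `panel`, `n`, `nPositive`,
#'   `rate`.
#' @export
positiveRateTable <- function(cohort, rules) {
  stopifnot(is(cohort, "SerumCohort"))
  rules <- .asRuleList(rules)
  stageLevelsUsed <- levels(droplevels(cohort@stage))
  rows <- list()
  for (rn in names(rules)) {
    rule <- rules[[rn]]
    sub <- completeForMarkers(cohort, rule@markers)
    pos <- panelPositive(sub, rule)
    st <- as.character(sub@stage)
    for (s in stageLevelsUsed) {
      n <- sum(st == s)
      np <- sum(pos[st == s])
      rows[[length(rows) + 1]] <- data.frame(
        stage = s, panel = rn, n = n, nPositive = np,
        rate = if (n > 0) 100 * np / n else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Rescue analysis relative to a reference marker
#'
#' Within cases, stratifies by positivity on a reference marker (AFP at
#' 20 ng/mL by convention) and reports each candidate marker's positive
#' rate inside the reference-negative and reference-positive strata —
#' the reference-negative rates are the "rescue" rates.
#'
#' @param cohort a [SerumCohort-class] restricted to case subjects.
#' @param reference one-member [PanelRule-class] (or marker name with
#'   `referenceCutoff`).
#' @param markers named numeric vector of candidate cutoffs (names are
#'   markers).
#' @param referenceCutoff cutoff when `reference` is a marker name.
#' @return data.frame with columns `stratum`
#'   (`"reference-negative"`/`"reference-positive"`), `marker`, `n`,
#'   `nPositive`, `rate`; empty strata carry `NA` rates.
#' @export
rescueAnalysis <- function(cohort, reference = "AFP", markers,
                           referenceCutoff = 20) {
  stopifnot(is(cohort, "SerumCohort"))
  if (is.character(reference))
    reference <- panelRule(reference, referenceCutoff)
  need <- c(reference@markers, names(markers))
  sub <- completeForMarkers(cohort, need)
  refPos <- panelPositive(sub, reference)
  rows <- list()
  for (stratum in c("reference-negative", "reference-positive")) {
    idx <- if (stratum == "reference-negative") !refPos else refPos
    for (m in names(markers)) {
      n <- sum(idx)
      np <- if (n > 0)
        sum(sub@concentrations[idx, m] > markers[[m]]) else 0L
      rows[[length(rows) + 1]] <- data.frame(
        stratum = stratum, marker = m, n = n, nPositive = np,
        rate = if (n > 0) 100 * np / n else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Exhaustive search for full-coverage panels
#'
#' Enumerates every size-`k` subset of the candidate markers and returns
#' the panels whose OR-rule positivity covers every case (100\% case
#' positivity), ordered lexicographically by member names.
#'
#' @param cases a [SerumCohort-class] (cases only) or subjects x markers
#'   matrix with every candidate measured on every case.
#' @param candidates named numeric vector of cutoffs (names are marker
#'   names).
#' @param k panel size, 2 or 3.
#' @return List of [PanelRule-class] objects (possibly empty).
#' @export
searchFullCoverage <- function(cases, candidates, k) {
  if (!k %in% c(2L, 3L)) stop("panel size k must be 2 or 3")
  markers <- sort(names(candidates))
  if (length(markers) < k) return(list())
  vals <- if (is(cases, "SerumCohort"))
    cases@concentrations[, markers, drop = FALSE]
  else as.matrix(cases)[, markers, drop = FALSE]
  if (anyNA(vals)) stop("all cases must be measured on all candidates")
  exceeds <- sweep(vals, 2, candidates[markers], ">")
  subsets <- utils::combn(markers, k, simplify = FALSE)
  keep <- Filter(function(mm) {
    all(rowSums(exceeds[, mm, drop = FALSE]) > 0)
  }, subsets)
  lapply(keep, function(mm) panelRule(mm, candidates[mm]))
}

#' Table-2-style metrics for a set of panels
#'
#' For each rule, computes the combination ROC on the continuous panel
#' score ([combinedScore()]) and the cutoff metrics of OR-rule positivity
#' at score 0 — one published-style row per panel.
#'
#' @param cohort a [SerumCohort-class].
#' @param rules a [PanelRule-class] or list of them.
#' @param caseStages,controlStages stage labels defining the comparison.
#' @return data.frame, one row per panel: `panel`, `n`, `auc`, `aucLo`,
#'   `aucHi`, then the [metricsFromConfusion()] columns.
#' @export
panelDiagnostics <- function(cohort, rules,
                             caseStages = c("eHCC", "aHCC"),
                             controlStages = c("NL", "CH", "LC")) {
  rules <- .asRuleList(rules)
  rows <- list()
  for (rn in names(rules)) {
    rule <- rules[[rn]]
    sub <- completeForMarkers(cohort, rule@markers)
    st <- as.character(sub@stage)
    keep <- st %in% c(caseStages, controlStages)
    sub <- sub[keep]
    labels <- as.character(sub@stage) %in% caseStages
    score <- combinedScore(sub, rule)
    d <- aucCiDelong(score[labels], score[!labels])
    conf <- confusionAtCutoff(score, labels, 0)
    rows[[length(rows) + 1]] <- cbind(
      data.frame(panel = rn, n = length(sub), auc = d$auc,
                 aucLo = d$ci[1], aucHi = d$ci[2],
                 stringsAsFactors = FALSE),
      metricsFromConfusion(conf))
  }
  do.call(rbind, rows)
}
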