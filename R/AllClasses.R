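#' @import methods
#' @importFrom stats qnorm pnorm pt rlnorm rnorm rexp runif var sd
#'   complete.cases p.adjust pchisq t.test setNames
NULL

## Canonical ordering of multistage liver-disease labels.  DN is kept as a
## level so external metadata using it still validates; the built-in designs
## fold high-grade DN into eHCC, mirroring how early-stage HCC groups are
## usually composed in multistage cohorts.
STAGE_LEVELS <- c("NL", "CH", "LC", "DN", "eHCC", "aHCC")

#' Stage labels of multistage hepatocarcinogenesis
#'
#' Returns the canonical ordered set of disease-stage labels used
#' throughout the package: normal liver (NL), chronic hepatitis (CH),
#' liver cirrhosis (LC), dysplastic nodule (DN), early-stage HCC (eHCC,
#' high-grade DN plus Edmondson grade 1) and advanced HCC (aHCC, grades
#' 2-3).
#'
#' @return Character vector of stage labels in progression order.
#' @export
#' @examples
#' stageLevels()
stageLevels <- function() STAGE_LEVELS

#' SerumCohort: per-subject serum marker concentrations
#'
#' A cohort of subjects, each carrying one liver-disease stage label and a
#' set of serum marker concentrations in ng/mL.  Missing measurements are
#' `NA` (a subject need not have been assayed for every marker).
#'
#' @slot subjectId character, unique subject identifiers.
#' @slot stage factor over [stageLevels()], one label per subject.
#' @slot concentrations numeric matrix, subjects x markers, ng/mL,
#'   nonnegative or `NA`.
#'
#' @seealso [generateSerumCohort()], [readSerumCohort()]
#' @export
setClass("SerumCohort",
  representation(
    subjectId = "character",
    stage = "factor",
    concentrations = "matrix"
  )
)

setValidity("SerumCohort", function(object) {
  msg <- character()
  n <- length(object@subjectId)
  if (anyDuplicated(object@subjectId))
    msg <- c(msg, "duplicate subject ids")
  if (length(object@stage) != n)
    msg <- c(msg, "stage length != number of subjects")
  if (!all(levels(object@stage) %in% STAGE_LEVELS))
    msg <- c(msg, sprintf(
      "unknown stage levels: %s",
      paste(setdiff(levels(object@stage), STAGE_LEVELS), collapse = ", ")))
  if (nrow(object@concentrations) != n)
    msg <- c(msg, "concentration matrix rows != number of subjects")
  if (is.null(colnames(object@concentrations)) &&
      ncol(object@concentrations) > 0)
    msg <- c(msg, "concentration matrix must have marker column names")
  vals <- object@concentrations
  if (any(vals < 0, na.rm = TRUE))
    msg <- c(msg, "negative concentrations")
  if (length(msg)) msg else TRUE
})

#' CohortDesign: stage counts and per-marker log-normal parameters
#'
#' Specifies a synthetic serum cohort: how many subjects per disease
#' stage, and for each marker and stage the log-normal location (meanlog)
#' and scale (sdlog) of the ng/mL concentration distribution.  Optionally
#' a missingness rate used to mask a random subset of measurements.
#'
#' @slot counts named integer, subjects per stage (names are stage labels).
#' @slot markers character, marker names.
#' @slot meanlog numeric matrix, markers x stages, log-normal locations.
#' @slot sdlog numeric matrix, markers x stages, log-normal scales (> 0).
#' @slot missingRate numeric in [0, 1), fraction of measurements masked.
#'
#' @seealso [cohortDesign()], [hccValidationDesign()], [hccTestDesign()]
#' @export
setClass("CohortDesign",
  representation(
    counts = "integer",
    markers = "character",
    meanlog = "matrix",
    sdlog = "matrix",
    missingRate = "numeric"
  )
)

setValidity("CohortDesign", function(object) {
  msg <- character()
  if (is.null(names(object@counts)) ||
      !all(names(object@counts) %in% STAGE_LEVELS))
    msg <- c(msg, "counts must be named by valid stage labels")
  if (any(object@counts < 0)) msg <- c(msg, "negative stage counts")
  dims <- c(length(object@markers), length(object@counts))
  if (!identical(dim(object@meanlog), dims))
    msg <- c(msg, "meanlog must be markers x stages")
  if (!identical(dim(object@sdlog), dims))
    msg <- c(msg, "sdlog must be markers x stages")
  if (any(object@sdlog <= 0)) msg <- c(msg, "sdlog must be positive")
  if (length(object@missingRate) != 1 || object@missingRate < 0 ||
      object@missingRate >= 1)
    msg <- c(msg, "missingRate must be a single value in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' RocCurve: empirical receiver operating characteristic
#'
#' The tie-grouped empirical ROC of a continuous marker, where larger
#' values are more disease-like and positivity is strict (`value >
#' threshold`).  The curve starts at (0, 0) (threshold `+Inf`) and ends at
#' (1, 1) (threshold `-Inf`); its trapezoidal area equals the Mann-Whitney
#' statistic with ties counted one half.
#'
#' @slot thresholds numeric, descending, with `+Inf`/`-Inf` sentinels.
#' @slot fpr,tpr numeric in [0, 1], one operating point per threshold.
#' @slot auc numeric, area under the curve.
#' @slot ci numeric length 2, 95\% DeLong confidence interval (NA until
#'   computed).
#' @slot nCases,nControls integer group sizes.
#'
#' @seealso [empiricalRoc()], [aucCiDelong()], [optimalCutoff()]
#' @export
setClass("RocCurve",
  representation(
    thresholds = "numeric",
    fpr = "numeric",
    tpr = "numeric",
    auc = "numeric",
    ci = "numeric",
    nCases = "integer",
    nControls = "integer"
  )
)

setValidity("RocCurve", function(object) {
  msg <- character()
  k <- length(object@thresholds)
  if (length(object@fpr) != k || length(object@tpr) != k)
    msg <- c(msg, "fpr/tpr length must match thresholds")
  if (is.unsorted(rev(object@thresholds)))
    msg <- c(msg, "thresholds must be descending")
  if (is.unsorted(object@fpr) || is.unsorted(object@tpr))
    msg <- c(msg, "fpr and tpr must be non-decreasing")
  if (k > 0 && (object@fpr[1] != 0 || object@tpr[1] != 0 ||
                object@fpr[k] != 1 || object@tpr[k] != 1))
    msg <- c(msg, "curve must run from (0,0) to (1,1)")
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc outside [0,1]")
  if (length(msg)) msg else TRUE
})

#' ConfusionCounts: the 2x2 diagnostic table
#'
#' True/false positive and negative counts of a binary diagnostic rule
#' applied to labelled subjects.
#'
#' @slot TP,FN,FP,TN nonnegative integer cell counts.
#' @seealso [confusionAtCutoff()], [metricsFromConfusion()]
#' @export
setClass("ConfusionCounts",
  representation(TP = "integer", FN = "integer", FP = "integer",
                 TN = "integer")
)

setValidity("ConfusionCounts", function(object) {
  cells <- c(object@TP, object@FN, object@FP, object@TN)
  if (length(cells) != 4 || any(is.na(cells)) || any(cells < 0))
    "all four cells must be single nonnegative integers"
  else TRUE
})

#' PanelRule: a multi-marker positivity rule
#'
#' A panel of distinct markers, each with its own ng/mL cutoff, combined
#' by OR-logic (panel positive if any member exceeds its cutoff) or, for
#' specificity-oriented use, AND-logic.
#'
#' @slot markers character, distinct member marker names.
#' @slot cutoffs numeric, positive cutoffs (ng/mL), parallel to markers.
#' @slot logic `"OR"` (default) or `"AND"`.
#' @seealso [panelRule()], [panelPositive()], [combinedScore()]
#' @export
setClass("PanelRule",
  representation(markers = "character", cutoffs = "numeric",
                 logic = "character")
)

setValidity("PanelRule", function(object) {
  msg <- character()
  if (length(object@markers) == 0) msg <- c(msg, "panel must be non-empty")
  if (anyDuplicated(object@markers)) msg <- c(msg, "duplicate member markers")
  if (length(object@cutoffs) != length(object@markers))
    msg <- c(msg, "cutoffs must parallel markers")
  if (any(!is.finite(object@cutoffs)) || any(object@cutoffs <= 0))
    msg <- c(msg, "cutoffs must be positive and finite")
  if (!identical(object@logic, "OR") && !identical(object@logic, "AND"))
    msg <- c(msg, "logic must be 'OR' or 'AND'")
  if (length(msg)) msg else TRUE
})
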