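#' Accessors for package classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `markerNames()` returns the marker set of a [SerumCohort-class],
#' [CohortDesign-class] or [PanelRule-class]; `stages()` the per-subject
#' stage factor; `subjectIds()` the subject identifiers;
#' `concentrations()` the subjects x markers ng/mL matrix; `stageCounts()`
#' the per-stage subject counts of a design; `auc()` the area under a
#' [RocCurve-class]; `aucCi()` its 95\% confidence interval; `cutoffs()`
#' the per-member cutoffs of a panel rule.
#'
#' @param x the object.
#' @return See each method's description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))

#' @rdname accessors
#' @export
setGeneric("stages", function(x) standardGeneric("stages"))

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname accessors
#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))

#' @rdname accessors
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname accessors
#' @export
setGeneric("aucCi", function(x) standardGeneric("aucCi"))

#' @rdname accessors
#' @export
setGeneric("cutoffs", function(x) standardGeneric("cutoffs"))

#' @rdname accessors
#' @export
setMethod("markerNames", "SerumCohort",
          function(x) colnames(x@concentrations))

#' @rdname accessors
#' @export
setMethod("markerNames", "CohortDesign", function(x) x@markers)

#' @rdname accessors
#' @export
setMethod("markerNames", "PanelRule", function(x) x@markers)

#' @rdname accessors
#' @export
setMethod("stages", "SerumCohort", function(x) x@stage)

#' @rdname accessors
#' @export
setMethod("subjectIds", "SerumCohort", function(x) x@subjectId)

#' @rdname accessors
#' @export
setMethod("concentrations", "SerumCohort", function(x) x@concentrations)

#' @rdname accessors
#' @export
setMethod("stageCounts", "CohortDesign", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("auc", "RocCurve", function(x) x@auc)

#' @rdname accessors
#' @export
setMethod("aucCi", "RocCurve", function(x) x@ci)

#' @rdname accessors
#' @export
setMethod("cutoffs", "PanelRule",
          function(x) setNames(x@cutoffs, x@markers))

#' Number of subjects in a cohort
#' @param x a [SerumCohort-class].
#' @return Integer subject count.
#' @export
setMethod("length", "SerumCohort", function(x) length(x@subjectId))

#' Subset a SerumCohort by subject
#'
#' @param x a [SerumCohort-class].
#' @param i logical, integer or character (subject id) index.
#' @param j,...,drop ignored.
#' @return A [SerumCohort-class] with the selected subjects.
#' @export
setMethod("[", "SerumCohort", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@subjectId)
  new("SerumCohort",
      subjectId = x@subjectId[i],
      stage = x@stage[i],
      concentrations = x@concentrations[i, , drop = FALSE])
})

setMethod("show", "SerumCohort", function(object) {
  cat(sprintf("SerumCohort with %d subjects, %d markers\n",
              length(object@subjectId), ncol(object@concentrations)))
  tab <- table(droplevels(object@stage))
  cat("stages: ",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "),
      "\n", sep = "")
  cat("markers:", paste(colnames(object@concentrations), collapse = ", "),
      "\n")
  nm <- sum(is.na(object@concentrations))
  if (nm > 0) cat(sprintf("missing measurements: %d\n", nm))
})

setMethod("show", "CohortDesign", function(object) {
  cat(sprintf("CohortDesign: %d subjects over %d stages, %d markers\n",
              sum(object@counts), length(object@counts),
              length(object@markers)))
  cat("counts: ",
      paste(sprintf("%s=%d", names(object@counts), object@counts),
            collapse = " "), "\n", sep = "")
  cat("markers:", paste(object@markers, collapse = ", "), "\n")
  if (object@missingRate > 0)
    cat(sprintf("missing rate: %.3f\n", object@missingRate))
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: %d cases vs %d controls, %d operating points\n",
              object@nCases, object@nControls, length(object@thresholds)))
  if (all(is.finite(object@ci)))
    cat(sprintf("AUC = %.4f (95%% CI %.4f-%.4f)\n", object@auc,
                object@ci[1], object@ci[2]))
  else
    cat(sprintf("AUC = %.4f\n", object@auc))
})

setMethod("show", "ConfusionCounts", function(object) {
  m <- matrix(c(object@TP, object@FP, object@FN, object@TN), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              truth = c("case", "control")))
  cat("ConfusionCounts\n")
  print(m)
})

setMethod("show", "PanelRule", function(object) {
  cat(sprintf("PanelRule (%s-rule, %d members)\n", object@logic,
              length(object@markers)))
  cat(paste(sprintf("  %s > %g ng/mL", object@markers, object@cutoffs),
            collapse = "\n"), "\n")
})
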