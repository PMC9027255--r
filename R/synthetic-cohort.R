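## Synthetic multistage cohorts.
##
## The serum data behind the marker panel are modelled per stage as
## log-normal concentrations (positive, right-skewed, closed-form
## exceedance), calibrated so that the probability of exceeding a marker's
## diagnostic cutoff hits a configured target.  This gives cohorts whose
## downstream sensitivity/specificity at the published cutoffs match the
## published operating points in expectation.

#' Calibrate a log-normal location to a target exceedance probability
#'
#' Returns the location `mu` such that a log-normal(mu, sigma) variable
#' exceeds `cutoff` with probability `target`:
#' `mu = log(cutoff) - sigma * qnorm(1 - target)`.
#'
#' @param target exceedance probability, strictly between 0 and 1.
#' @param cutoff positive concentration cutoff (ng/mL).
#' @param sigma positive log-scale standard deviation.
#' @return The calibrated `meanlog` (scalar, vectorized over arguments).
#' @export
#' @examples
#' mu <- calibrateLognormal(0.803, cutoff = 0.8, sigma = 1)
#' mean(rlnorm(1e5, mu, 1) > 0.8)  # ~0.803
calibrateLognormal <- function(target, cutoff, sigma) {
  if (any(!is.finite(target)) || any(target <= 0) || any(target >= 1))
    stop("target exceedance must lie strictly between 0 and 1")
  if (any(!is.finite(cutoff)) || any(cutoff <= 0))
    stop("cutoff must be positive")
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("sigma must be positive")
  log(cutoff) - sigma * qnorm(1 - target)
}

#' Published per-marker diagnostic operating points
#'
#' The validation-cohort diagnostic cutoffs (ng/mL) with their
#' sensitivities and specificities for the four candidate secretory
#' markers, plus AFP at its recommended clinical cutoff of 20 ng/mL.
#' These are the calibration anchors of the default synthetic designs.
#'
#' @return A data.frame with columns `marker`, `cutoff`, `sensitivity`,
#'   `specificity` (rates as percentages).
#' @export
markerOperatingPoints <- function() {
  data.frame(
    marker = c("AFP", "HMMR", "NXPH4", "PITX1", "THBS4"),
    cutoff = c(20, 0.8, 7.5, 2.5, 90),
    sensitivity = c(52.27, 80.30, 75.00, 80.30, 57.58),
    specificity = c(84.88, 91.86, 74.42, 66.28, 90.70),
    stringsAsFactors = FALSE
  )
}

#' Construct a CohortDesign
#'
#' @param counts named integer vector of subjects per stage; names must be
#'   drawn from [stageLevels()].
#' @param meanlog,sdlog numeric matrices (markers x stages) of log-normal
#'   parameters; rownames are marker names, colnames must match
#'   `names(counts)`.
#' @param missingRate fraction of measurements masked as missing.
#' @return A [CohortDesign-class].
#' @export
cohortDesign <- function(counts, meanlog, sdlog, missingRate = 0) {
  counts <- setNames(as.integer(counts), names(counts))
  meanlog <- as.matrix(meanlog)
  sdlog <- as.matrix(sdlog)
  if (!is.null(colnames(meanlog)) &&
      !identical(colnames(meanlog), names(counts)))
    stop("meanlog columns must match stage names")
  markers <- rownames(meanlog)
  if (is.null(markers)) stop("meanlog must have marker rownames")
  new("CohortDesign", counts = counts, markers = markers,
      meanlog = meanlog, sdlog = sdlog, missingRate = missingRate)
}

## Per-marker per-stage exceedance targets implied by the published
## operating points: case stages carry the sensitivity, control stages
## 1 - specificity.  AFP additionally honours the published 2% positive
## rate in normal liver; its CH/LC exceedance is solved so the
## validation-design control mixture (NL:CH:LC = 49:31:46) still pools to
## the published specificity.
.defaultExceedance <- function() {
  op <- markerOperatingPoints()
  stages <- c("NL", "CH", "LC", "eHCC", "aHCC")
  ex <- matrix(NA_real_, nrow(op), length(stages),
               dimnames = list(op$marker, stages))
  for (i in seq_len(nrow(op))) {
    sens <- op$sensitivity[i] / 100
    fpr <- 1 - op$specificity[i] / 100
    ex[i, c("NL", "CH", "LC")] <- fpr
    ex[i, c("eHCC", "aHCC")] <- sens
  }
  nlRate <- 0.02
  ctrl <- c(NL = 49, CH = 31, LC = 46)
  fprAfp <- 1 - op$specificity[op$marker == "AFP"] / 100
  chlc <- (fprAfp * sum(ctrl) - nlRate * ctrl["NL"]) / (ctrl["CH"] + ctrl["LC"])
  ex["AFP", "NL"] <- nlRate
  ex["AFP", c("CH", "LC")] <- chlc
  ex
}

.calibratedDesign <- function(counts, sdlog, missingRate) {
  op <- markerOperatingPoints()
  ex <- .defaultExceedance()
  stages <- colnames(ex)
  meanlog <- matrix(NA_real_, nrow(ex), ncol(ex), dimnames = dimnames(ex))
  for (m in rownames(ex))
    meanlog[m, ] <- calibrateLognormal(ex[m, ], op$cutoff[op$marker == m],
                                       sdlog)
  sd <- matrix(sdlog, nrow(ex), ncol(ex), dimnames = dimnames(ex))
  cohortDesign(counts[stages], meanlog, sd, missingRate)
}

#' Default synthetic cohort designs
#'
#' `hccTestDesign()` mirrors the test-set composition (16 NL, 13 CH, 15
#' LC, 35 eHCC, 24 aHCC); `hccValidationDesign()` the validation-set
#' composition (49 NL, 31 CH, 46 LC, 77 eHCC, 64 aHCC).  Both carry the
#' five markers of [markerOperatingPoints()] with log-normal parameters
#' calibrated so that, at the published cutoffs, case stages exceed with
#' probability equal to the published sensitivity and the pooled control
#' arm with probability `1 - specificity` (AFP: 2\% in NL).
#'
#' @param sdlog common log-scale standard deviation (default 1).
#' @param missingRate fraction of measurements masked as missing.
#' @return A [CohortDesign-class].
#' @export
hccValidationDesign <- function(sdlog = 1, missingRate = 0) {
  .calibratedDesign(c(NL = 49, CH = 31, LC = 46, eHCC = 77, aHCC = 64),
                    sdlog, missingRate)
}

#' @rdname hccValidationDesign
#' @export
hccTestDesign <- function(sdlog = 1, missingRate = 0) {
  .calibratedDesign(c(NL = 16, CH = 13, LC = 15, eHCC = 35, aHCC = 24),
                    sdlog, missingRate)
}

#' Rescale a design's stage counts
#'
#' Scales the subject counts of a design (rounded to integers), keeping
#' the marker distributions; used to grow a design to simulation size
#' while preserving the stage mixture.
#'
#' @param design a [CohortDesign-class].
#' @param factor positive scale factor.
#' @return A [CohortDesign-class].
#' @export
scaleDesign <- function(design, factor) {
  stopifnot(is(design, "CohortDesign"), factor > 0)
  counts <- as.integer(round(design@counts * factor))
  names(counts) <- names(design@counts)
  initialize(design, counts = counts)
}

#' Generate a synthetic serum cohort
#'
#' Draws per-subject marker concentrations from the design's per-stage
#' log-normal distributions.  Reproducible: the same `(design, seed)`
#' yields an identical cohort.
#'
#' @param design a [CohortDesign-class].
#' @param seed integer random seed (set before any draw).
#' @return A [SerumCohort-class].
#' @export
#' @examples
#' cohort <- generateSerumCohort(hccValidationDesign(), seed = 1)
#' cohort
generateSerumCohort <- function(design, seed = NULL) {
  stopifnot(is(design, "CohortDesign"))
  validObject(design)
  if (!is.null(seed)) set.seed(seed)
  counts <- design@counts
  stageVec <- factor(rep(names(counts), counts), levels = STAGE_LEVELS)
  n <- length(stageVec)
  markers <- design@markers
  conc <- matrix(NA_real_, n, length(markers),
                 dimnames = list(NULL, markers))
  for (s in names(counts)[counts > 0]) {
    idx <- which(stageVec == s)
    for (m in markers)
      conc[idx, m] <- rlnorm(length(idx), design@meanlog[m, s],
                             design@sdlog[m, s])
  }
  if (design@missingRate > 0 && n > 0) {
    mask <- matrix(runif(n * length(markers)) < design@missingRate,
                   n, length(markers))
    conc[mask] <- NA_real_
  }
  ids <- if (n > 0) sprintf("S%04d", seq_len(n)) else character()
  new("SerumCohort", subjectId = ids, stage = stageVec,
      concentrations = conc)
}

#' Case/control concentration vectors for one marker
#'
#' Splits a cohort's measurements for one marker into case and control
#' vectors by stage membership, dropping missing values.
#'
#' @param cohort a [SerumCohort-class].
#' @param marker marker name.
#' @param caseStages,controlStages character vectors of stage labels
#'   (defaults: eHCC+aHCC vs NL+CH+LC).
#' @return list with numeric `cases` and `controls`.
#' @export
caseControlValues <- function(cohort, marker,
                              caseStages = c("eHCC", "aHCC"),
                              controlStages = c("NL", "CH", "LC")) {
  stopifnot(is(cohort, "SerumCohort"))
  if (!marker %in% markerNames(cohort))
    stop(sprintf("unknown marker '%s'", marker))
  v <- cohort@concentrations[, marker]
  st <- as.character(cohort@stage)
  list(cases = v[st %in% caseStages & !is.na(v)],
       controls = v[st %in% controlStages & !is.na(v)])
}

#' Generate a planted staged expression fixture
#'
#' Builds a genes x samples FPKM matrix with known ground truth for
#' exercising the candidate-selection funnel.  The planted marker genes
#' are protein-coding, carry a synthetic signal-peptide-bearing protein,
#' sit in the external signature list, and are overexpressed in the HCC
#' stages only, with geometrically graded effects (ratio `grading`) so
#' the top-K ranking order is determined.  Decoy genes each violate
#' exactly one selection criterion: non-coding, coding without a signal
#' peptide, overexpressed also in CH/LC, or absent from the signature.
#'
#' @param nGenes total gene count (planted + decoys).
#' @param plantedMarkers character vector of planted gene ids.
#' @param design named integer vector of samples per stage; must contain
#'   an HCC stage (eHCC or aHCC) and NL.
#' @param effect fold-change (> 1) of the weakest planted gene in HCC
#'   stages; stronger planted genes are graded upward from it.
#' @param seed integer random seed.
#' @param grading ratio between consecutive planted effects (default
#'   1.25).
#' @param noiseSd log2-scale expression noise standard deviation.
#' @return A list: `se` (a
#'   [SummarizedExperiment::SummarizedExperiment-class] with assay
#'   `fpkm`, `colData$stage`, and rowData columns `biotype`,
#'   `inSignature`, `planted`), `proteins` (an
#'   [Biostrings::AAStringSet-class], coding genes only), `signature`
#'   (character vector of signature gene ids), and `plantedEffects`
#'   (named fold-changes).
#' @export
generateExpressionFixture <- function(nGenes, plantedMarkers,
                                      design = c(NL = 15, CH = 20, LC = 10,
                                                 eHCC = 18, aHCC = 45),
                                      effect = 4, seed = NULL,
                                      grading = 1.25, noiseSd = 0.35) {
  if (effect <= 1) stop("effect must exceed 1")
  if (!all(names(design) %in% STAGE_LEVELS))
    stop("unknown stage labels in design")
  hasHcc <- any(c("eHCC", "aHCC") %in% names(design)[design > 0])
  if (!hasHcc || !("NL" %in% names(design)) || design[["NL"]] == 0)
    stop("design must include NL and at least one HCC stage")
  nPlanted <- length(plantedMarkers)
  if (nPlanted < 1 || nPlanted > nGenes)
    stop("plantedMarkers must be non-empty and fit within nGenes")
  if (!is.null(seed)) set.seed(seed)

  nDecoy <- nGenes - nPlanted
  decoyClass <- rep(c("nonCoding", "noSignal", "chlcOver", "noSignature"),
                    length.out = nDecoy)
  decoyIds <- sprintf("DECOY%03d_%s", seq_len(nDecoy),
                      toupper(substr(decoyClass, 1, 4)))
  genes <- c(plantedMarkers, decoyIds)

  stageVec <- factor(rep(names(design), design), levels = STAGE_LEVELS)
  nSamples <- length(stageVec)
  sampleIds <- sprintf("T%03d", seq_len(nSamples))

  ## planted genes share one baseline so ranking follows planted effect
  plantedEffects <- effect * grading ^ (rev(seq_len(nPlanted)) - 1)
  names(plantedEffects) <- plantedMarkers
  baseline <- c(rep(4, nPlanted), runif(nDecoy, 2, 6))
  names(baseline) <- genes

  hccStages <- c("eHCC", "aHCC")
  mu <- matrix(rep(baseline, nSamples), nGenes, nSamples,
               dimnames = list(genes, sampleIds))
  isHcc <- as.character(stageVec) %in% hccStages
  isChlc <- as.character(stageVec) %in% c("CH", "LC")
  mu[plantedMarkers, isHcc] <-
    mu[plantedMarkers, isHcc] + log2(plantedEffects)
  decoyUp <- decoyIds  # every decoy is HCC-overexpressed
  mu[decoyUp, isHcc] <- mu[decoyUp, isHcc] + log2(effect)
  chlcIds <- decoyIds[decoyClass == "chlcOver"]
  mu[chlcIds, isChlc] <- mu[chlcIds, isChlc] + log2(effect)

  fpkm <- 2 ^ (mu + matrix(rnorm(nGenes * nSamples, sd = noiseSd),
                           nGenes, nSamples))

  biotype <- ifelse(genes %in% decoyIds[decoyClass == "nonCoding"],
                    "non-coding", "coding")
  names(biotype) <- genes
  inSignature <- !(genes %in% decoyIds[decoyClass == "noSignature"])
  names(inSignature) <- genes

  coding <- genes[biotype == "coding"]
  noSignal <- decoyIds[decoyClass == "noSignal"]
  proteins <- vapply(coding, function(g) {
    if (g %in% noSignal) .syntheticMatureProtein() else
      .syntheticSecretoryProtein()
  }, character(1))
  proteins <- Biostrings::AAStringSet(proteins)
  names(proteins) <- coding

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = fpkm),
    colData = S4Vectors::DataFrame(stage = stageVec, row.names = sampleIds),
    rowData = S4Vectors::DataFrame(
      biotype = biotype,
      inSignature = inSignature,
      planted = genes %in% plantedMarkers,
      row.names = genes))
  list(se = se, proteins = proteins,
       signature = genes[inSignature], plantedEffects = plantedEffects)
}

## A canonical tripartite signal peptide: positively charged n-region,
## leucine-rich h-region, small-residue c-region ending in A-S-A, followed
## by a random hydrophilic mature region.
.syntheticSecretoryProtein <- function(matureLength = 80) {
  signal <- "MKKLLLLLLLLLLASA"
  mature <- paste(sample(strsplit("DESTNQHRKGP", "")[[1]], matureLength,
                         replace = TRUE), collapse = "")
  paste0(signal, mature)
}

## Cytosolic-like control: acidic N-terminus, no hydrophobic core.
.syntheticMatureProtein <- function(length = 90) {
  nterm <- "MDEEDSEQNT"
  rest <- paste(sample(strsplit("DESTNQHRKGP", "")[[1]], length,
                       replace = TRUE), collapse = "")
  paste0(nterm, rest)
}

#' Generate synthetic two-group survival data
#'
#' Exponential event times with a configured hazard ratio between groups
#' `"A"` (baseline hazard 1) and `"B"` (hazard `hazardRatio`), under
#' independent exponential censoring whose rate is chosen so a baseline
#' subject is censored with probability `censorRate`.
#'
#' @param nPerGroup subjects per group (>= 1).
#' @param hazardRatio positive hazard ratio of group B vs A.
#' @param censorRate probability in [0, 1) of censoring a baseline
#'   subject; 0 disables censoring.
#' @param seed integer random seed.
#' @return data.frame with columns `subject_id`, `time`, `event` (1 =
#'   event, 0 = censored), `group`.
#' @export
generateSurvival <- function(nPerGroup, hazardRatio, censorRate = 0,
                             seed = NULL) {
  if (nPerGroup < 1) stop("nPerGroup must be >= 1")
  if (!is.finite(hazardRatio) || hazardRatio <= 0)
    stop("hazardRatio must be positive")
  if (censorRate < 0 || censorRate >= 1)
    stop("censorRate must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(nPerGroup)
  group <- rep(c("A", "B"), each = n)
  times <- c(rexp(n, rate = 1), rexp(n, rate = hazardRatio))
  if (censorRate > 0) {
    cens <- rexp(2 * n, rate = censorRate / (1 - censorRate))
  } else {
    cens <- rep(Inf, 2 * n)
  }
  event <- as.integer(times <= cens)
  data.frame(subject_id = sprintf("P%04d", seq_len(2 * n)),
             time = pmin(times, cens), event = event, group = group,
             stringsAsFactors = FALSE)
}
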