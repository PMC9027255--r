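# Independent oracles used across tests.  These deliberately avoid the
# package's own code paths: brute-force pairwise counts for AUC,
# per-subject loops for panel coverage, direct textbook formulas for
# Welch's t.

# O(n^2) Mann-Whitney AUC with ties counted one half.
bruteAuc <- function(cases, controls) {
  total <- 0
  for (x in cases)
    for (y in controls)
      total <- total + (x > y) + 0.5 * (x == y)
  total / (length(cases) * length(controls))
}

# Textbook Welch-Satterthwaite statistic.
bruteWelch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Exhaustive per-subject coverage check over all size-k marker subsets.
bruteCoverage <- function(values, cutoffs, k) {
  markers <- sort(names(cutoffs))
  found <- list()
  for (mm in combn(markers, k, simplify = FALSE)) {
    ok <- TRUE
    for (i in seq_len(nrow(values))) {
      hit <- FALSE
      for (m in mm) if (values[i, m] > cutoffs[[m]]) hit <- TRUE
      if (!hit) { ok <- FALSE; break }
    }
    if (ok) found[[length(found) + 1]] <- mm
  }
  found
}

# Random small case/control vectors with ties (integer-valued).
randomTiedVectors <- function(n = 30, maxVal = 8) {
  list(cases = sample.int(maxVal, n, replace = TRUE) + 0.0,
       controls = sample.int(maxVal, n, replace = TRUE) + 0.0)
}

# Shared planted fixture (10 markers, 90 single-violation decoys).
plantedFixture <- function(seed = 42) {
  generateExpressionFixture(
    nGenes = 100, plantedMarkers = sprintf("MARK%02d", 1:10),
    seed = seed)
}

# A random serum cohort with uncorrelated markers at assorted operating
# points, for panel property checks.
randomPanelCohort <- function(seed, nPerStage = 40) {
  d <- hccValidationDesign()
  counts <- stats::setNames(rep(as.integer(nPerStage),
                                length(stageCounts(d))),
                            names(stageCounts(d)))
  generateSerumCohort(methods::initialize(d, counts = counts),
                      seed = seed)
}

publishedCutoffs <- function() {
  op <- markerOperatingPoints()
  stats::setNames(op$cutoff, op$marker)
}
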