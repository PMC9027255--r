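test_that("OR-rule positivity fires on any exceeded member", {
  rule <- panelRule(c("AFP", "HMMR"), c(20, 0.8))
  vals <- rbind(c(AFP = 25, HMMR = 0.5),   # AFP alone positive
                c(AFP = 10, HMMR = 0.4),   # both at half cutoff
                c(AFP = 5, HMMR = 2))      # HMMR alone positive
  expect_identical(panelPositive(vals, rule), c(TRUE, FALSE, TRUE))
  andRule <- panelRule(c("AFP", "HMMR"), c(20, 0.8), logic = "AND")
  expect_identical(panelPositive(vals, andRule), c(FALSE, FALSE, FALSE))
  expect_error(panelPositive(rbind(c(AFP = NA, HMMR = 1)), rule),
               "missing")
  expect_error(panelRule(c("AFP", "AFP"), c(20, 20)), "duplicate")
})

test_that("single-member panels reduce exactly to marker positivity", {
  co <- randomPanelCohort(seed = 3)
  rule <- panelRule("HMMR", 0.8)
  expect_identical(panelPositive(co, rule),
                   unname(concentrations(co)[, "HMMR"] > 0.8))
  # continuous score is a strictly increasing transform of the value,
  # so the panel AUC equals the raw-marker AUC exactly
  score <- combinedScore(co, rule)
  labels <- as.character(stages(co)) %in% c("eHCC", "aHCC")
  expect_equal(auc(empiricalRoc(score[labels], score[!labels])),
               auc(empiricalRoc(concentrations(co)[labels, "HMMR"],
                                concentrations(co)[!labels, "HMMR"])),
               tolerance = 1e-12)
})

test_that("combined score sign agrees with OR positivity and is monotone", {
  rule <- panelRule(c("AFP", "HMMR", "PITX1"), c(20, 0.8, 2.5))
  atCutoff <- rbind(c(AFP = 20, HMMR = 0.8, PITX1 = 2.5))
  expect_equal(combinedScore(atCutoff, rule), 0)
  set.seed(9)
  for (i in 1:20) {
    co <- randomPanelCohort(seed = 100 + i, nPerStage = 10)
    score <- combinedScore(co, rule)
    pos <- panelPositive(co, rule)
    expect_identical(score > 0, pos)
    # doubling one member never lowers the score
    vals <- concentrations(co)
    bumped <- vals
    bumped[, "AFP"] <- bumped[, "AFP"] * 2
    expect_true(all(combinedScore(bumped, rule) >= score))
  }
})

test_that("panel sensitivity dominates members; specificity is dominated", {
  op <- markerOperatingPoints()
  cuts <- publishedCutoffs()
  for (seed in 1:5) {
    co <- randomPanelCohort(seed = seed)
    labels <- as.character(stages(co)) %in% c("eHCC", "aHCC")
    vals <- concentrations(co)
    rule <- panelRule(names(cuts), unname(cuts))
    pos <- panelPositive(co, rule)
    panelSens <- mean(pos[labels]); panelSpec <- mean(!pos[!labels])
    memberSens <- vapply(names(cuts), function(m)
      mean(vals[labels, m] > cuts[[m]]), numeric(1))
    memberSpec <- vapply(names(cuts), function(m)
      mean(vals[!labels, m] <= cuts[[m]]), numeric(1))
    expect_gte(panelSens, max(memberSens))
    expect_lte(panelSpec, min(memberSpec))
  }
})

test_that("adding a member never decreases case coverage", {
  cuts <- publishedCutoffs()
  co <- randomPanelCohort(seed = 44)
  cases <- co[as.character(stages(co)) %in% c("eHCC", "aHCC")]
  cov2 <- mean(panelPositive(cases, panelRule(c("AFP", "HMMR"),
                                              cuts[c("AFP", "HMMR")])))
  cov3 <- mean(panelPositive(
    cases, panelRule(c("AFP", "HMMR", "PITX1"),
                     cuts[c("AFP", "HMMR", "PITX1")])))
  expect_gte(cov3, cov2)
})

test_that("positive-rate tables report denominators and dominance", {
  cuts <- publishedCutoffs()
  co <- randomPanelCohort(seed = 12)
  singles <- lapply(names(cuts), function(m) panelRule(m, cuts[[m]]))
  rule <- panelRule(names(cuts), unname(cuts))
  tab <- positiveRateTable(co, c(singles, list(panel = rule)))
  expect_true(all(tab$nPositive <= tab$n))
  expect_equal(tab$rate, 100 * tab$nPositive / tab$n)
  # per stage, the OR-panel rate dominates every member rate
  for (s in unique(tab$stage)) {
    sub <- tab[tab$stage == s, ]
    expect_gte(sub$rate[sub$panel == "panel"],
               max(sub$rate[sub$panel != "panel"]))
  }
})

test_that("an all-positive stage reports a 100% rate", {
  co <- randomPanelCohort(seed = 1)
  rule <- panelRule("HMMR", 1e-9)
  tab <- positiveRateTable(co, rule)
  expect_true(all(tab$rate == 100))
})

test_that("rescue analysis stratifies cases by reference positivity", {
  cuts <- publishedCutoffs()
  co <- randomPanelCohort(seed = 31, nPerStage = 500)
  cases <- co[as.character(stages(co)) %in% c("eHCC", "aHCC")]
  out <- rescueAnalysis(cases, reference = "AFP",
                        markers = cuts[c("HMMR", "THBS4")],
                        referenceCutoff = 20)
  expect_setequal(unique(out$stratum),
                  c("reference-negative", "reference-positive"))
  # strata partition the case set
  expect_equal(sum(out$n[out$marker == "HMMR"]), length(cases))
  # markers independent of AFP: rescue rate ~ marginal positivity
  marginal <- mean(concentrations(cases)[, "HMMR"] > cuts[["HMMR"]])
  rescue <- out$rate[out$stratum == "reference-negative" &
                     out$marker == "HMMR"] / 100
  expect_lt(abs(rescue - marginal), 0.05)

  # a marker identical to the reference can never rescue
  vals <- cbind(concentrations(cases),
                AFPCOPY = concentrations(cases)[, "AFP"])
  withCopy <- new("SerumCohort", subjectId = subjectIds(cases),
                  stage = stages(cases), concentrations = vals)
  out2 <- rescueAnalysis(withCopy, reference = "AFP",
                         markers = c(AFPCOPY = 20))
  expect_equal(out2$rate[out2$stratum == "reference-negative"], 0)

  # all cases reference-positive -> empty stratum flagged as NA
  out3 <- rescueAnalysis(withCopy, reference = "AFP",
                         markers = c(AFPCOPY = 20),
                         referenceCutoff = 1e-9)
  expect_true(is.na(out3$rate[out3$stratum == "reference-negative"]))
})

test_that("full-coverage search agrees with brute force on random cohorts", {
  cuts <- publishedCutoffs()
  for (seed in 1:50) {
    co <- randomPanelCohort(seed = 500 + seed, nPerStage = 15)
    cases <- co[as.character(stages(co)) %in% c("eHCC", "aHCC")]
    vals <- concentrations(cases)
    for (k in 2:3) {
      got <- searchFullCoverage(cases, cuts, k = k)
      gotSets <- lapply(got, markerNames)
      want <- bruteCoverage(vals, as.list(cuts), k)
      expect_equal(length(gotSets), length(want))
      if (length(want))
        expect_identical(gotSets, want)
    }
  }
})

test_that("full-coverage search enumerates deterministically and validates", {
  # constructed cohort: markers A and B jointly cover all cases, C misses
  vals <- rbind(c(A = 10, B = 1, C = 1),
                c(A = 1, B = 10, C = 1))
  cuts <- c(A = 5, B = 5, C = 5)
  got <- searchFullCoverage(vals, cuts, k = 2)
  expect_identical(lapply(got, markerNames), list(c("A", "B")))
  expect_error(searchFullCoverage(vals, cuts, k = 4), "size")
  expect_identical(searchFullCoverage(vals, cuts[1], k = 2), list())
})

test_that("panel diagnostic rows carry consistent AUC and cutoff metrics", {
  cuts <- publishedCutoffs()
  co <- randomPanelCohort(seed = 88, nPerStage = 60)
  rule <- panelRule(c("AFP", "HMMR", "PITX1"),
                    cuts[c("AFP", "HMMR", "PITX1")])
  row <- panelDiagnostics(co, rule)
  expect_identical(row$panel, "AFP-HMMR-PITX1")
  expect_true(row$auc > 0.5 && row$auc <= 1)
  # OR-rule sensitivity must dominate the best single member's
  single <- panelDiagnostics(co, panelRule("HMMR", cuts[["HMMR"]]))
  expect_gte(row$sensitivity, single$sensitivity)
})
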