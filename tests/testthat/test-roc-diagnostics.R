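test_that("empirical ROC covers the boundary cases", {
  perfect <- empiricalRoc(c(2, 3), c(0, 1))
  expect_equal(auc(perfect), 1)
  same <- empiricalRoc(c(1, 2, 3), c(1, 2, 3))
  expect_equal(auc(same), 0.5)
  expect_error(empiricalRoc(numeric(), c(1)), "at least one")
})

test_that("trapezoidal AUC equals the Mann-Whitney pairwise count", {
  set.seed(101)
  for (i in 1:120) {
    v <- randomTiedVectors(n = sample(5:30, 1), maxVal = sample(3:10, 1))
    a <- auc(empiricalRoc(v$cases, v$controls))
    b <- bruteAuc(v$cases, v$controls)
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("AUC obeys label-flip duality and monotone-transform invariance", {
  set.seed(7)
  for (i in 1:20) {
    v <- randomTiedVectors(25)
    a <- auc(empiricalRoc(v$cases, v$controls))
    expect_equal(auc(empiricalRoc(v$controls, v$cases)), 1 - a,
                 tolerance = 1e-12)
    expect_equal(auc(empiricalRoc(exp(v$cases), exp(v$controls))), a,
                 tolerance = 1e-12)
  }
})

test_that("DeLong variance and CI agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:10) {
    cases <- rlnorm(30, 1, 1); controls <- rlnorm(40, 0, 1)
    got <- aucCiDelong(cases, controls)
    ref <- pROC::roc(response = rep(c(1, 0), c(30, 40)),
                     predictor = c(cases, controls), quiet = TRUE,
                     direction = "<")
    expect_equal(got$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
    expect_equal(got$se^2, as.numeric(pROC::var(ref, method = "delong")),
                 tolerance = 1e-10)
    refCi <- as.numeric(pROC::ci.auc(ref, method = "delong"))
    expect_equal(got$ci, pmin(pmax(refCi[c(1, 3)], 0), 1),
                 tolerance = 1e-10)
  }
})

test_that("DeLong variance is close to a bootstrap estimate", {
  set.seed(57)
  cases <- rlnorm(25, 0.8, 1); controls <- rlnorm(25, 0, 1)
  got <- aucCiDelong(cases, controls)
  boot <- replicate(1e4, {
    bruteless <- auc(empiricalRoc(sample(cases, replace = TRUE),
                                  sample(controls, replace = TRUE)))
  })
  expect_lt(abs(got$se^2 - var(boot)) / var(boot), 0.15)
})

test_that("perfect separation collapses the DeLong interval", {
  out <- aucCiDelong(c(10, 11, 12), c(1, 2, 3))
  expect_equal(out$auc, 1)
  expect_equal(out$ci[2], 1)
  expect_true(out$boundary)
})

test_that("paired DeLong comparison is antisymmetric and null-consistent", {
  set.seed(77)
  labels <- rep(c(TRUE, FALSE), each = 40)
  a <- c(rlnorm(40, 1.5, 1), rlnorm(40, 0, 1))
  b <- runif(80)
  same <- compareAucPaired(a, a, labels)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  ab <- compareAucPaired(a, b, labels)
  ba <- compareAucPaired(b, a, labels)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$p, ba$p)
  expect_lt(ab$p, 0.001)
  expect_error(compareAucPaired(a[1:10], b, labels), "parallel")
})

test_that("paired DeLong p-value matches pROC's paired test", {
  skip_if_not_installed("pROC")
  set.seed(91)
  labels <- rep(c(1, 0), each = 30)
  a <- c(rlnorm(30, 1, 1), rlnorm(30, 0, 1))
  b <- c(rlnorm(30, 0.5, 1), rlnorm(30, 0, 1))
  got <- compareAucPaired(a, b, labels)
  rocA <- pROC::roc(labels, a, quiet = TRUE, direction = "<")
  rocB <- pROC::roc(labels, b, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(rocA, rocB, method = "delong", paired = TRUE)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("Youden cutoff equals an exhaustive threshold scan", {
  set.seed(13)
  for (i in 1:25) {
    v <- randomTiedVectors(20, maxVal = 12)
    curve <- empiricalRoc(v$cases, v$controls)
    got <- optimalCutoff(curve)
    thr <- sort(unique(c(v$cases, v$controls)))
    js <- vapply(thr, function(t)
      mean(v$cases > t) + mean(v$controls <= t) - 1, numeric(1))
    expect_equal(got$j, max(js), tolerance = 1e-12)
    # reported cutoff attains the maximal J
    expect_equal(mean(v$cases > got$cutoff) +
                 mean(v$controls <= got$cutoff) - 1, got$j,
                 tolerance = 1e-12)
  }
})

test_that("Youden ties break toward higher specificity", {
  # thresholds 1 and 2 both give J = 0.5; 2 has higher specificity
  curve <- empiricalRoc(c(2, 3), c(1, 2))
  got <- optimalCutoff(curve)
  expect_equal(got$cutoff, 2)
  expect_equal(got$specificity, 1)
  flat <- optimalCutoff(empiricalRoc(c(1, 1), c(1, 1)))
  expect_true(flat$uninformative)
  expect_equal(flat$j, 0)
})

test_that("confusion tables partition subjects at the cutoff", {
  conf <- confusionAtCutoff(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE), 3)
  expect_identical(c(conf@TP, conf@FN, conf@FP, conf@TN),
                   c(2L, 0L, 0L, 2L))
  high <- confusionAtCutoff(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE), 10)
  expect_identical(c(high@TP, high@FP), c(0L, 0L))
  expect_error(confusionAtCutoff(c(NA, 1), c(TRUE, FALSE), 1), "missing")
})

test_that("published single-marker table rows are recovered from their 2x2", {
  m <- metricsFromConfusion(confusionCounts(106, 27, 7, 79))
  expect_equal(round(m$sensitivity, 2), 79.70)
  expect_equal(round(m$specificity, 2), 91.86)
  expect_equal(round(m$accuracy, 2), 84.47)
  expect_equal(round(m$ppv, 2), 93.81)
  expect_equal(round(m$npv, 2), 74.53)
  expect_equal(round(m$oddsRatio, 2), 44.31)
})

test_that("published panel table rows are recovered from their 2x2", {
  m <- metricsFromConfusion(confusionCounts(124, 8, 13, 73))
  expect_equal(round(m$plr, 2), 6.21)
  expect_equal(round(m$nlr, 2), 0.07)
  expect_equal(round(m$accuracy, 2), 90.37)
  expect_equal(round(m$oddsRatio, 2), 87.04)
})

test_that("degenerate confusion tables are flagged, not thrown", {
  perfect <- metricsFromConfusion(confusionCounts(5, 0, 0, 5))
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$accuracy, 100)
  expect_true(is.infinite(perfect$oddsRatio))
  expect_match(perfect$flags, "or-boundary")
  hald <- metricsFromConfusion(confusionCounts(5, 0, 0, 5),
                               correction = "haldane")
  expect_true(is.finite(hald$oddsRatio))
  expect_error(metricsFromConfusion(confusionCounts(0, 0, 1, 1)),
               "at least one")
})

test_that("OR = (+LR)/(-LR) whenever all four cells are positive", {
  set.seed(5)
  for (i in 1:50) {
    cells <- sample.int(80, 4)
    m <- metricsFromConfusion(confusionCounts(cells[1], cells[2],
                                              cells[3], cells[4]))
    expect_equal(m$oddsRatio, m$plr / m$nlr,
                 tolerance = 1e-9)
  }
})
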