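test_that("Welch t matches the textbook formula and handles degeneracy", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  got <- welchT(x, y)
  want <- bruteWelch(x, y)
  expect_equal(got$t, want$t)
  expect_equal(got$df, want$df)
  expect_equal(got$p, want$p)

  same <- welchT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  flat <- welchT(c(2, 2, 2), c(2, 2, 2))
  expect_equal(flat$t, 0)
  expect_equal(flat$p, 1)
  expect_identical(flat$flag, "zero-variance")

  sep <- welchT(c(5, 5), c(1, 1))
  expect_identical(sep$t, Inf)
  expect_equal(sep$p, 0)

  expect_identical(welchT(c(1), c(1, 2))$flag, "insufficient-n")
})

test_that("overexpression calls compute log2 fold change vs NL", {
  # two genes x 8 samples; GENEA doubled in eHCC at high abundance so
  # log2(FPKM+1) differences approximate log2 of the FPKM ratio
  fpkm <- rbind(GENEA = c(1000, 1010, 990, 1005, 2000, 2020, 1985, 2010),
                GENEB = c(10, 11, 9, 10.5, 10.2, 9.8, 10.4, 10.1))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = fpkm),
    colData = S4Vectors::DataFrame(
      stage = factor(rep(c("NL", "eHCC"), each = 4),
                     levels = stageLevels()),
      row.names = paste0("S", 1:8)))
  calls <- callOverexpression(se, "eHCC")
  a <- calls[calls$gene == "GENEA", ]
  expect_equal(a$log2fc, 1, tolerance = 0.02)
  expect_true(a$pass)
  b <- calls[calls$gene == "GENEB", ]
  expect_false(b$pass)
  expect_lt(abs(b$log2fc), 0.2)
  expect_error(callOverexpression(se, "aHCC"), "absent")
})

test_that("threshold monotonicity: stricter thresholds never grow call sets", {
  fx <- plantedFixture(seed = 17)
  se <- fx$se
  base <- callOverexpression(se, "eHCC", fcThreshold = 2, alpha = 0.05)
  for (fc in c(3, 4, 8)) {
    tighter <- callOverexpression(se, "eHCC", fcThreshold = fc)
    expect_true(all(tighter$gene[tighter$pass] %in%
                    base$gene[base$pass]))
  }
  for (a in c(0.01, 0.001)) {
    tighter <- callOverexpression(se, "eHCC", alpha = a)
    expect_true(all(tighter$gene[tighter$pass] %in%
                    base$gene[base$pass]))
  }
})

test_that("Venn filter keeps HCC-exclusive genes only", {
  calls <- list(CH = c("A", "B"), LC = c("B", "C"),
                eHCC = c("A", "B", "C", "D", "E"),
                aHCC = c("A", "C", "D", "E", "F"))
  # D, E pass both HCC stages; A hits CH, C hits LC
  expect_setequal(vennFilter(calls), c("D", "E"))
  expect_error(vennFilter(calls[c("CH", "eHCC", "aHCC")]), "LC")
})

test_that("signature intersection is case-normalized and warns when empty", {
  expect_setequal(intersectSignature(c("A", "B", "C"), c("b", "C", "D")),
                  c("B", "C"))
  expect_warning(out <- intersectSignature(c("A"), c("Z")), "disjoint")
  expect_identical(out, character(0))
  expect_error(intersectSignature(c("A"), character(0)), "empty")
})

test_that("candidate ranking orders by mean HCC expression with lexicographic ties", {
  fpkm <- rbind(ZGENE = c(1, 1, 100, 100),
                AGENE = c(1, 1, 100, 100),
                MGENE = c(1, 1, 400, 400))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = fpkm),
    colData = S4Vectors::DataFrame(
      stage = factor(c("NL", "NL", "eHCC", "aHCC"),
                     levels = stageLevels()),
      row.names = paste0("S", 1:4)))
  expect_identical(rankCandidates(se, rownames(se), k = 3),
                   c("MGENE", "AGENE", "ZGENE"))
  expect_identical(rankCandidates(se, rownames(se), k = 1), "MGENE")
  expect_message(all3 <- rankCandidates(se, c("AGENE", "ZGENE"), k = 5),
                 "returning all")
  expect_identical(all3, c("AGENE", "ZGENE"))
  expect_error(rankCandidates(se, "NOPE", k = 1), "rows")
})

test_that("the funnel recovers planted genes in planted-effect order", {
  fx <- plantedFixture(seed = 42)
  funnel <- selectionFunnel(fx$se, proteins = fx$proteins,
                            signature = fx$signature)
  planted <- names(sort(fx$plantedEffects, decreasing = TRUE))
  expect_identical(funnel$candidates, planted)
  expect_true(all(diff(funnel$counts) <= 0))
  # every step is a subset of the previous one
  expect_true(all(funnel$sets$secretory %in% funnel$sets$coding))
  expect_true(all(funnel$sets$afterVenn %in% funnel$sets$secretory))
  expect_true(all(funnel$sets$afterSignature %in% funnel$sets$afterVenn))
})

test_that("the funnel supports the detection-based CH/LC exclusion rule", {
  fx <- plantedFixture(seed = 19)
  # under 'detected', planted genes are detectably expressed in CH/LC
  # (they are present at baseline), so the candidate set empties
  expect_warning(
    funnel <- selectionFunnel(fx$se, proteins = fx$proteins,
                              signature = fx$signature,
                              chlcRule = "detected", detectionFpkm = 1),
    "disjoint")
  expect_identical(funnel$counts[["afterVenn"]], 0L)
})

test_that("the allow-list restricts candidates to assayable genes", {
  fx <- plantedFixture(seed = 23)
  allow <- sprintf("MARK%02d", 1:5)
  funnel <- selectionFunnel(fx$se, proteins = fx$proteins,
                            signature = fx$signature, allowList = allow)
  expect_setequal(funnel$candidates, allow)
})
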