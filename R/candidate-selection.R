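## Candidate-selection funnel over a staged FPKM matrix:
## coding filter -> signal-peptide screen -> per-stage overexpression
## calls -> Venn exclusion of CH/LC -> external signature intersection ->
## top-K ranking by mean HCC expression.

.assayFpkm <- function(se) {
  a <- SummarizedExperiment::assays(se)
  if ("fpkm" %in% names(a)) a[["fpkm"]] else a[[1]]
}

.stageOf <- function(se) {
  cd <- SummarizedExperiment::colData(se)
  if (!"stage" %in% names(cd)) stop("colData must carry a 'stage' column")
  as.character(cd$stage)
}

#' Welch's two-sample t test with degenerate-case handling
#'
#' Welch-Satterthwaite unequal-variance t statistic with a two-sided
#' p-value.  Degenerate inputs are flagged rather than thrown: fewer than
#' two values in either group gives an `NA` result with flag
#' `"insufficient-n"`; zero variance in both groups gives `t = 0, p = 1`
#' when the means agree and `t = +/-Inf, p = 0` (flag
#' `"zero-variance"`) when they differ.
#'
#' @param x,y numeric sample vectors.
#' @return list with `t`, `df`, `p`, `flag` (`NA` when regular).
#' @export
#' @examples
#' welchT(c(1, 2, 3), c(4, 5, 6))
welchT <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                flag = "insufficient-n"))
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                  flag = "zero-variance"))
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p = 0,
                flag = "zero-variance"))
  }
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, flag = NA_character_)
}

#' Stage-vs-normal overexpression calls
#'
#' Per gene, compares a disease stage against normal liver (NL) on
#' `log2(FPKM + 1)` values: the log2 fold change is the difference of
#' group means and significance comes from Welch's t test.  A gene
#' passes when `log2FC >= log2(fcThreshold)` and `p < alpha`.
#'
#' @param se a `SummarizedExperiment` with an FPKM assay and
#'   `colData$stage`.
#' @param stage target stage label (must be present, as must NL).
#' @param fcThreshold fold-change threshold (default 2).
#' @param alpha significance level (default 0.05).
#' @param adjust p-value adjustment: `"none"` (default) or `"BH"`.
#' @return data.frame with columns `gene`, `stage`, `log2fc`, `t`, `df`,
#'   `p`, `pass`, `flag`.
#' @export
callOverexpression <- function(se, stage, fcThreshold = 2, alpha = 0.05,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  st <- .stageOf(se)
  if (!stage %in% st) stop(sprintf("stage '%s' absent from matrix", stage))
  if (!"NL" %in% st) stop("matrix contains no NL reference samples")
  mat <- log2(.assayFpkm(se) + 1)
  sIdx <- st == stage
  nIdx <- st == "NL"
  res <- lapply(seq_len(nrow(mat)), function(i) {
    w <- welchT(mat[i, sIdx], mat[i, nIdx])
    c(lfc = mean(mat[i, sIdx]) - mean(mat[i, nIdx]),
      t = w$t, df = w$df, p = w$p,
      flag = is.na(w$flag))
  })
  lfc <- vapply(res, `[[`, numeric(1), "lfc")
  p <- vapply(res, `[[`, numeric(1), "p")
  if (adjust == "BH") p <- p.adjust(p, "BH")
  pass <- !is.na(p) & lfc >= log2(fcThreshold) & p < alpha
  data.frame(
    gene = rownames(mat), stage = stage, log2fc = lfc,
    t = vapply(res, `[[`, numeric(1), "t"),
    df = vapply(res, `[[`, numeric(1), "df"),
    p = p, pass = pass,
    flag = ifelse(vapply(res, `[[`, numeric(1), "flag") == 1,
                  NA_character_, "degenerate"),
    stringsAsFactors = FALSE, row.names = NULL)
}

.passSet <- function(calls) {
  if (is.data.frame(calls)) calls$gene[calls$pass] else as.character(calls)
}

#' Venn exclusion of chronic-disease expression
#'
#' Keeps genes called overexpressed (vs NL) in both HCC stages while not
#' called in chronic hepatitis or cirrhosis: `eHCC AND aHCC AND NOT CH
#' AND NOT LC`.
#'
#' @param calls named list with elements `CH`, `LC`, `eHCC`, `aHCC`, each
#'   either an overexpression-call data.frame (from
#'   [callOverexpression()]) or a character vector of passing genes.
#' @return Character vector of retained gene ids.
#' @export
vennFilter <- function(calls) {
  need <- c("CH", "LC", "eHCC", "aHCC")
  if (!all(need %in% names(calls)))
    stop(sprintf("calls must contain %s", paste(need, collapse = ", ")))
  keep <- intersect(.passSet(calls$eHCC), .passSet(calls$aHCC))
  setdiff(keep, union(.passSet(calls$CH), .passSet(calls$LC)))
}

#' Intersect candidates with an external HCC signature
#'
#' Case-normalized set intersection with an external gene-signature list
#' (e.g. an HCC-specific signature derived from an independent tumor
#' cohort).  An empty intersection warns rather than errors.
#'
#' @param candidates character vector of candidate gene ids.
#' @param signature non-empty character vector of signature gene ids.
#' @return Character vector of candidates present in the signature.
#' @export
intersectSignature <- function(candidates, signature) {
  if (length(signature) == 0) stop("signature list is empty")
  keep <- candidates[toupper(candidates) %in% toupper(signature)]
  if (length(keep) == 0)
    warning("candidate set and signature are disjoint")
  keep
}

#' Rank candidates by mean HCC expression
#'
#' Orders genes by decreasing mean `log2(FPKM + 1)` over all HCC samples
#' (eHCC + aHCC), ties broken lexicographically by gene id, and returns
#' the top `k`.
#'
#' @param se a `SummarizedExperiment` with an FPKM assay and
#'   `colData$stage`.
#' @param genes character vector of gene ids (subset of rows).
#' @param k number of genes to keep (default 10).
#' @return Character vector of up to `k` gene ids, best first.
#' @export
rankCandidates <- function(se, genes, k = 10) {
  if (k < 1) stop("k must be >= 1")
  if (!all(genes %in% rownames(se)))
    stop("genes must be rows of the expression matrix")
  if (length(genes) == 0) return(character())
  st <- .stageOf(se)
  hcc <- st %in% c("eHCC", "aHCC")
  if (!any(hcc)) stop("matrix contains no HCC samples")
  mat <- log2(.assayFpkm(se)[genes, hcc, drop = FALSE] + 1)
  means <- rowMeans(mat)
  ord <- order(-means, genes)
  if (k > length(genes))
    message(sprintf("k = %d exceeds candidate count %d; returning all",
                    k, length(genes)))
  genes[ord][seq_len(min(k, length(genes)))]
}

#' Run the full candidate-selection funnel
#'
#' Orchestrates the selection stages on a staged expression matrix:
#' protein-coding filter, signal-peptide secretome screen, per-stage
#' overexpression calls with Venn exclusion of CH/LC, intersection with
#' an external signature, an optional assayability allow-list, and top-K
#' ranking.
#'
#' @param se `SummarizedExperiment` with an FPKM assay, `colData$stage`
#'   and `rowData$biotype`.
#' @param proteins named `AAStringSet` of protein sequences for coding
#'   genes (used by the built-in predictor when `decisions` is `NULL`).
#' @param signature character vector of external signature gene ids.
#' @param decisions optional precomputed signal decisions (from
#'   [signalCalls()] or [parseSignalpShort()]).
#' @param allowList optional character vector restricting candidates to
#'   assayable genes.
#' @param fcThreshold,alpha,adjust passed to [callOverexpression()].
#' @param k top-K size (default 10).
#' @param chlcRule how "expressed in CH or LC" is judged:
#'   `"differential"` (default; called overexpressed vs NL) or
#'   `"detected"` (mean FPKM above `detectionFpkm`).
#' @param detectionFpkm detection threshold for `chlcRule = "detected"`.
#' @param ... passed to [builtinSignalCall()] via [signalCalls()].
#' @return list of class `"SelectionFunnel"`: `counts` (named funnel
#'   sizes), `candidates` (ranked top-K), `sets` (gene-id sets per
#'   stage), `calls` (per-stage call tables).
#' @export
selectionFunnel <- function(se, proteins = NULL, signature,
                            decisions = NULL, allowList = NULL,
                            fcThreshold = 2, alpha = 0.05,
                            adjust = "none", k = 10,
                            chlcRule = c("differential", "detected"),
                            detectionFpkm = 1, ...) {
  chlcRule <- match.arg(chlcRule)
  rd <- SummarizedExperiment::rowData(se)
  if (!"biotype" %in% names(rd)) stop("rowData must carry 'biotype'")
  records <- data.frame(gene = rownames(se), biotype = rd$biotype,
                        stringsAsFactors = FALSE)
  coding <- records$gene[records$biotype == "coding"]

  if (is.null(decisions)) {
    if (is.null(proteins)) stop("supply either proteins or decisions")
    decisions <- signalCalls(proteins[names(proteins) %in% coding], ...)
  }
  secretory <- secretomeFilter(records, decisions)

  callStage <- function(stage) callOverexpression(
    se[secretory, ], stage, fcThreshold = fcThreshold, alpha = alpha,
    adjust = adjust)
  calls <- list(eHCC = callStage("eHCC"), aHCC = callStage("aHCC"))
  if (chlcRule == "differential") {
    calls$CH <- callStage("CH")
    calls$LC <- callStage("LC")
  } else {
    st <- .stageOf(se)
    mat <- .assayFpkm(se)[secretory, , drop = FALSE]
    detected <- function(stage)
      secretory[rowMeans(mat[, st == stage, drop = FALSE]) > detectionFpkm]
    calls$CH <- detected("CH")
    calls$LC <- detected("LC")
  }
  afterVenn <- vennFilter(calls)
  afterSig <- intersectSignature(afterVenn, signature)
  pool <- if (is.null(allowList)) afterSig else
    intersect(afterSig, allowList)
  ranked <- rankCandidates(se, pool, k = k)

  out <- list(
    counts = c(total = nrow(se), coding = length(coding),
               secretory = length(secretory), afterVenn = length(afterVenn),
               afterSignature = length(afterSig),
               assayable = length(pool), topK = length(ranked)),
    candidates = ranked,
    sets = list(coding = coding, secretory = secretory,
                afterVenn = afterVenn, afterSignature = afterSig,
                assayable = pool),
    calls = calls)
  class(out) <- "SelectionFunnel"
  out
}

#' @export
print.SelectionFunnel <- function(x, ...) {
  cat("Candidate-selection funnel\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-15s %d\n", nm, x$counts[[nm]]))
  cat("candidates:", paste(x$candidates, collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate funnel counts
#'
#' @param funnel a `SelectionFunnel` from [selectionFunnel()].
#' @return data.frame with columns `step`, `count`.
#' @export
funnelReport <- function(funnel) {
  data.frame(step = names(funnel$counts),
             count = unname(funnel$counts),
             stringsAsFactors = FALSE)
}
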