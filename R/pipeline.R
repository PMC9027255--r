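## Configuration-driven front end.  One seeded run per invocation; every
## subcommand writes its artifacts plus a manifest (inputs, parameters,
## seed, md5 checksums) so outputs are reproducible from the manifest.

.writeManifest <- function(outDir, subcommand, config, seed, inputs,
                           outputs) {
  manifest <- list(
    subcommand = subcommand,
    seed = seed,
    parameters = config,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

.designFromConfig <- function(config) {
  name <- config$design %||% "validation"
  sdlog <- config$sdlog %||% 1
  miss <- config$missing_rate %||% 0
  switch(name,
         validation = hccValidationDesign(sdlog, miss),
         test = hccTestDesign(sdlog, miss),
         stop(sprintf("unknown design '%s'", name)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a pipeline subcommand
#'
#' Ties the package's stages into reproducible, manifest-tracked runs.
#' Subcommands: `simulate` (write a synthetic serum cohort), `select`
#' (candidate-selection funnel from expression + metadata + proteins +
#' signature), `roc` (per-marker diagnostic rows), `panel-rates`
#' (positive-rate table for a panel file), `panel-search` (exhaustive
#' full-coverage search), `survival` (KM curves + log-rank).  Identical
#' config and seed produce byte-identical outputs.
#'
#' @param config named list (typically from a JSON file via
#'   [jsonlite::fromJSON()]); recognized fields per subcommand are the
#'   input paths (`serum`, `expression`, `metadata`, `proteins`,
#'   `signature`, `panel`, `survival`), thresholds (`fold_change`,
#'   `alpha`, `cutoffs`, `size`) and generator settings (`design`,
#'   `sdlog`, `missing_rate`).
#' @param subcommand one of `"simulate"`, `"select"`, `"roc"`,
#'   `"panel-rates"`, `"panel-search"`, `"survival"`.
#' @param outDir output directory (created if needed).
#' @param seed integer seed recorded in the manifest and used for all
#'   randomness.
#' @return Invisibly, a list of output paths.
#' @export
runPipeline <- function(config, subcommand, outDir, seed = 1) {
  subcommand <- match.arg(subcommand,
                          c("simulate", "select", "roc", "panel-rates",
                            "panel-search", "survival"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character()
  outputs <- character()
  addOut <- function(p) outputs <<- c(outputs, p)

  if (subcommand == "simulate") {
    design <- .designFromConfig(config)
    cohort <- generateSerumCohort(design, seed = seed)
    p <- file.path(outDir, "serum.tsv")
    writeSerumCohort(cohort, p); addOut(p)
  } else if (subcommand == "select") {
    inputs <- c(config$expression, config$metadata, config$signature)
    se <- readExpressionMatrix(config$expression, config$metadata,
                               rowData = NULL)
    ann <- utils::read.table(config$annotations, header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
    inputs <- c(inputs, config$annotations)
    SummarizedExperiment::rowData(se)$biotype <-
      ann$biotype[match(rownames(se), ann$gene_id)]
    proteins <- readProteinFasta(config$proteins)
    inputs <- c(inputs, config$proteins)
    signature <- readGeneList(config$signature)
    allow <- if (!is.null(config$allow_list)) {
      inputs <- c(inputs, config$allow_list)
      readGeneList(config$allow_list)
    } else NULL
    funnel <- selectionFunnel(
      se, proteins = proteins, signature = signature,
      allowList = allow,
      fcThreshold = config$fold_change %||% 2,
      alpha = config$alpha %||% 0.05,
      k = config$k %||% 10)
    p1 <- file.path(outDir, "funnel.tsv")
    utils::write.table(funnelReport(funnel), p1, sep = "\t",
                       quote = FALSE, row.names = FALSE); addOut(p1)
    p2 <- file.path(outDir, "candidates.tsv")
    utils::write.table(
      data.frame(rank = seq_along(funnel$candidates),
                 gene = funnel$candidates),
      p2, sep = "\t", quote = FALSE, row.names = FALSE); addOut(p2)
  } else if (subcommand == "roc") {
    inputs <- config$serum
    cohort <- readSerumCohort(config$serum)
    cuts <- unlist(config$cutoffs)
    rows <- do.call(rbind, lapply(names(cuts), function(m)
      markerDiagnostics(cohort, m, cuts[[m]])))
    p <- file.path(outDir, "marker_metrics.tsv")
    utils::write.table(rows, p, sep = "\t", quote = FALSE,
                       row.names = FALSE); addOut(p)
    for (m in names(cuts)) {
      cc <- caseControlValues(cohort, m)
      pr <- file.path(outDir, sprintf("roc_%s.tsv", m))
      writeRocPoints(empiricalRoc(cc$cases, cc$controls), pr); addOut(pr)
    }
  } else if (subcommand == "panel-rates") {
    inputs <- c(config$serum, config$panel)
    cohort <- readSerumCohort(config$serum)
    rule <- readPanelJson(config$panel)
    singles <- lapply(seq_along(rule@markers), function(i)
      panelRule(rule@markers[i], rule@cutoffs[i]))
    p <- file.path(outDir, "panel_rates.tsv")
    utils::write.table(positiveRateTable(cohort, c(singles, list(rule))),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    addOut(p)
  } else if (subcommand == "panel-search") {
    inputs <- config$serum
    cohort <- readSerumCohort(config$serum)
    cuts <- unlist(config$cutoffs)
    caseStages <- config$case_stages %||% c("eHCC", "aHCC")
    cases <- completeForMarkers(
      cohort[as.character(stages(cohort)) %in% caseStages], names(cuts))
    found <- searchFullCoverage(cases, cuts, k = config$size %||% 3L)
    p <- file.path(outDir, "full_coverage_panels.tsv")
    utils::write.table(
      data.frame(panel = vapply(found, function(r)
        paste(r@markers, collapse = "-"), character(1))),
      p, sep = "\t", quote = FALSE, row.names = FALSE); addOut(p)
  } else if (subcommand == "survival") {
    inputs <- config$survival
    surv <- readSurvivalTable(config$survival)
    for (g in unique(surv$group)) {
      sub <- surv[surv$group == g, ]
      pg <- file.path(outDir, sprintf("km_%s.tsv", g))
      utils::write.table(kmEstimate(sub$time, sub$event), pg, sep = "\t",
                         quote = FALSE, row.names = FALSE); addOut(pg)
    }
    lr <- logrankTest(surv$time, surv$event, surv$group)
    p <- file.path(outDir, "logrank.json")
    jsonlite::write_json(
      list(observed = as.list(lr$observed),
           expected = as.list(lr$expected),
           variance = lr$variance, chisq = lr$chisq, df = lr$df,
           p = lr$p),
      p, auto_unbox = TRUE, digits = NA); addOut(p)
  }

  .writeManifest(outDir, subcommand, config, seed, as.list(inputs),
                 as.list(outputs))
  invisible(outputs)
}
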