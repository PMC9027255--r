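## Plain-text interchange formats: serum cohorts, expression matrices
## with stage metadata, gene lists, survival tables and panel
## definitions.  All tables are TSV with a header row; empty serum cells
## are missing measurements.

#' Read and write serum cohort TSVs
#'
#' The serum format has columns `subject_id`, `stage`, then one column
#' per marker holding ng/mL concentrations; empty cells are missing.
#'
#' @param path file path.
#' @param cohort a [SerumCohort-class].
#' @return `readSerumCohort` returns a [SerumCohort-class];
#'   `writeSerumCohort` returns `path` invisibly.
#' @export
readSerumCohort <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"))
  need <- c("subject_id", "stage")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: serum table must have columns %s", path,
                 paste(need, collapse = ", ")))
  markers <- setdiff(names(df), need)
  bad <- which(!df$stage %in% STAGE_LEVELS)
  if (length(bad))
    stop(sprintf("%s: line %d: unknown stage '%s'", path, bad[1] + 1,
                 df$stage[bad[1]]))
  conc <- as.matrix(df[, markers, drop = FALSE])
  storage.mode(conc) <- "double"
  rownames(conc) <- NULL
  new("SerumCohort", subjectId = as.character(df$subject_id),
      stage = factor(df$stage, levels = STAGE_LEVELS),
      concentrations = conc)
}

#' @rdname readSerumCohort
#' @export
writeSerumCohort <- function(cohort, path) {
  stopifnot(is(cohort, "SerumCohort"))
  df <- data.frame(subject_id = cohort@subjectId,
                   stage = as.character(cohort@stage),
                   cohort@concentrations, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write staged expression matrices
#'
#' The expression format is a genes x samples TSV of FPKM values (first
#' column `gene_id`) plus a sample-metadata TSV with columns `sample_id`
#' and `stage`.  Gene annotations (`biotype`, `inSignature`) may be
#' given as extra metadata via `rowData`.
#'
#' @param valuesPath,metadataPath file paths.
#' @param rowData optional data.frame of gene annotations, rownames =
#'   gene ids (must include `biotype` for selection use).
#' @param se a `SummarizedExperiment` to write.
#' @return `readExpressionMatrix` returns a `SummarizedExperiment` with
#'   assay `fpkm` and `colData$stage`; `writeExpressionMatrix` returns
#'   `valuesPath` invisibly.
#' @export
readExpressionMatrix <- function(valuesPath, metadataPath,
                                 rowData = NULL) {
  vals <- utils::read.table(valuesPath, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  if (names(vals)[1] != "gene_id")
    stop(sprintf("%s: first column must be gene_id", valuesPath))
  genes <- vals$gene_id
  if (anyDuplicated(genes))
    stop(sprintf("%s: duplicate gene ids", valuesPath))
  mat <- as.matrix(vals[, -1, drop = FALSE])
  rownames(mat) <- genes
  if (any(mat < 0, na.rm = TRUE))
    stop(sprintf("%s: negative FPKM values", valuesPath))
  meta <- utils::read.table(metadataPath, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (!all(c("sample_id", "stage") %in% names(meta)))
    stop(sprintf("%s: metadata needs sample_id and stage", metadataPath))
  if (!setequal(meta$sample_id, colnames(mat)))
    stop("metadata samples do not match expression columns")
  meta <- meta[match(colnames(mat), meta$sample_id), ]
  bad <- which(!meta$stage %in% STAGE_LEVELS)
  if (length(bad))
    stop(sprintf("%s: unknown stage '%s'", metadataPath, meta$stage[bad[1]]))
  cd <- S4Vectors::DataFrame(
    stage = factor(meta$stage, levels = STAGE_LEVELS),
    row.names = colnames(mat))
  rd <- if (is.null(rowData)) NULL else
    S4Vectors::DataFrame(rowData[match(genes, rownames(rowData)), ,
                                 drop = FALSE], row.names = genes)
  args <- list(assays = list(fpkm = mat), colData = cd)
  if (!is.null(rd)) args$rowData <- rd
  do.call(SummarizedExperiment::SummarizedExperiment, args)
}

#' @rdname readExpressionMatrix
#' @export
writeExpressionMatrix <- function(se, valuesPath, metadataPath) {
  mat <- SummarizedExperiment::assays(se)[[1]]
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, valuesPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(
    sample_id = colnames(se),
    stage = as.character(SummarizedExperiment::colData(se)$stage),
    stringsAsFactors = FALSE)
  utils::write.table(meta, metadataPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(valuesPath)
}

#' Read a gene list (one id per line)
#'
#' @param path file path; lines starting with `#` and blanks ignored.
#' @return Character vector of gene ids.
#' @export
readGeneList <- function(path) {
  lines <- trimws(readLines(path))
  lines[lines != "" & !startsWith(lines, "#")]
}

#' Read and write survival tables
#'
#' TSV with columns `subject_id`, `time`, `event` (0/1), `group`.
#'
#' @param path file path.
#' @param records data.frame in the same layout.
#' @return `readSurvivalTable` returns the validated data.frame;
#'   `writeSurvivalTable` returns `path` invisibly.
#' @export
readSurvivalTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "time", "event", "group")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: survival table must have columns %s", path,
                 paste(need, collapse = ", ")))
  if (any(df$time < 0)) stop(sprintf("%s: negative times", path))
  if (!all(df$event %in% c(0, 1)))
    stop(sprintf("%s: event must be 0/1", path))
  df
}

#' @rdname readSurvivalTable
#' @export
writeSurvivalTable <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a panel definition file
#'
#' JSON array of objects `{"marker": name, "cutoff_ng_per_ml": value}`.
#'
#' @param path JSON file path.
#' @param logic combination logic for the resulting rule.
#' @return A [PanelRule-class].
#' @export
readPanelJson <- function(path, logic = "OR") {
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!all(c("marker", "cutoff_ng_per_ml") %in% names(spec)))
    stop(sprintf("%s: panel entries need marker and cutoff_ng_per_ml",
                 path))
  panelRule(spec$marker, spec$cutoff_ng_per_ml, logic = logic)
}

#' Export ROC operating points as TSV
#'
#' @param curve a [RocCurve-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRocPoints <- function(curve, path) {
  stopifnot(is(curve, "RocCurve"))
  utils::write.table(
    data.frame(threshold = curve@thresholds, fpr = curve@fpr,
               tpr = curve@tpr),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
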