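## Signal-peptide screening.
##
## Two routes feed the secretome filter with a boolean call per protein:
## parsing real SignalP 4.x short-format output, or a built-in simplified
## classical predictor (von-Heijne-style tripartite rule: charged
## n-region, hydrophobic h-region by Kyte-Doolittle window score, and a
## (-3,-1) small-residue cleavage site).  The built-in rule is an
## explicitly simplified stand-in, not a neural-network reimplementation.

## Kyte-Doolittle hydropathy.  Non-standard residues (B, Z, X, U, J, O)
## score 0 (neutral) and are never allowed at the -3/-1 cleavage sites.
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2,
  B = 0, Z = 0, X = 0, U = 0, J = 0, O = 0
)

## Small-residue preference at the -3 and -1 cleavage positions.
SMALL_RESIDUE_WEIGHT <- c(A = 1.0, G = 0.9, S = 0.85, C = 0.8, T = 0.7,
                          V = 0.5)

.aaVector <- function(sequence) {
  sequence <- toupper(gsub("\\s", "", as.character(sequence)))
  sequence <- sub("\\*$", "", sequence)  # trailing stop
  strsplit(sequence, "")[[1]]
}

#' Mean Kyte-Doolittle hydropathy over a window
#'
#' @param sequence amino-acid string (standard one-letter codes; B, Z, X,
#'   U score 0).
#' @param start 1-based start of the window.
#' @param width window width (>= 1).
#' @param strict if `TRUE`, non-standard residues raise an error instead
#'   of scoring 0.
#' @return Mean hydropathy over the window (leucine scores 3.8, aspartate
#'   -3.5).
#' @export
#' @examples
#' kdWindowScore("LLLLLLLL", 1, 8)  # 3.8
kdWindowScore <- function(sequence, start, width, strict = FALSE) {
  if (width < 1) stop("width must be >= 1")
  aa <- .aaVector(sequence)
  if (start < 1 || start + width - 1 > length(aa))
    stop("window outside sequence bounds")
  win <- aa[start:(start + width - 1)]
  unknown <- !(win %in% names(KD_HYDROPATHY))
  if (any(unknown))
    stop(sprintf("unknown residue(s): %s",
                 paste(unique(win[unknown]), collapse = ", ")))
  if (strict && any(!(win %in% names(KD_HYDROPATHY)[1:20])))
    stop("non-standard residue in window (strict mode)")
  mean(KD_HYDROPATHY[win])
}

#' Simplified built-in signal-peptide call
#'
#' Deterministic tripartite rule over the N-terminus of a protein:
#' \enumerate{
#'   \item h-region: the maximal mean Kyte-Doolittle hydropathy over
#'     8-residue windows starting within residues 1-30 must exceed
#'     `hydroThreshold` (default 1.6);
#'   \item n-region: at least one positively charged residue (K/R) must
#'     precede the h-region window;
#'   \item cleavage site: scanning candidate last-signal residues within
#'     positions 10-45, the residues at -3 and -1 relative to cleavage
#'     must both be small (A, G, S, C, T, V), scored by a small-residue
#'     weight matrix; the best-scoring position is reported (ties to the
#'     earliest position).
#' }
#' The call is positive only if all three components pass; the reported
#' score is a weighted sum of the components.  Sequences shorter than 25
#' residues are negative with a reason, not an error.
#'
#' @param sequence amino-acid string.
#' @param hydroThreshold minimum h-region window hydropathy.
#' @param hWidth hydrophobic window width (default 8).
#' @param cleavageRange integer length-2, candidate cleavage-position
#'   range (1-based index of the last signal residue).
#' @return A list: `hasSignal` (logical), `cleavagePos` (last signal
#'   residue, `NA` when negative), `score`, `method = "builtin"`, and
#'   `reason` (`NA` when positive).
#' @export
#' @examples
#' builtinSignalCall("MKKLLLLLLLLLLASADDEESSTTNNQQRRKKGGPP")
builtinSignalCall <- function(sequence, hydroThreshold = 1.6, hWidth = 8,
                              cleavageRange = c(10, 45)) {
  negative <- function(reason, score = 0) {
    list(hasSignal = FALSE, cleavagePos = NA_integer_, score = score,
         method = "builtin", reason = reason)
  }
  aa <- .aaVector(sequence)
  if (length(aa) < 25) return(negative("sequence shorter than 25 residues"))

  ## (i) hydrophobic core within residues 1-30
  lastStart <- min(30, length(aa) - hWidth + 1)
  winScores <- vapply(seq_len(lastStart), function(s) {
    win <- aa[s:(s + hWidth - 1)]
    mean(KD_HYDROPATHY[match(win, names(KD_HYDROPATHY))], na.rm = TRUE)
  }, numeric(1))
  hStart <- which.max(winScores)
  hMax <- winScores[hStart]
  if (!is.finite(hMax) || hMax <= hydroThreshold)
    return(negative("h-region hydrophobicity below threshold"))

  ## (ii) positively charged residue before the h-region
  if (hStart < 2 || !any(aa[seq_len(hStart - 1)] %in% c("K", "R")))
    return(negative("no K/R in n-region"))

  ## (iii) (-3,-1) small-residue cleavage site
  lo <- max(cleavageRange[1], hStart + hWidth)
  hi <- min(cleavageRange[2], length(aa))
  best <- NA_integer_; bestW <- -Inf
  for (p in seq(lo, hi)) {
    if (p - 2 < 1) next
    r3 <- aa[p - 2]; r1 <- aa[p]
    if (r3 %in% names(SMALL_RESIDUE_WEIGHT) &&
        r1 %in% names(SMALL_RESIDUE_WEIGHT)) {
      w <- SMALL_RESIDUE_WEIGHT[r3] + SMALL_RESIDUE_WEIGHT[r1]
      if (w > bestW) { bestW <- w; best <- p }
    }
  }
  if (is.na(best))
    return(negative("no (-3,-1) small-residue cleavage site",
                    score = 0.5 * hMax / 4.5))

  score <- 0.5 * hMax / 4.5 + 0.2 + 0.3 * bestW / 2
  list(hasSignal = TRUE, cleavagePos = as.integer(best),
       score = unname(score), method = "builtin", reason = NA_character_)
}

#' Signal-peptide calls for a set of proteins
#'
#' Applies [builtinSignalCall()] to every sequence of an
#' [Biostrings::AAStringSet-class] (or named character vector).
#'
#' @param proteins an `AAStringSet` or named character vector.
#' @param ... passed to [builtinSignalCall()].
#' @return data.frame with columns `id`, `hasSignal`, `cleavagePos`,
#'   `score`, `method`, `reason`.
#' @export
signalCalls <- function(proteins, ...) {
  ids <- names(proteins)
  if (is.null(ids)) stop("proteins must be named")
  calls <- lapply(as.character(proteins), builtinSignalCall, ...)
  data.frame(
    id = ids,
    hasSignal = vapply(calls, `[[`, logical(1), "hasSignal"),
    cleavagePos = vapply(calls, `[[`, integer(1), "cleavagePos"),
    score = vapply(calls, `[[`, numeric(1), "score"),
    method = "builtin",
    reason = vapply(calls, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Parse SignalP 4.x short-format output
#'
#' Reads the tabular "short" output of SignalP 4.x (columns: name, Cmax,
#' pos, Ymax, pos, Smax, pos, Smean, D, ?, Dmaxcut, network; comment
#' lines start with `#`).  A sequence is signal-positive when the `?`
#' column is `Y`; SignalP reports the Ymax position as the first residue
#' of the mature protein, so the stored cleavage position (last signal
#' residue) is `Ymax pos - 1`.  The D score is kept as the decision
#' score.
#'
#' @param lines character vector of lines, or a file path of length 1
#'   pointing to an existing file.
#' @return data.frame with columns `id`, `hasSignal`, `cleavagePos`,
#'   `score`, `method = "parsed"`.
#' @export
parseSignalpShort <- function(lines) {
  if (length(lines) == 1 && !grepl("\n", lines) && file.exists(lines))
    lines <- readLines(lines)
  out <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#")) next
    fields <- strsplit(line, "[ \t]+")[[1]]
    if (length(fields) < 10)
      stop(sprintf("malformed SignalP line %d: expected >= 10 fields, got %d",
                   i, length(fields)))
    id <- fields[1]
    ymaxPos <- suppressWarnings(as.integer(fields[5]))
    d <- suppressWarnings(as.numeric(fields[9]))
    flag <- fields[10]
    if (is.na(d) || !(flag %in% c("Y", "N")))
      stop(sprintf("malformed SignalP line %d: bad D score or Y/N flag", i))
    if (id %in% names(out))
      stop(sprintf("duplicate sequence id '%s' at line %d", id, i))
    out[[id]] <- list(
      hasSignal = flag == "Y",
      cleavagePos = if (flag == "Y") ymaxPos - 1L else NA_integer_,
      score = d)
  }
  data.frame(
    id = names(out),
    hasSignal = vapply(out, `[[`, logical(1), "hasSignal"),
    cleavagePos = vapply(out, `[[`, integer(1), "cleavagePos"),
    score = vapply(out, `[[`, numeric(1), "score"),
    method = if (length(out)) "parsed" else character(0),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Secretome filter
#'
#' Restricts genes to the protein-coding ones with a positive
#' signal-peptide call.  Coding genes without a decision are treated as
#' signal-negative (with a message); non-coding genes never pass.
#'
#' @param records data.frame with columns `gene` (or `id`) and `biotype`
#'   (`"coding"` / `"non-coding"`).
#' @param decisions data.frame as returned by [signalCalls()] or
#'   [parseSignalpShort()] (columns `id`, `hasSignal`).
#' @return Character vector of secretory coding gene ids.
#' @export
secretomeFilter <- function(records, decisions) {
  geneCol <- if ("gene" %in% names(records)) "gene" else "id"
  genes <- records[[geneCol]]
  coding <- genes[records$biotype == "coding"]
  idx <- match(coding, decisions$id)
  uncovered <- coding[is.na(idx)]
  if (length(uncovered))
    message(sprintf(
      "%d coding gene(s) without a signal decision treated as no-signal",
      length(uncovered)))
  has <- decisions$hasSignal[idx]
  has[is.na(has)] <- FALSE
  coding[has]
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] that keeps only the
#' first whitespace-delimited token of each header as the id, uppercases
#' sequences and strips a terminal `*` stop.
#'
#' @param path FASTA file path.
#' @return An [Biostrings::AAStringSet-class] named by gene id.
#' @export
readProteinFasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  names(aa) <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1)
  seqs <- toupper(sub("\\*$", "", as.character(aa)))
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- names(aa)
  out
}

#' Write signal-peptide decisions as TSV
#'
#' @param decisions data.frame from [signalCalls()] or
#'   [parseSignalpShort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSignalDecisions <- function(decisions, path) {
  cols <- intersect(c("id", "hasSignal", "cleavagePos", "score", "method"),
                    names(decisions))
  utils::write.table(decisions[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
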