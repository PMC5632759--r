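## Peptide sequence identity and cross-reactivity networks.
##
## Sequence "similarity" here is strict positional identity between
## equal-length peptides (no alignment): epitopes presented by the same
## class I MHC compete for the same groove register, so a positional
## comparison is the relevant one, and the printed percentages (e.g. the
## 37.5% shared between well-known cross-reactive H-2Kb octamers) are
## exact position-match fractions.

.aaAlphabet <- "^[ACDEFGHIKLMNPQRSTVWY]+$"

#' Percent positional identity between two equal-length peptides
#'
#' `100 * matches / length`, reported to one decimal. Unequal lengths are
#' an error: no gapped alignment is attempted.
#'
#' @param a,b one-letter amino-acid strings of equal length.
#' @return percentage in \[0, 100\].
#' @examples
#' percentIdentity("AIVNYANL", "SIINFEKL")  # 37.5
#' @export
percentIdentity <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b))
    stop("sequences differ in length (", nchar(a), " vs ", nchar(b),
         "); positional identity undefined")
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  round(100 * sum(av == bv) / length(av), 1)
}

#' Pairwise percent-identity matrix
#'
#' Symmetric with a diagonal of 100. Peptides of different lengths form
#' separate blocks: cross-block entries are `NA` and the matrix carries
#' `attr(, "lengthMismatch") = TRUE`.
#'
#' @param peptides named character vector of sequences, or a data.frame
#'   with columns `id` and `sequence`.
#' @return labelled numeric matrix of percentages.
#' @export
pairwiseIdentityMatrix <- function(peptides) {
  if (is.data.frame(peptides))
    peptides <- stats::setNames(peptides$sequence, peptides$id)
  n <- length(peptides)
  ids <- names(peptides) %||% as.character(seq_len(n))
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m) <- 100
  mism <- FALSE
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (nchar(peptides[i]) == nchar(peptides[j])) {
      m[i, j] <- m[j, i] <- percentIdentity(peptides[[i]], peptides[[j]])
    } else mism <- TRUE
  }
  attr(m, "lengthMismatch") <- mism
  m
}

#' Construct a cross-reactivity network
#'
#' @param peptides data.frame with columns `id`, `sequence`, `mhc` (one
#'   MHC restriction per network).
#' @param edges data.frame with columns `source`, `target`, `strength`
#'   (`"strong"` or `"weak"`); direction records which T-cell line (primed
#'   on `source`) recognized `target`.
#' @param nonEdges data.frame with columns `source`, `target`: pairs
#'   tested and found non-cross-reactive.
#' @return A [CrossReactivityNetwork-class].
#' @export
crossReactivityNetwork <- function(peptides,
                                   edges = data.frame(source = character(),
                                                      target = character(),
                                                      strength = character()),
                                   nonEdges = data.frame(source = character(),
                                                         target = character())) {
  if (nrow(edges) && !all(edges$strength %in% c("strong", "weak")))
    stop("edge strengths must be 'strong' or 'weak'")
  new("CrossReactivityNetwork",
      peptides = as.data.frame(peptides, stringsAsFactors = FALSE),
      edges = as.data.frame(edges, stringsAsFactors = FALSE),
      nonEdges = as.data.frame(nonEdges, stringsAsFactors = FALSE))
}

#' Read peptides from CSV or FASTA
#'
#' CSV needs columns `id`, `sequence`, `mhc`. FASTA headers are parsed as
#' `id [mhc]`, with `mhc` defaulting to `"unknown"`.
#'
#' @param path input file (`.csv`, `.fasta`/`.fa`).
#' @return data.frame with columns `id`, `sequence`, `mhc`.
#' @export
readPeptides <- function(path) {
  if (grepl("\\.(fa|fasta)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("reading FASTA requires the Biostrings package")
    ss <- Biostrings::readAAStringSet(path)
    hdr <- strsplit(names(ss), "\\s+")
    data.frame(id = vapply(hdr, `[`, character(1), 1),
               sequence = as.character(ss),
               mhc = vapply(hdr, function(h)
                 if (length(h) > 1) h[2] else "unknown", character(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("id", "sequence", "mhc") %in% names(df)))
      stop("peptide CSV needs columns id, sequence, mhc")
    df
  }
}

#' Read a cross-reactivity network from CSV files
#'
#' The edge list has columns `source`, `target`, `type` with `type` in
#' \{`strong`, `weak`, `none`\}; `none` rows become tested-negative pairs.
#'
#' @param peptidesPath peptide CSV/FASTA (see [readPeptides()]).
#' @param edgesPath edge-list CSV.
#' @return A [CrossReactivityNetwork-class].
#' @export
readNetwork <- function(peptidesPath, edgesPath) {
  peptides <- readPeptides(peptidesPath)
  el <- utils::read.csv(edgesPath, stringsAsFactors = FALSE)
  if (!all(c("source", "target", "type") %in% names(el)))
    stop("edge CSV needs columns source, target, type")
  if (!all(el$type %in% c("strong", "weak", "none")))
    stop("edge type must be strong, weak or none")
  pos <- el[el$type != "none", , drop = FALSE]
  neg <- el[el$type == "none", , drop = FALSE]
  crossReactivityNetwork(
    peptides,
    data.frame(source = pos$source, target = pos$target,
               strength = pos$type, stringsAsFactors = FALSE),
    data.frame(source = neg$source, target = neg$target,
               stringsAsFactors = FALSE))
}

.pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Score a partition against an observed cross-reactivity network
#'
#' Structural similarity is undirected, so edge direction is ignored for
#' scoring (a directionality summary is reported separately, not scored):
#' sensitivity is the fraction of observed cross-reactive pairs that are
#' co-clustered, specificity the fraction of tested-negative pairs that
#' are separated. Violating pairs are listed. Invariant under permutation
#' of cluster labels.
#'
#' @param partition named cluster vector (names must cover the network's
#'   peptides that are scored; see [cutDendrogram()]).
#' @param network a [CrossReactivityNetwork-class].
#' @return list with `sensitivity`, `specificity`, `nEdges`, `nNonEdges`,
#'   `missedEdges`, `violatedNonEdges`, `directionality`.
#' @export
evaluatePartition <- function(partition, network) {
  stopifnot(is(network, "CrossReactivityNetwork"))
  e <- network@edges
  ne <- network@nonEdges
  if (nrow(e) + nrow(ne) == 0L) stop("network has no tested pairs")
  unknown <- setdiff(unique(c(e$source, e$target, ne$source, ne$target)),
                     names(partition))
  if (length(unknown))
    stop("partition lacks peptide(s): ", paste(unknown, collapse = ", "))

  pairDF <- function(df) {
    if (!nrow(df)) return(df[, c("source", "target")])
    k <- .pairKey(df$source, df$target)
    df[!duplicated(k), c("source", "target"), drop = FALSE]
  }
  ep <- pairDF(e)
  np <- pairDF(ne)
  together <- function(df) partition[df$source] == partition[df$target]

  sens <- if (nrow(ep)) mean(together(ep)) else NA_real_
  spec <- if (nrow(np)) mean(!together(np)) else NA_real_
  fmt <- function(df, keep) if (any(keep))
    paste(df$source[keep], df$target[keep], sep = " - ") else character(0)

  recip <- if (nrow(e)) sum(.pairKey(e$source, e$target) %in%
                              .pairKey(e$target, e$source) &
                              duplicated(.pairKey(e$source, e$target))) else 0L
  list(sensitivity = sens,
       specificity = spec,
       nEdges = nrow(ep), nNonEdges = nrow(np),
       missedEdges = fmt(ep, !together(ep)),
       violatedNonEdges = fmt(np, together(np)),
       directionality = list(
         nDirected = nrow(e),
         nStrong = sum(e$strength == "strong"),
         nWeak = sum(e$strength == "weak"),
         nReciprocated = recip))
}

#' Write an agreement report as JSON
#'
#' @param report result of [evaluatePartition()].
#' @param path output file.
#' @export
writeAgreementJSON <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
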