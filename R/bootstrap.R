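## Multiscale bootstrap support for the surface-similarity dendrogram.
##
## Feature rows (the exported CSV rows) are the resampling units. Ordinary
## bootstrap probabilities (BP) count how often each reference cluster
## reappears in trees built from resampled features; the approximately
## unbiased (AU) p-value extrapolates BP across resampling scales r via the
## probit model z_r = v*sqrt(r) + c/sqrt(r), fit by weighted least squares,
## with AU = 1 - Phi(v - c) and a delta-method standard error.

.sampleSizes <- function(nf, scales) {
  m <- floor(nf * scales + 0.5)   # round half away from zero
  if (any(m < 2L))
    stop("scale(s) ", paste(scales[m < 2L], collapse = ", "),
         " give bootstrap sample sizes < 2")
  as.integer(m)
}

.refSetsMatrix <- function(hc) {
  n <- length(hc$labels)
  members <- .edgeMembers(hc)
  m <- matrix(0L, length(members), n)
  for (e in seq_along(members)) m[e, members[[e]]] <- 1L
  m
}

.checkBootInputs <- function(features, nBoot, scales) {
  features <- as.matrix(features)
  if (nrow(features) < 4L)
    stop("need at least 4 feature rows to resample")
  if (ncol(features) < 3L)
    stop("need at least 3 complexes to cluster")
  if (ncol(features) > 64L)
    stop("bootstrap engine supports at most 64 complexes")
  if (nBoot < 100L) stop("nBoot must be at least 100")
  if (any(scales <= 0)) stop("all scales must be > 0")
  features
}

#' Bootstrap probabilities at a single resampling scale
#'
#' Draws `round(n_f * scale)` feature rows with replacement per replicate,
#' recomputes the correlation-distance UPGMA tree, and records which of the
#' reference tree's membership sets reappear. The PRNG is seeded and
#' replicate-indexed, so each replicate is independently reproducible.
#'
#' @param features feature matrix (features x complexes, >= 4 rows,
#'   3..64 columns).
#' @param nBoot replicates (>= 100).
#' @param scale resampling scale multiplier r.
#' @param seed integer seed.
#' @return data.frame with `edge`, `members`, `height`, `count`, `bp`.
#' @export
bootstrapBP <- function(features, nBoot = 1000, scale = 1, seed = 1) {
  features <- .checkBootInputs(features, nBoot, scale)
  hc <- upgma(correlationDistance(features))
  counts <- boot_counts_cpp(features, .refSetsMatrix(hc),
                            .sampleSizes(nrow(features), scale),
                            as.integer(nBoot), as.numeric(seed))
  members <- .edgeMembers(hc)
  data.frame(
    edge = seq_along(members),
    members = vapply(members, function(m)
      paste(hc$labels[m], collapse = "+"), character(1)),
    height = hc$height,
    count = counts[, 1],
    bp = counts[, 1] / nBoot,
    stringsAsFactors = FALSE)
}

#' Fit the multiscale-bootstrap AU model to per-scale BP counts
#'
#' For each edge, BP values (with the continuity correction
#' `(count + 0.5)/(nBoot + 1)` applied to counts of 0 or nBoot) are probit
#' transformed, `z_r = qnorm(1 - BP_r)`, and fit by weighted least squares
#' to `z_r = v*sqrt(r) + c/sqrt(r)` with inverse-variance weights
#' (binomial variance propagated through the probit). Then
#' `AU = 1 - Phi(v - c)`, the model-implied BP at r = 1 is
#' `1 - Phi(v + c)`, and `se(AU)` follows from the WLS covariance of
#' (v, c) by the delta method. Edges with fewer than 3 usable scales fall
#' back to `AU = BP` with `se = NaN` and are flagged degenerate.
#'
#' @param counts integer matrix, edges x scales, of reappearance counts.
#' @param nBoot replicates per scale.
#' @param scales the resampling scale multipliers (>= 3 for a fit).
#' @return data.frame with `au`, `bp`, `bp.model`, `se.au`, `v`, `c`,
#'   `df`, `degenerate` per edge.
#' @export
multiscaleAU <- function(counts, nBoot, scales) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == length(scales))
  iOne <- which(abs(scales - 1) < 1e-9)[1]
  out <- data.frame(au = numeric(0), bp = numeric(0), bp.model = numeric(0),
                    se.au = numeric(0), v = numeric(0), c = numeric(0),
                    df = integer(0), degenerate = logical(0))
  for (e in seq_len(nrow(counts))) {
    cnt <- counts[e, ]
    bp <- cnt / nBoot
    edgeBP <- if (!is.na(iOne)) bp[iOne] else NA_real_
    corr <- cnt == 0L | cnt == nBoot
    bp[corr] <- (cnt[corr] + 0.5) / (nBoot + 1)
    ## the probit model is only identifiable from scales where the cluster
    ## neither always nor never reappears; an edge seen in all (or no)
    ## replicates at nearly every scale is reported at its face value
    usable <- !corr
    if (sum(usable) < 3L) {
      ## certain edges (BP identically 0 or 1) have a zero-variance BP,
      ## hence SE 0; anything else is an unfittable edge, flagged NaN
      se <- if (isTRUE(all(corr)) && edgeBP %in% c(0, 1)) 0 else NaN
      out[e, ] <- list(edgeBP, edgeBP, edgeBP, se, NA_real_, NA_real_,
                       NA_integer_, TRUE)
      next
    }
    usable <- bp > 0 & bp < 1   # corrected values all qualify
    r <- scales[usable]
    z <- stats::qnorm(bp[usable], lower.tail = FALSE)
    w <- stats::dnorm(z)^2 * nBoot / (bp[usable] * (1 - bp[usable]))
    X <- cbind(sqrt(r), 1 / sqrt(r))
    A <- crossprod(X, w * X)
    b <- crossprod(X, w * z)
    cf <- solve(A, b)
    cov <- solve(A)
    v <- cf[1]; cc <- cf[2]
    au <- stats::pnorm(v - cc, lower.tail = FALSE)
    bpModel <- stats::pnorm(v + cc, lower.tail = FALSE)
    seVC <- sqrt(max(cov[1, 1] + cov[2, 2] - 2 * cov[1, 2], 0))
    seAU <- stats::dnorm(v - cc) * seVC
    out[e, ] <- list(au, edgeBP, bpModel, seAU, v, cc,
                     as.integer(sum(usable) - 2L), FALSE)
  }
  out
}

#' UPGMA clustering with multiscale-bootstrap AU/BP support
#'
#' The full uncertainty assessment: builds the correlation-distance UPGMA
#' tree, runs `nBoot` bootstrap replicates at each resampling scale
#' (feature rows are the resampling units), and attaches AU and BP
#' p-values with standard errors to every internal edge via
#' [multiscaleAU()]. Edges are numbered in merge order (increasing
#' height), as in the edge-numbered dendrograms this mirrors.
#'
#' @param features feature matrix (features x complexes).
#' @param nBoot bootstrap replicates per scale (default 10000).
#' @param scales scale multipliers; must include 1.0
#'   (default `seq(0.5, 1.4, 0.1)`).
#' @param seed integer seed; the same seed, data and configuration give
#'   bit-identical results.
#' @return A [SupportedDendrogram-class].
#' @examples
#' fm <- simulateFeatureMatrix(9, 20, rep(1:3, each = 3),
#'                             contrast = 8, noise = 1, seed = 7)
#' dend <- msBootstrap(fm, nBoot = 200, seed = 7)
#' edgeSupport(dend)
#' @export
msBootstrap <- function(features, nBoot = 10000,
                        scales = seq(0.5, 1.4, by = 0.1), seed = 1) {
  features <- .checkBootInputs(features, nBoot, scales)
  if (!any(abs(scales - 1) < 1e-9))
    stop("scales must include 1.0")
  hc <- upgma(correlationDistance(features))
  counts <- boot_counts_cpp(features, .refSetsMatrix(hc),
                            .sampleSizes(nrow(features), scales),
                            as.integer(nBoot), as.numeric(seed))
  fit <- multiscaleAU(counts, nBoot, scales)
  members <- .edgeMembers(hc)
  edges <- cbind(
    data.frame(
      edge = seq_along(members),
      members = vapply(members, function(m)
        paste(hc$labels[m], collapse = "+"), character(1)),
      height = hc$height, stringsAsFactors = FALSE),
    fit)
  new("SupportedDendrogram", hclust = unclass(hc), edges = edges,
      nBoot = as.integer(nBoot), scales = as.numeric(scales),
      seed = as.integer(seed))
}

#' Write the per-edge support report as CSV
#'
#' @param x a [SupportedDendrogram-class].
#' @param path output file.
#' @export
writeEdgeReportCSV <- function(x, path) {
  utils::write.csv(edgeSupport(x), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
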