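## Hierarchical clustering of complexes by surface similarity:
## correlation distance + unweighted average linkage (UPGMA), with a fixed
## tie rule so trees are bit-reproducible across platforms.

#' Correlation distance between complexes
#'
#' `d(i, j) = 1 - Pearson correlation` of the two complexes' feature
#' vectors (columns of the feature matrix); bounded in \[0, 2\].
#'
#' @param features numeric matrix, features x complexes (>= 2 features).
#' @return a `stats::dist` object with complex labels.
#' @export
correlationDistance <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need at least 2 features per complex")
  v <- apply(features, 2, stats::var)
  if (any(v == 0)) {
    bad <- colnames(features)[v == 0] %||% which(v == 0)
    stop("zero-variance feature column(s): undefined correlation for ",
         paste(bad, collapse = ", "))
  }
  stats::as.dist(1 - stats::cor(features))
}

## UPGMA with deterministic tie-breaking: among equally distant pairs the
## pair with the lexicographically smallest (min leaf index, max leaf
## index) representatives merges first. Returns a stats::hclust object.

#' Unweighted average-linkage (UPGMA) clustering
#'
#' Merged-cluster distance is the size-weighted mean of the member
#' clusters' distances, i.e. the plain mean over all cross pairs of the
#' original distance matrix; merge heights are those distances. Ties are
#' broken by the smallest pair of minimal original leaf indices, making
#' the tree a pure function of the distance matrix.
#'
#' @param d a `dist` object or symmetric matrix with labels (n >= 2,
#'   no NA/NaN).
#' @return an object of class `hclust` (method `"upgma"`).
#' @export
upgma <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 2L) stop("need at least 2 items to cluster")
  if (any(is.na(dm))) stop("distance matrix contains NA/NaN")
  labels <- rownames(dm) %||% as.character(seq_len(n))

  size <- rep(1L, n)
  rep_ <- seq_len(n)            # min original leaf index per cluster
  node <- -seq_len(n)           # hclust coding: leaves negative
  active <- seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- vector("list", n - 1L)
  memb <- as.list(seq_len(n))

  for (step in seq_len(n - 1L)) {
    best <- Inf; bi <- 0L; bj <- 0L; bra <- Inf; brb <- Inf
    na <- length(active)
    for (a in seq_len(na - 1L)) {
      ia <- active[a]
      for (b in (a + 1L):na) {
        ib <- active[b]
        dd <- dm[ia, ib]
        ra <- min(rep_[ia], rep_[ib]); rb <- max(rep_[ia], rep_[ib])
        if (dd < best ||
            (dd == best && (ra < bra || (ra == bra && rb < brb)))) {
          best <- dd; bi <- ia; bj <- ib; bra <- ra; brb <- rb
        }
      }
    }
    for (ic in setdiff(active, c(bi, bj))) {
      nd <- (size[bi] * dm[bi, ic] + size[bj] * dm[bj, ic]) /
        (size[bi] + size[bj])
      dm[bi, ic] <- nd; dm[ic, bi] <- nd
    }
    merge[step, ] <- sort(c(node[bi], node[bj]))
    height[step] <- best
    memb[[bi]] <- sort(c(memb[[bi]], memb[[bj]]))
    members[[step]] <- memb[[bi]]
    size[bi] <- size[bi] + size[bj]
    rep_[bi] <- bra
    node[bi] <- step
    active <- setdiff(active, bj)
  }

  order <- .hclustOrder(merge, n)
  hc <- list(merge = merge, height = height, order = order, labels = labels,
             method = "upgma", call = match.call(),
             dist.method = "correlation")
  attr(hc, "members") <- members
  class(hc) <- "hclust"
  hc
}

.hclustOrder <- function(merge, n) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

## Leaf-index membership sets per internal edge, in merge order.
.edgeMembers <- function(hc) {
  m <- attr(hc, "members")
  if (!is.null(m)) return(m)
  n <- length(hc$labels)
  out <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    kids <- hc$merge[step, ]
    out[[step]] <- sort(unlist(lapply(kids, function(k)
      if (k < 0L) -k else out[[k]])))
  }
  out
}

#' Cut a dendrogram at a threshold height
#'
#' Clusters are the maximal subtrees whose internal merge heights are all
#' strictly below `h`: `h = 0` gives all singletons, `h` above the root
#' height gives one cluster. This realizes a "cross-reactivity threshold"
#' on the structural dendrogram.
#'
#' @param x a [SupportedDendrogram-class] or `hclust`.
#' @param h threshold height (>= 0).
#' @return named integer vector of cluster memberships (clusters numbered
#'   by their smallest leaf index).
#' @export
cutDendrogram <- function(x, h) {
  hc <- if (is(x, "SupportedDendrogram")) asHclust(x) else x
  stopifnot(h >= 0)
  n <- length(hc$labels)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i] <- parent[parent[i]]; i }
  node2cl <- integer(n - 1L)
  for (step in seq_len(max(n - 1L, 0L))) {
    if (hc$height[step] >= h) { node2cl[step] <- 0L; next }
    kids <- hc$merge[step, ]
    reps <- vapply(kids, function(k)
      if (k < 0L) find(-k) else find(node2cl[k]), integer(1))
    parent[reps[2]] <- reps[1]
    node2cl[step] <- reps[1]
  }
  roots <- vapply(seq_len(n), find, integer(1))
  minLeaf <- vapply(split(seq_len(n), roots), min, integer(1))
  ids <- stats::setNames(rank(minLeaf), names(minLeaf))
  out <- as.integer(ids[as.character(roots)])
  names(out) <- hc$labels
  out
}

#' Newick export with optional AU/BP support labels
#'
#' Branch lengths follow the midpoint (ultrametric) convention: a leaf
#' under a merge at height h gets branch h/2, an internal child at height
#' h_c under a parent at h_p gets (h_p - h_c)/2; two leaves merging at 0.2
#' give `"(A:0.1,B:0.1);"`. With `support = TRUE` internal nodes are
#' labelled `"AU|BP"` to 2 decimals.
#'
#' @param x a [SupportedDendrogram-class], or an `hclust`
#'   (then `support` must be FALSE).
#' @param support attach AU/BP labels to internal nodes.
#' @param path optional file to write to.
#' @return the Newick string (invisibly if `path` is given).
#' @export
toNewick <- function(x, support = TRUE, path = NULL) {
  if (is(x, "SupportedDendrogram")) {
    hc <- asHclust(x)
    edges <- x@edges
  } else {
    hc <- x
    if (support) stop("support labels require a SupportedDendrogram")
    edges <- NULL
  }
  n <- length(hc$labels)
  minLeaf <- function(node) {
    if (node < 0L) return(-node)
    min(vapply(hc$merge[node, ], minLeaf, integer(1)))
  }
  build <- function(node, parentH) {
    if (node < 0L)
      return(sprintf("%s:%g", hc$labels[-node], parentH / 2))
    h <- hc$height[node]
    kids0 <- hc$merge[node, ]
    kids0 <- kids0[order(vapply(kids0, minLeaf, integer(1)))]
    kids <- vapply(kids0, build, character(1), parentH = h)
    lab <- if (support && !is.null(edges))
      sprintf("%.2f|%.2f", edges$au[node], edges$bp[node]) else ""
    if (is.na(parentH))
      sprintf("(%s)%s", paste(kids, collapse = ","), lab)
    else
      sprintf("(%s)%s:%g", paste(kids, collapse = ","), lab,
              (parentH - h) / 2)
  }
  nwk <- paste0(build(n - 1L, NA_real_), ";")
  if (!is.null(path)) { writeLines(nwk, path); return(invisible(nwk)) }
  nwk
}

#' Write the square labelled distance matrix as CSV
#'
#' @param d a `dist` object.
#' @param path output file.
#' @export
writeDistanceCSV <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
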