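#' Accessors and show methods
#'
#' Small accessor generics so downstream code never touches slots directly.
#' @name accessors
#' @keywords internal
NULL

#' @describeIn accessors atom table of a ChargedStructure
#' @param x object
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @export
setMethod("atoms", "ChargedStructure", function(x) x@atoms)

#' @describeIn accessors number of atoms
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @export
setMethod("nAtoms", "ChargedStructure", function(x) nrow(x@atoms))

#' @describeIn accessors complex label
#' @export
setGeneric("structureLabel", function(x) standardGeneric("structureLabel"))

#' @export
setMethod("structureLabel", "ChargedStructure", function(x) x@label)

#' @export
setMethod("structureLabel", "SurfaceImage", function(x) x@label)

#' @describeIn accessors atom coordinates as an n x 3 matrix
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @export
setMethod("coords", "ChargedStructure", function(x)
  as.matrix(x@atoms[, c("x", "y", "z")]))

#' @describeIn accessors atom partial charges (e); NA when unset
#' @export
setGeneric("charges", function(x) standardGeneric("charges"))

#' @export
setMethod("charges", "ChargedStructure", function(x) x@atoms$charge)

#' @describeIn accessors per-internal-edge support table of a dendrogram
#' @export
setGeneric("edgeSupport", function(x) standardGeneric("edgeSupport"))

#' @export
setMethod("edgeSupport", "SupportedDendrogram", function(x) x@edges)

#' @describeIn accessors the underlying hclust merge tree
#' @export
setGeneric("asHclust", function(x) standardGeneric("asHclust"))

#' @export
setMethod("asHclust", "SupportedDendrogram", function(x) {
  hc <- x@hclust
  class(hc) <- "hclust"
  hc
})

setMethod("show", "ChargedStructure", function(object) {
  a <- object@atoms
  ch <- a$charge
  netq <- if (all(is.na(ch))) "unset" else sprintf("%+.2f e", sum(ch, na.rm = TRUE))
  cat("ChargedStructure \"", object@label, "\": ", nrow(a), " atoms, ",
      length(unique(a$chain)), " chain(s) [",
      paste(unique(a$chain), collapse = ","), "], net charge ", netq, "\n",
      sep = "")
})

setMethod("show", "ElectrostaticModel", function(object) {
  cat(sprintf(
    "ElectrostaticModel: mode=%s eps_in=%g eps_out=%g I=%g M T=%g K grid=%g A pad=%g A\n",
    object@mode, object@epsIn, object@epsOut, object@ionicStrength,
    object@temperature, object@gridSpacing, object@gridPadding))
})

setMethod("show", "GridPotential", function(object) {
  d <- dim(object@values)
  cat(sprintf("GridPotential: %d x %d x %d nodes, spacing %g A, phi in [%.3g, %.3g] kT/e\n",
              d[1], d[2], d[3], object@spacing,
              min(object@values), max(object@values)))
})

setMethod("show", "SurfaceImage", function(object) {
  d <- dim(object@mask)
  cat(sprintf(
    "SurfaceImage \"%s\": %d x %d px (%.1f A/px), %.0f%% molecule, %s\n",
    object@label, d[1], d[2], object@pixelSize,
    100 * mean(object@mask),
    if (length(object@rgb)) sprintf("rendered (clamp %g kT/e)", object@clamp)
    else "not rendered"))
})

setMethod("show", "RegionGrid", function(object) {
  cat(sprintf("RegionGrid: %d x %d regions over x[%g, %g] y[%g, %g]%s\n",
              object@nx, object@ny, object@window[1], object@window[2],
              object@window[3], object@window[4],
              if (length(object@excluded))
                paste0(", excluded: ", paste(object@excluded, collapse = ","))
              else ""))
})

setMethod("show", "SupportedDendrogram", function(object) {
  n <- length(object@hclust$labels)
  cat(sprintf(
    "SupportedDendrogram: %d leaves, %d internal edges; n_boot=%d x %d scales, seed=%d\n",
    n, nrow(object@edges), object@nBoot, length(object@scales), object@seed))
  if (nrow(object@edges)) {
    e <- object@edges
    cat(sprintf("  AU in [%.3f, %.3f], max SE(AU) = %.4f\n",
                min(e$au), max(e$au), max(e$se.au, na.rm = TRUE)))
  }
})

setMethod("show", "CrossReactivityNetwork", function(object) {
  cat(sprintf(
    "CrossReactivityNetwork: %d peptides (%s), %d reactive edge(s), %d tested-negative pair(s)\n",
    nrow(object@peptides), unique(object@peptides$mhc),
    nrow(object@edges), nrow(object@nonEdges)))
})

setMethod("show", "ToyGrooveSpec", function(object) {
  cat(sprintf(
    "ToyGrooveSpec \"%s\": floor %d x %d @ %.1f A, peptide L=%d charges [%s]%s\n",
    object@label, object@nx, object@ny, object@spacing,
    length(object@peptideCharges),
    paste(sprintf("%+d", as.integer(object@peptideCharges)), collapse = ""),
    if (is.na(object@spicyPosition)) ""
    else sprintf(", spicy at P%d", object@spicyPosition)))
})
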