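#' @import methods
NULL

## Atom table column contract shared by validity checks and constructors.
.atomCols <- c("serial", "name", "resname", "chain", "resno",
               "x", "y", "z", "radius", "charge")

#' ChargedStructure: atoms with coordinates, radii and partial charges
#'
#' The central container of the package: an ordered atom table (one row per
#' heavy atom) together with the bookkeeping needed to treat the molecule as a
#' pMHC-like "groove" (which chains form the MHC groove plus peptide, how long
#' the peptide is, and a display label). Coordinates are in Angstrom, charges
#' in elementary charges (e). Charges may be `NA` ("unset") until
#' [assignCharges()] or a generator fills them in.
#'
#' @slot atoms data.frame with columns `serial`, `name`, `resname`, `chain`,
#'   `resno`, `x`, `y`, `z`, `radius` (Angstrom, > 0), `charge` (e, in
#'   \[-2, 2\] or `NA` when unset).
#' @slot grooveChains character; chain ids of the MHC heavy chain and peptide.
#' @slot peptideLength integer; number of peptide positions.
#' @slot label character; complex identifier.
#'
#' @seealso [readPDB()], [assignCharges()], [canonicalOrient()],
#'   [makeToyGroove()]
#' @export
setClass("ChargedStructure",
         representation(atoms = "data.frame",
                        grooveChains = "character",
                        peptideLength = "integer",
                        label = "character"))

setValidity("ChargedStructure", function(object) {
  a <- object@atoms
  if (nrow(a) < 1L) return("structure must contain at least one atom")
  missing <- setdiff(.atomCols, names(a))
  if (length(missing))
    return(paste("atom table lacks columns:", paste(missing, collapse = ", ")))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) return("non-finite atom coordinates")
  if (!all(is.finite(a$radius)) || any(a$radius <= 0))
    return("atom radii must be finite and > 0")
  ch <- a$charge[!is.na(a$charge)]
  if (length(ch) && (any(!is.finite(ch)) || any(ch < -2) || any(ch > 2)))
    return("assigned charges must be finite and within [-2, 2] e")
  if (length(object@label) != 1L) return("label must be a single string")
  TRUE
})

#' CanonicalFrame: the rigid motion placing a structure in the canonical pose
#'
#' Produced by [canonicalOrient()]. `rotation` is a proper (det = +1)
#' orthonormal 3x3 matrix; transformed coordinates are
#' `x' = rotation %*% x + translation`.
#'
#' @slot rotation 3x3 proper orthonormal matrix.
#' @slot translation length-3 numeric, Angstrom.
#' @slot rmsd numeric; RMSD of the fitted atoms to the reference, Angstrom.
#' @export
setClass("CanonicalFrame",
         representation(rotation = "matrix",
                        translation = "numeric",
                        rmsd = "numeric"))

setValidity("CanonicalFrame", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation must be orthonormal")
  if (abs(det(R) - 1) > 1e-9)
    return("rotation must be proper (det = +1)")
  if (length(object@translation) != 3L) return("translation must be length 3")
  if (object@rmsd < 0) return("rmsd must be >= 0")
  TRUE
})

#' ElectrostaticModel: physical parameters of the potential calculation
#'
#' @slot mode `"coulomb-dh"` (screened Coulomb, the pipeline default) or
#'   `"fd-linear-pb"` (finite-difference linearized Poisson-Boltzmann).
#' @slot epsIn relative dielectric of the molecular interior (default 4).
#' @slot epsOut relative dielectric of the solvent (default 80).
#' @slot ionicStrength mol/L of 1:1 salt (default 0.145).
#' @slot temperature Kelvin (default 298.15).
#' @slot gridSpacing Angstrom, PB grid spacing (default 1.0).
#' @slot gridPadding Angstrom of solvent added around the structure (default 10).
#'
#' @seealso [electroModel()], [screenedCoulomb()], [solveLinearPB()]
#' @export
setClass("ElectrostaticModel",
         representation(mode = "character",
                        epsIn = "numeric",
                        epsOut = "numeric",
                        ionicStrength = "numeric",
                        temperature = "numeric",
                        gridSpacing = "numeric",
                        gridPadding = "numeric"))

setValidity("ElectrostaticModel", function(object) {
  if (!object@mode %in% c("coulomb-dh", "fd-linear-pb"))
    return("mode must be 'coulomb-dh' or 'fd-linear-pb'")
  if (object@epsIn <= 0 || object@epsOut <= 0)
    return("dielectric constants must be > 0")
  if (object@ionicStrength < 0) return("ionic strength must be >= 0")
  if (object@temperature <= 0) return("temperature must be > 0 K")
  if (object@gridSpacing <= 0) return("grid spacing must be > 0")
  if (object@gridPadding < 0) return("grid padding must be >= 0")
  TRUE
})

#' GridPotential: a scalar potential field on a cubic grid
#'
#' @slot origin length-3 numeric; coordinates of grid node (1,1,1), Angstrom.
#' @slot spacing numeric, Angstrom.
#' @slot values 3D numeric array (kT/e), dims >= 3 per axis.
#' @export
setClass("GridPotential",
         representation(origin = "numeric",
                        spacing = "numeric",
                        values = "array"))

setValidity("GridPotential", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L || any(d < 3L)) return("values must be a 3D array, >= 3 nodes per axis")
  if (!all(is.finite(object@values))) return("potential values must be finite")
  if (length(object@origin) != 3L) return("origin must be length 3")
  if (object@spacing <= 0) return("spacing must be > 0")
  TRUE
})

#' SurfaceImage: the fixed-orientation TCR-interacting surface raster
#'
#' A top-down orthographic raster of the canonical-frame structure over a
#' rectangular window. `height[i, j]` is the solvent-accessible top of the
#' molecule above pixel center `(x_i, y_j)`; `potential` is the electrostatic
#' potential sampled on that surface; `rgb` is the rendered image
#' (red = negative, white = 0, blue = positive, clamped at +/- `clamp` kT/e);
#' `mask` is TRUE where the molecule is present.
#'
#' @slot window numeric length 4: (x_min, x_max, y_min, y_max), Angstrom.
#' @slot pixelSize Angstrom per pixel (default 0.5).
#' @slot height numeric matrix (nx x ny), Angstrom; NA on background.
#' @slot potential numeric matrix (nx x ny), kT/e; 0 on background.
#' @slot rgb integer array (nx x ny x 3), 0..255; white on background.
#' @slot mask logical matrix (nx x ny).
#' @slot clamp numeric; rendering clamp in kT/e (5 once rendered).
#' @slot label character; complex identifier.
#' @export
setClass("SurfaceImage",
         representation(window = "numeric",
                        pixelSize = "numeric",
                        height = "matrix",
                        potential = "matrix",
                        rgb = "array",
                        mask = "matrix",
                        clamp = "numeric",
                        label = "character"))

setValidity("SurfaceImage", function(object) {
  if (length(object@window) != 4L) return("window must be (x_min, x_max, y_min, y_max)")
  if (object@window[2] <= object@window[1] || object@window[4] <= object@window[3])
    return("window must have positive extent")
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  d <- dim(object@mask)
  if (!identical(dim(object@height), d)) return("height/mask dimensions differ")
  if (length(object@potential) && !identical(dim(object@potential), d))
    return("potential/mask dimensions differ")
  if (length(object@rgb) && !identical(dim(object@rgb)[1:2], d))
    return("rgb/mask dimensions differ")
  if (length(object@potential)) {
    ph <- object@potential[object@mask]
    if (any(!is.finite(ph))) return("potential must be finite where mask is TRUE")
  }
  TRUE
})

#' RegionGrid: the predetermined regions used for feature extraction
#'
#' A regular `nx` x `ny` tiling of the surface window. Regions are indexed
#' row-major from (x_min, y_min): index = (iy - 1) * nx + ix. Regions listed
#' in `excluded` are dropped from descriptors (region masking).
#'
#' @slot nx,ny integer region counts (defaults 8 x 4).
#' @slot window numeric length 4, as in [SurfaceImage-class].
#' @slot excluded integer vector of excluded region indices.
#' @seealso [regionGrid()], [maskRegions()], [extractFeatures()]
#' @export
setClass("RegionGrid",
         representation(nx = "integer", ny = "integer",
                        window = "numeric", excluded = "integer"))

setValidity("RegionGrid", function(object) {
  n <- object@nx * object@ny
  if (n < 2L) return("need at least 2 regions")
  if (length(object@window) != 4L) return("window must be length 4")
  if (length(object@excluded)) {
    if (any(object@excluded < 1L | object@excluded > n))
      return("excluded indices out of range")
    if (length(setdiff(seq_len(n), object@excluded)) < 1L)
      return("cannot exclude every region")
  }
  TRUE
})

#' SupportedDendrogram: a UPGMA tree with AU/BP support on its edges
#'
#' Wraps an `hclust`-compatible merge tree (correlation distance, average
#' linkage) and a per-internal-edge support table from the multiscale
#' bootstrap: approximately unbiased p-value (AU) with delta-method standard
#' error, bootstrap probability (BP) at scale 1, and the probit-fit
#' diagnostics (v, c, degrees of freedom).
#'
#' @slot hclust the merge tree (class `hclust`), UPGMA over correlation distance.
#' @slot edges data.frame, one row per internal edge in merge order: `edge`,
#'   `members` (label sets joined by "+"), `height`, `au`, `bp`, `bp.model`,
#'   `se.au`, `v`, `c`, `df`, `degenerate`.
#' @slot nBoot integer; bootstrap replicates per scale.
#' @slot scales numeric; resampling scale multipliers.
#' @slot seed integer; bootstrap seed.
#' @seealso [msBootstrap()], [edgeSupport()], [cutDendrogram()], [toNewick()]
#' @export
setClass("SupportedDendrogram",
         representation(hclust = "list",
                        edges = "data.frame",
                        nBoot = "integer",
                        scales = "numeric",
                        seed = "integer"))

setValidity("SupportedDendrogram", function(object) {
  hc <- object@hclust
  if (!all(c("merge", "height", "labels", "order") %in% names(hc)))
    return("hclust slot must carry merge/height/labels/order")
  e <- object@edges
  if (nrow(e)) {
    if (any(e$au < -1e-12 | e$au > 1 + 1e-12, na.rm = TRUE))
      return("AU values must lie in [0, 1]")
    if (any(e$bp < -1e-12 | e$bp > 1 + 1e-12, na.rm = TRUE))
      return("BP values must lie in [0, 1]")
  }
  if (is.unsorted(hc$height)) return("merge heights must be non-decreasing")
  TRUE
})

#' CrossReactivityNetwork: observed reactions between peptides under one MHC
#'
#' Nodes are peptides (all restricted by the same MHC allotype); directed
#' edges are experimentally observed cross-reactive responses with a strength
#' class (`strong`/`weak`); `nonEdges` records pairs tested and found
#' non-cross-reactive. Edge direction encodes which T-cell line (primed on
#' `source`) recognized `target`.
#'
#' @slot peptides data.frame with columns `id`, `sequence`, `mhc`.
#' @slot edges data.frame with columns `source`, `target`, `strength`.
#' @slot nonEdges data.frame with columns `source`, `target`.
#' @seealso [crossReactivityNetwork()], [readNetwork()], [evaluatePartition()]
#' @export
setClass("CrossReactivityNetwork",
         representation(peptides = "data.frame",
                        edges = "data.frame",
                        nonEdges = "data.frame"))

setValidity("CrossReactivityNetwork", function(object) {
  p <- object@peptides
  if (!all(c("id", "sequence", "mhc") %in% names(p)))
    return("peptides must have id, sequence, mhc")
  if (anyDuplicated(p$id)) return("duplicate peptide ids")
  if (length(unique(p$mhc)) > 1L)
    return("all peptides in one network must share a single MHC restriction")
  if (!all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", p$sequence)))
    return("sequences must use the 20-letter amino-acid alphabet")
  if (any(nchar(p$sequence) < 8L)) return("peptide sequences must be >= 8 residues")
  ids <- p$id
  for (slot in list(object@edges, object@nonEdges)) {
    if (nrow(slot) && !all(c(slot$source, slot$target) %in% ids))
      return("edge endpoints must be declared peptides")
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  if (nrow(object@edges) && nrow(object@nonEdges)) {
    k1 <- key(object@edges$source, object@edges$target)
    k2 <- key(object@nonEdges$source, object@nonEdges$target)
    if (length(intersect(k1, k2)))
      return("edges and nonEdges must be disjoint pairs")
  }
  TRUE
})

#' ToyGrooveSpec: deterministic specification of a pMHC-like toy groove
#'
#' The synthetic stand-in for a pMHC complex: a neutral floor lattice
#' (z = 0), two flanking rim rows carrying fixed alternating charges (the
#' conserved "MHC context", z = 2), and a peptide row along x (y = 0, z = 3)
#' whose per-position charges are controlled. An optional "spicy" position is
#' raised to z = 6, emulating a prominent TCR-exposed feature such as an
#' arginine at P7.
#'
#' @slot nx,ny integer floor lattice dimensions (defaults 9 x 5).
#' @slot spacing lattice spacing, Angstrom (default 3.5).
#' @slot peptideCharges numeric in \{-1, 0, +1\}, one per peptide position
#'   (length 8-11).
#' @slot spicyPosition integer or NA; peptide position raised to z = 6.
#' @slot rimCharge numeric; magnitude of the alternating rim charges (0.25).
#' @slot atomRadius numeric; pseudo-atom radius, Angstrom (2.0).
#' @slot label character.
#' @seealso [toyGrooveSpec()], [makeToyGroove()], [makeToyFamily()]
#' @export
setClass("ToyGrooveSpec",
         representation(nx = "integer", ny = "integer", spacing = "numeric",
                        peptideCharges = "numeric", spicyPosition = "integer",
                        rimCharge = "numeric", atomRadius = "numeric",
                        label = "character"))

setValidity("ToyGrooveSpec", function(object) {
  L <- length(object@peptideCharges)
  if (L < 8L || L > 11L) return("peptide length must be within [8, 11]")
  if (!all(object@peptideCharges %in% c(-1, 0, 1)))
    return("peptide charges must be in {-1, 0, +1}")
  sp <- object@spicyPosition
  if (!is.na(sp) && (sp < 1L || sp > L))
    return("spicyPosition must index a peptide position")
  if (object@nx < 2L || object@ny < 2L) return("floor lattice must be >= 2 x 2")
  if (object@spacing <= 0 || object@atomRadius <= 0)
    return("spacing and atomRadius must be > 0")
  TRUE
})
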