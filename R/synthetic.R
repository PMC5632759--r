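## Deterministic pMHC-like toy structures with known ground truth.
##
## A toy groove emulates the features of a class I pMHC that the surface
## pipeline consumes: a neutral floor (the beta-sheet), two flanking rim
## rows with fixed alternating charges (the conserved alpha-helix "MHC
## context", identical across every toy so the canonical orientation is
## exact), and a controllable peptide row, optionally with one "spicy"
## prominent position raised towards the TCR. Geometry is a pure function
## of the spec; randomness only enters named, seeded generators.

#' Construct a toy-groove specification
#'
#' Geometry defaults: floor lattice 9 x 5 at 3.5 Angstrom spacing in the
#' z = 0 plane; rim rows above the outermost floor rows at z = 2 with
#' alternating +/- 0.25 e charges; peptide positions along x at y = 0,
#' z = 3 (z = 6 at the spicy position); pseudo-atom radius 2 Angstrom.
#' The 3.5 Angstrom spacing with a 1.4 Angstrom probe gives a fully
#' connected projected surface at 0.5 Angstrom pixels.
#'
#' @param peptideCharges numeric vector over \{-1, 0, +1\}, length 8-11;
#'   one entry per peptide position.
#' @param spicyPosition optional peptide position (e.g. 7 for the
#'   "arginine at P7" motif) whose pseudo-atom is raised to z = 6.
#' @param label complex label.
#' @param nx,ny floor lattice dimensions.
#' @param spacing lattice spacing, Angstrom.
#' @param rimCharge magnitude of the alternating rim charges, e.
#' @param atomRadius pseudo-atom radius, Angstrom.
#' @return A [ToyGrooveSpec-class].
#' @export
toyGrooveSpec <- function(peptideCharges = rep(0, 8), spicyPosition = NA,
                          label = "toy", nx = 9, ny = 5, spacing = 3.5,
                          rimCharge = 0.25, atomRadius = 2.0) {
  new("ToyGrooveSpec", nx = as.integer(nx), ny = as.integer(ny),
      spacing = spacing, peptideCharges = as.numeric(peptideCharges),
      spicyPosition = as.integer(spicyPosition), rimCharge = rimCharge,
      atomRadius = atomRadius, label = label)
}

#' Build the ChargedStructure of a toy groove
#'
#' Deterministic: coordinates and charges are a pure function of the spec.
#' The groove (floor + rims) is chain A, the peptide chain P. Atom count
#' is exactly `nx*ny + 2*nx + L`. Optionally writes a standard PDB file
#' (charges stored in the B-factor column; see [writePDB()]). PDB stores no
#' radii, so a re-read toy gets the bundled per-element radius (P, 1.80
#' Angstrom) in place of the spec's `atomRadius`.
#'
#' @param spec a [ToyGrooveSpec-class].
#' @param path optional PDB output path.
#' @return A [ChargedStructure-class] in the canonical pose (floor z = 0,
#'   peptide axis +x, TCR face +z).
#' @export
makeToyGroove <- function(spec, path = NULL) {
  stopifnot(is(spec, "ToyGrooveSpec"))
  validObject(spec)
  L <- length(spec@peptideCharges)
  sp <- spec@spacing
  fx <- (seq_len(spec@nx) - (spec@nx + 1) / 2) * sp
  fy <- (seq_len(spec@ny) - (spec@ny + 1) / 2) * sp
  yRim <- max(fy)

  floorAt <- expand.grid(x = fx, y = fy)
  rims <- rbind(data.frame(x = fx, y = -yRim), data.frame(x = fx, y = yRim))
  rimQ <- rep(spec@rimCharge * c(1, -1), length.out = spec@nx)
  pz <- rep(3, L)
  if (!is.na(spec@spicyPosition)) pz[spec@spicyPosition] <- 6
  pep <- data.frame(x = (seq_len(L) - (L + 1) / 2) * sp, y = 0, z = pz)

  atoms <- data.frame(
    serial = seq_len(nrow(floorAt) + nrow(rims) + L),
    name = "PS",
    resname = c(rep("FLR", nrow(floorAt)), rep("RIM", nrow(rims)),
                rep("UNK", L)),
    chain = c(rep("A", nrow(floorAt) + nrow(rims)), rep("P", L)),
    resno = c(seq_len(nrow(floorAt) + nrow(rims)), seq_len(L)),
    x = c(floorAt$x, rims$x, pep$x),
    y = c(floorAt$y, rims$y, pep$y),
    z = c(rep(0, nrow(floorAt)), rep(2, nrow(rims)), pep$z),
    radius = spec@atomRadius,
    charge = c(rep(0, nrow(floorAt)), rep(rimQ, 2), spec@peptideCharges),
    stringsAsFactors = FALSE)

  s <- .newStructure(atoms, grooveChains = c("A", "P"),
                     peptideLength = L, label = spec@label)
  if (!is.null(path)) writePDB(s, path)
  s
}

#' Generate a family of toy grooves with a planted partition
#'
#' Members are defined by explicit peptide charge vectors (no hidden
#' randomness); the shared floor/rim context is identical across members,
#' so canonical orientation onto any member is exact. Labels must be
#' unique.
#'
#' @param base a [ToyGrooveSpec-class] providing geometry and defaults.
#' @param members named list of peptide charge vectors (names = labels).
#' @param partition grouping of members (vector alignable to `members`).
#' @param spicyPositions optional named list/vector of spicy positions per
#'   member (NA = none; default: the base spec's).
#' @return list with `structures` (list of [ChargedStructure-class]),
#'   `partition` (named integer vector), and `manifest` (data.frame
#'   linking label, charges and planted group).
#' @export
makeToyFamily <- function(base = toyGrooveSpec(), members, partition,
                          spicyPositions = NULL) {
  labels <- names(members)
  if (is.null(labels) || anyDuplicated(labels) || any(!nzchar(labels)))
    stop("members must carry unique non-empty labels")
  stopifnot(length(partition) == length(members))
  structures <- vector("list", length(members))
  for (i in seq_along(members)) {
    sp <- if (is.null(spicyPositions)) base@spicyPosition
          else as.integer(spicyPositions[[i]])
    spec <- initialize(base, peptideCharges = as.numeric(members[[i]]),
                       spicyPosition = sp, label = labels[i])
    structures[[i]] <- makeToyGroove(spec)
  }
  names(structures) <- labels
  part <- as.integer(factor(partition))
  names(part) <- labels
  manifest <- data.frame(
    label = labels,
    charges = vapply(members, function(q)
      paste(sprintf("%+d", as.integer(q)), collapse = ""), character(1)),
    group = part, row.names = NULL, stringsAsFactors = FALSE)
  list(structures = structures, partition = part, manifest = manifest)
}

#' Default two-group toy family (planted ground truth)
#'
#' Six complexes in two groups of three. The groups differ at two
#' group-defining peptide positions (an acidic patch at P4/P7 versus a
#' basic one); within a group, members additionally differ by one seeded
#' random charge mutation at a non-defining position, emulating escape
#' variants around a shared motif.
#'
#' @param nPerGroup members per group (default 3).
#' @param seed integer seed for the within-group mutations.
#' @param base geometry spec (peptide length taken from it).
#' @return as [makeToyFamily()].
#' @export
defaultToyFamily <- function(nPerGroup = 3, seed = 1,
                             base = toyGrooveSpec()) {
  L <- length(base@peptideCharges)
  defining <- c(4L, 7L)
  groupA <- groupB <- rep(0, L)
  groupA[defining] <- -1
  groupB[defining] <- +1
  free <- setdiff(seq_len(L), defining)
  set.seed(seed)
  members <- list()
  for (g in 1:2) {
    centre <- if (g == 1) groupA else groupB
    for (m in seq_len(nPerGroup)) {
      q <- centre
      pos <- free[sample.int(length(free), 1)]
      q[pos] <- sample(c(-1, 1), 1)
      members[[sprintf("g%d_m%d", g, m)]] <- q
    }
  }
  makeToyFamily(base, members, rep(1:2, each = nPerGroup))
}

#' Simulate a feature matrix with planted clusters
#'
#' Unit-level input for the clustering stage: one Gaussian centre per
#' planted group (standard normal scaled by `contrast`), members = centre
#' plus Gaussian noise of standard deviation `noise`. Fully determined by
#' the seed.
#'
#' @param nComplexes number of complexes (columns).
#' @param nFeatures number of features (rows, >= 4).
#' @param partition planted grouping, length `nComplexes`
#'   (default: two contiguous equal blocks).
#' @param contrast scale of the cluster centres.
#' @param noise within-group standard deviation.
#' @param seed integer seed.
#' @return features x complexes matrix with the planted partition in
#'   `attr(, "partition")`.
#' @export
simulateFeatureMatrix <- function(nComplexes, nFeatures,
                                  partition = rep(1:2, each = ceiling(nComplexes / 2),
                                                  length.out = nComplexes),
                                  contrast = 10, noise = 1, seed = 1) {
  if (nFeatures < 4L) stop("need at least 4 features")
  stopifnot(contrast >= 0, noise >= 0,
            length(partition) == nComplexes)
  grp <- as.integer(factor(partition))
  set.seed(seed)
  centres <- matrix(stats::rnorm(nFeatures * max(grp)), nFeatures) * contrast
  m <- centres[, grp, drop = FALSE] +
    matrix(stats::rnorm(nFeatures * nComplexes), nFeatures) * noise
  rownames(m) <- sprintf("f%02d", seq_len(nFeatures))
  colnames(m) <- sprintf("c%02d_g%d", seq_len(nComplexes), grp)
  attr(m, "partition") <- stats::setNames(grp, colnames(m))
  m
}
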