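## Structure input, charge assignment and canonical orientation.
##
## All complexes must end up in one canonical frame before their surfaces are
## comparable pixel-for-pixel: groove floor in the z ~ 0 plane, peptide N->C
## axis along +x, TCR side facing +z. The frame is defined by least-squares
## superposition onto a designated reference structure that is constructed
## (or chosen) in that pose.

.elementRadii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
.defaultRadius <- 1.70

.elementFromName <- function(name, elesy = NULL) {
  if (!is.null(elesy)) {
    e <- toupper(trimws(elesy))
    ok <- !is.na(e) & nzchar(e)
    if (any(!ok)) e[!ok] <- NA
  } else e <- rep(NA_character_, length(name))
  guess <- toupper(substr(gsub("^[0-9]", "", trimws(name)), 1L, 1L))
  ifelse(is.na(e), guess, e)
}

.radiusForElement <- function(elem) {
  r <- .elementRadii[elem]
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(elem[unknown]), collapse = ", "),
            "; using default radius ", .defaultRadius, " A", call. = FALSE)
    r[unknown] <- .defaultRadius
  }
  unname(r)
}

.newStructure <- function(atoms, grooveChains = unique(atoms$chain),
                          peptideLength = NA_integer_, label = "structure") {
  rownames(atoms) <- NULL
  new("ChargedStructure", atoms = atoms, grooveChains = grooveChains,
      peptideLength = as.integer(peptideLength), label = label)
}

#' Read a PDB file into a ChargedStructure
#'
#' Parses fixed-column ATOM records via [bio3d::read.pdb()]. By default
#' HETATM records and waters are excluded, and alternate locations are
#' resolved to the highest-occupancy conformer (ties go to altLoc "A").
#' Charges are left unset (`NA`) unless `chargesFrom = "bfactor"`, which
#' takes partial charges from the B-factor column (the convention used by
#' [writePDB()] for toy grooves). Radii are assigned per element from the
#' bundled table (C 1.70, N 1.55, O 1.52, S 1.80, default 1.70 Angstrom).
#'
#' @param path PDB file path.
#' @param keepHetatm keep HETATM records (waters are always dropped).
#' @param chargesFrom `"none"` (charges unset) or `"bfactor"`.
#' @param label complex label; defaults to the file name.
#' @return A [ChargedStructure-class].
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writePDB(makeToyGroove(toyGrooveSpec()), pdb)
#' readPDB(pdb, chargesFrom = "bfactor")
#' @export
readPDB <- function(path, keepHetatm = FALSE,
                    chargesFrom = c("none", "bfactor"), label = NULL) {
  chargesFrom <- match.arg(chargesFrom)
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("unreadable PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  if (!keepHetatm) a <- a[a$type == "ATOM", , drop = FALSE]
  a <- a[!(a$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(a) == 0L) stop("no ATOM records in '", path, "'")

  ## altLoc resolution: per (chain, resno, insert, atom name) keep the
  ## highest-occupancy conformer; ties resolved alphabetically ('A' first).
  alt <- ifelse(is.na(a$alt), "", a$alt)
  if (any(nzchar(alt))) {
    key <- paste(a$chain, a$resno, ifelse(is.na(a$insert), "", a$insert),
                 a$elety, sep = "\r")
    occ <- ifelse(is.na(a$o), 1, a$o)
    ord <- order(key, -occ, alt)
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(key[ord]), , drop = FALSE]
    a <- a[order(a$eleno), , drop = FALSE]
  }

  elem <- .elementFromName(a$elety, a$elesy)
  charge <- rep(NA_real_, nrow(a))
  if (chargesFrom == "bfactor") charge <- ifelse(is.na(a$b), 0, a$b)
  atoms <- data.frame(serial = a$eleno, name = a$elety, resname = a$resid,
                      chain = ifelse(is.na(a$chain), "A", a$chain),
                      resno = a$resno,
                      x = a$x, y = a$y, z = a$z,
                      radius = .radiusForElement(elem),
                      charge = charge, stringsAsFactors = FALSE)
  .newStructure(atoms, label = label %||% sub("\\.pdb$", "", basename(path)))
}

#' Write a ChargedStructure as a PDB file
#'
#' Coordinates are written with the standard fixed-column precision (1e-3
#' Angstrom); assigned partial charges are stored in the B-factor column so
#' that toy structures round-trip through [readPDB()] with
#' `chargesFrom = "bfactor"`.
#'
#' @param x a [ChargedStructure-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePDB <- function(x, path) {
  a <- atoms(x)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   eleno = a$serial, elety = a$name, resid = a$resname,
                   chain = a$chain, resno = a$resno,
                   o = rep(1, nrow(a)),
                   b = ifelse(is.na(a$charge), 0, a$charge))
  invisible(path)
}

## Formal residue charges: the minimal physiological-pH model sufficient to
## reproduce the +/- 5 kT/e red/blue surface patterning. His neutral by default.
.standardResidues <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                       "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                       "THR", "TRP", "TYR", "VAL")

#' Assign partial charges (and optionally radii) to a structure
#'
#' The `"formal-residue"` scheme places integer formal charges on the
#' standard titratable groups: Asp (-0.5 on each of OD1/OD2), Glu (-0.5 on
#' OE1/OE2), Lys (+1 on NZ), Arg (+0.5 on NH1/NH2), His neutral; +1 on each
#' chain's N-terminal amide nitrogen, and -1 split over the C-terminal
#' carboxylate oxygens (O/OXT). Every other atom is 0. Unknown residue names
#' get zero charge with a warning. The `"per-atom-table"` scheme matches a
#' user table by residue/atom name and may also override radii.
#'
#' Idempotent: charges are recomputed from scratch on every call.
#'
#' @param x a [ChargedStructure-class].
#' @param scheme `"formal-residue"` or `"per-atom-table"`.
#' @param table for `"per-atom-table"`: data.frame with columns `resname`,
#'   `name`, `charge` and optionally `radius`.
#' @return the structure with charges set.
#' @export
assignCharges <- function(x, scheme = c("formal-residue", "per-atom-table"),
                          table = NULL) {
  scheme <- match.arg(scheme)
  a <- atoms(x)
  a$charge <- 0

  if (scheme == "per-atom-table") {
    if (is.null(table) || !all(c("resname", "name", "charge") %in% names(table)))
      stop("per-atom-table scheme needs a table with resname, name, charge")
    key <- paste(a$resname, a$name)
    tkey <- paste(table$resname, table$name)
    hit <- match(key, tkey)
    a$charge[!is.na(hit)] <- table$charge[hit[!is.na(hit)]]
    if ("radius" %in% names(table))
      a$radius[!is.na(hit)] <- ifelse(is.na(table$radius[hit[!is.na(hit)]]),
                                      a$radius[!is.na(hit)],
                                      table$radius[hit[!is.na(hit)]])
  } else {
    unknown <- setdiff(unique(a$resname), .standardResidues)
    if (length(unknown))
      warning("unknown residue name(s) ", paste(unknown, collapse = ", "),
              "; assigned zero charge", call. = FALSE)
    set <- function(res, nm, q) {
      idx <- a$resname == res & a$name %in% nm
      a$charge[idx] <<- q
    }
    set("ASP", c("OD1", "OD2"), -0.5)
    set("GLU", c("OE1", "OE2"), -0.5)
    set("LYS", "NZ", +1)
    set("ARG", c("NH1", "NH2"), +0.5)
    ## chain termini
    for (ch in unique(a$chain)) {
      rows <- which(a$chain == ch)
      resnos <- a$resno[rows]
      first <- rows[resnos == min(resnos)]
      last <- rows[resnos == max(resnos)]
      nIdx <- first[a$name[first] == "N"]
      if (length(nIdx)) a$charge[nIdx[1]] <- a$charge[nIdx[1]] + 1
      cIdx <- last[a$name[last] %in% c("O", "OXT")]
      if (length(cIdx)) a$charge[cIdx] <- a$charge[cIdx] - 1 / length(cIdx)
    }
  }
  initialize(x, atoms = a)
}

#' Parse an atom selection in "chain:from-to" mini-language
#'
#' Comma-separated terms of the form `"A:1-182"` (1-based, inclusive) or
#' `"A"` (whole chain); `NULL` selects all atoms. An optional atom-name
#' filter (e.g. `"CA"`) restricts further.
#'
#' @param x a [ChargedStructure-class].
#' @param selection selection string or `NULL`.
#' @param atomNames optional character vector of atom names to keep.
#' @return integer atom indices into `atoms(x)`.
#' @export
selectAtoms <- function(x, selection = NULL, atomNames = NULL) {
  a <- atoms(x)
  keep <- rep(is.null(selection), nrow(a))
  if (!is.null(selection)) {
    for (term in strsplit(selection, ",", fixed = TRUE)[[1]]) {
      term <- trimws(term)
      m <- regmatches(term, regexec("^([^:]+)(?::(\\d+)-(\\d+))?$", term))[[1]]
      if (length(m) == 0L || !nzchar(m[2]))
        stop("cannot parse selection term '", term, "'")
      inChain <- a$chain == m[2]
      if (nzchar(m[3]))
        inChain <- inChain & a$resno >= as.integer(m[3]) &
          a$resno <= as.integer(m[4])
      keep <- keep | inChain
    }
  }
  if (!is.null(atomNames)) keep <- keep & a$name %in% atomNames
  which(keep)
}

## Kabsch: proper (det = +1) least-squares rotation of P onto Q.
.kabsch <- function(P, Q) {
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  C <- crossprod(Pc, Qc)
  sv <- svd(C)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- qc - as.numeric(R %*% pc)
  fitted <- sweep(Pc %*% t(R), 2, qc, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

#' Apply a rigid motion to a structure
#'
#' @param x a [ChargedStructure-class].
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 numeric.
#' @return the transformed structure.
#' @export
transformStructure <- function(x, rotation = diag(3), translation = c(0, 0, 0)) {
  a <- atoms(x)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  initialize(x, atoms = a)
}

#' Superpose a structure onto a reference (canonical orientation)
#'
#' Least-squares rigid superposition (proper rotation only, Kabsch) of the
#' selected atoms onto the matching atoms of the reference. Atoms are paired
#' by (chain, residue number, atom name). The reference defines the canonical
#' frame by construction: groove floor in z ~ 0, peptide axis +x, TCR face
#' +z. For real class I pMHCs the conventional fit set is the heavy-chain
#' Calpha trace, e.g. `selection = "A:1-182"`, `atomNames = "CA"`; toy
#' grooves fit on all floor/rim pseudo-atoms by default.
#'
#' @param x structure to orient.
#' @param reference the reference [ChargedStructure-class], already canonical.
#' @param selection fit-atom selection (see [selectAtoms()]); default all
#'   atoms shared with the reference.
#' @param atomNames optional atom-name filter for the fit set.
#' @return `list(structure = <oriented copy>, frame = <CanonicalFrame>)`.
#' @export
canonicalOrient <- function(x, reference, selection = NULL, atomNames = NULL) {
  ix <- selectAtoms(x, selection, atomNames)
  ir <- selectAtoms(reference, selection, atomNames)
  ax <- atoms(x)[ix, , drop = FALSE]
  ar <- atoms(reference)[ir, , drop = FALSE]
  kx <- paste(ax$chain, ax$resno, ax$name, sep = "\r")
  kr <- paste(ar$chain, ar$resno, ar$name, sep = "\r")
  shared <- intersect(kx, kr)
  if (length(shared) != length(kx) || length(shared) != length(kr)) {
    if (length(shared) < 3L)
      stop("selection resolves to fewer than 3 shared atom pairs")
    stop("selection resolves to different atom sets in structure (",
         length(kx), ") and reference (", length(kr), ")")
  }
  P <- as.matrix(ax[match(shared, kx), c("x", "y", "z")])
  Q <- as.matrix(ar[match(shared, kr), c("x", "y", "z")])
  if (nrow(P) < 3L) stop("need at least 3 atom pairs for superposition")
  sv2 <- svd(sweep(P, 2, colMeans(P)))$d
  if (sv2[2] < 1e-6 * max(sv2[1], 1))
    stop("fit atoms are collinear; cannot define a frame")
  k <- .kabsch(P, Q)
  frame <- new("CanonicalFrame", rotation = k$R, translation = k$t,
               rmsd = k$rmsd)
  list(structure = transformStructure(x, k$R, k$t), frame = frame)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
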