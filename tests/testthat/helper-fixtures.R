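## Shared fixtures and independent oracles, all built in code.

## A single charged pseudo-atom ("Born sphere") for the electrostatics oracles.
bornSphere <- function(q = 1, radius = 2, at = c(0, 0, 0)) {
  new("ChargedStructure",
      atoms = data.frame(serial = 1L, name = "PS", resname = "UNK",
                         chain = "A", resno = 1L,
                         x = at[1], y = at[2], z = at[3],
                         radius = radius, charge = q,
                         stringsAsFactors = FALSE),
      grooveChains = "A", peptideLength = NA_integer_, label = "sphere")
}

## Arbitrary multi-atom structure with given coordinates/charges.
pointCharges <- function(xyz, q, label = "points") {
  xyz <- matrix(xyz, ncol = 3)
  new("ChargedStructure",
      atoms = data.frame(serial = seq_len(nrow(xyz)), name = "PS",
                         resname = "UNK", chain = "A",
                         resno = seq_len(nrow(xyz)),
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                         radius = 1.5, charge = q,
                         stringsAsFactors = FALSE),
      grooveChains = "A", peptideLength = NA_integer_, label = label)
}

## Reference value of e^2/(4 pi eps0 kT) at 298.15 K, frozen from the
## CODATA constants (independent of the package's internal constant).
L_REF <- 560.456

## Random proper rotation from a seeded axis-angle draw.
randomRotation <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0.1, 3)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## Brute-force average-linkage oracle: cluster distances recomputed at
## every step as plain means over the ORIGINAL distance matrix (no
## Lance-Williams recursion). Returns merge membership sets and heights.
bruteForceUPGMA <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  sets <- list()
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- 0L; bj <- 0L
    for (a in seq_len(length(clusters) - 1L)) {
      for (b in (a + 1L):length(clusters)) {
        dd <- mean(dm[clusters[[a]], clusters[[b]]])
        if (dd < best) { best <- dd; bi <- a; bj <- b }
      }
    }
    merged <- sort(c(clusters[[bi]], clusters[[bj]]))
    sets[[length(sets) + 1L]] <- merged
    heights <- c(heights, best)
    clusters[[bi]] <- merged
    clusters[[bj]] <- NULL
  }
  list(sets = sets, heights = heights)
}

## Canonical string form of a tree's membership sets (order-free compare).
setKey <- function(sets) sort(vapply(sets, paste, character(1), collapse = ","))

## Minimal hand-written PDB text fixtures.
onePdbLine <- function(serial, name, resname, chain, resno, x, y, z,
                       occ = 1, b = 0, alt = " ", elem = "C") {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resname, chain, resno, x, y, z, occ, b, elem)
}

writeTextPDB <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}
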