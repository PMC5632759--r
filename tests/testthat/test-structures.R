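test_that("readPDB parses minimal fixed-column records and filters waters", {
  p <- writeTextPDB(c(
    onePdbLine(1, "CA", "GLY", "A", 1, 1.234, -2.5, 3.75),
    "HETATM    2  O   HOH A 100      0.000   0.000   0.000  1.00  0.00           O"))
  s <- readPDB(p)
  expect_s4_class(s, "ChargedStructure")
  expect_equal(nAtoms(s), 1L)
  expect_equal(unname(coords(s)[1, ]), c(1.234, -2.5, 3.75))
  expect_true(all(is.na(charges(s))))

  expect_error(readPDB(tempfile()), "cannot read")
  empty <- writeTextPDB(character(0))
  expect_error(readPDB(empty), "no ATOM|unreadable")
})

test_that("alternate locations resolve to highest occupancy, ties to altLoc A", {
  p <- writeTextPDB(c(
    onePdbLine(1, "CA", "GLY", "A", 1, 0, 0, 0, occ = 0.4, alt = "A"),
    onePdbLine(2, "CA", "GLY", "A", 1, 5, 0, 0, occ = 0.6, alt = "B"),
    onePdbLine(3, "CB", "ALA", "A", 2, 1, 1, 1, occ = 0.5, alt = "B"),
    onePdbLine(4, "CB", "ALA", "A", 2, 2, 2, 2, occ = 0.5, alt = "A")))
  s <- readPDB(p)
  expect_equal(nAtoms(s), 2L)
  a <- atoms(s)
  expect_equal(a$x[a$resno == 1], 5)    # 0.6 conformer wins
  expect_equal(a$x[a$resno == 2], 2)    # tie: altLoc A wins
})

test_that("toy groove PDB round-trips atoms, coordinates and charges", {
  spec <- toyGrooveSpec(peptideCharges = c(0, 1, 0, -1, 0, 0, 1, 0),
                        spicyPosition = 7, label = "rt")
  s <- makeToyGroove(spec)
  p <- tempfile(fileext = ".pdb")
  writePDB(s, p)
  s2 <- readPDB(p, chargesFrom = "bfactor")
  expect_equal(nAtoms(s2), nAtoms(s))
  expect_lt(max(abs(coords(s2) - coords(s))), 1e-3)
  expect_equal(charges(s2), charges(s), tolerance = 1e-2)
})

test_that("formal-residue charges follow the titratable-group table", {
  mkRes <- function(serial, resname, names, chain, resno, elems)
    mapply(onePdbLine, serial, names, resname, chain, resno,
           x = seq_along(names), y = 0, z = 0, elem = elems)
  ## chain A: Gly-Lys-Gly (Lys mid-chain isolates the side-chain rule)
  ## chain B: a single Asp (termini + carboxylate combine)
  p <- writeTextPDB(c(
    mkRes(1:4, "GLY", c("N", "CA", "C", "O"), "A", 1, c("N", "C", "C", "O")),
    mkRes(5:9, "LYS", c("N", "CA", "C", "O", "NZ"), "A", 2,
          c("N", "C", "C", "O", "N")),
    mkRes(10:13, "GLY", c("N", "CA", "C", "O"), "A", 3, c("N", "C", "C", "O")),
    mkRes(14:19, "ASP", c("N", "CA", "C", "O", "OD1", "OD2"), "B", 1,
          c("N", "C", "C", "O", "O", "O"))))
  s <- assignCharges(readPDB(p))
  a <- atoms(s)
  lys <- a[a$resname == "LYS", ]
  expect_equal(lys$charge[lys$name == "NZ"], 1)
  expect_equal(sum(lys$charge), 1)          # only NZ charged mid-chain
  asp <- a[a$chain == "B", ]
  expect_equal(asp$charge[asp$name == "OD1"], -0.5)
  expect_equal(asp$charge[asp$name == "OD2"], -0.5)
  ## free residue: N-term +1, C-term O -1, side chain -1 => net -1
  expect_equal(sum(asp$charge), -1)
  ## chain A termini: N of res 1 is +1, O of res 3 is -1
  expect_equal(a$charge[a$resno == 1 & a$chain == "A" & a$name == "N"], 1)
  expect_equal(a$charge[a$resno == 3 & a$chain == "A" & a$name == "O"], -1)
  ## element radii from the bundled table
  expect_equal(sort(unique(a$radius)), c(1.52, 1.55, 1.70))
  ## idempotence
  expect_equal(atoms(assignCharges(s))$charge, a$charge)
})

test_that("unknown residues and elements warn and fall back", {
  p <- writeTextPDB(onePdbLine(1, "XX", "XYZ", "A", 1, 0, 0, 0, elem = "Q"))
  expect_warning(s <- readPDB(p), "unknown element")
  expect_equal(atoms(s)$radius, 1.70)
  expect_warning(s <- assignCharges(s), "unknown residue")
  expect_equal(charges(s), 0)
})

test_that("toy groove net charge is rims plus peptide charges", {
  spec <- toyGrooveSpec(peptideCharges = c(0, 0, 0, 0, 0, 0, 1, 0))
  s <- makeToyGroove(spec)
  ## 9 alternating +/-0.25 rim charges per rim sum to +0.25 each
  expect_equal(sum(charges(s)), 2 * 0.25 + 1)
})

test_that("canonical orientation recovers rigid motions exactly", {
  ref <- makeToyGroove(toyGrooveSpec(label = "ref"))
  ## identity case
  o <- canonicalOrient(ref, ref)
  expect_equal(o$frame@rotation, diag(3), tolerance = 1e-9)
  expect_lt(o$frame@rmsd, 1e-9)

  for (seed in 1:5) {
    R <- randomRotation(seed)
    set.seed(seed + 100)
    tr <- rnorm(3, sd = 10)
    moved <- transformStructure(ref, R, tr)
    o <- canonicalOrient(moved, ref)
    expect_lt(o$frame@rmsd, 1e-6)
    expect_lt(max(abs(coords(o$structure) - coords(ref))), 1e-5)
    expect_equal(det(o$frame@rotation), 1, tolerance = 1e-9)
  }
})

test_that("backbone-only fit gives identical frames for charge variants", {
  a <- makeToyGroove(toyGrooveSpec(rep(0, 8), label = "a"))
  b <- makeToyGroove(toyGrooveSpec(c(1, 0, -1, 0, 0, 1, 0, 0), label = "b"))
  o <- canonicalOrient(b, a, selection = "A")   # groove only, charges differ
  expect_lt(o$frame@rmsd, 1e-12)
  expect_equal(o$frame@rotation, diag(3), tolerance = 1e-9)
  expect_equal(unname(o$frame@translation), c(0, 0, 0), tolerance = 1e-9)
})

test_that("degenerate fit selections are rejected", {
  ref <- makeToyGroove(toyGrooveSpec(label = "ref"))
  ## collinear: three atoms along the peptide row
  lin <- pointCharges(cbind(c(0, 3.5, 7), 0, 0), c(0, 0, 0))
  expect_error(canonicalOrient(lin, lin), "collinear")
  ## mismatched selections
  expect_error(canonicalOrient(ref, lin), "fewer than 3|different atom sets")
  ## selection mini-language
  idx <- selectAtoms(ref, "P:2-4")
  expect_equal(atoms(ref)$resno[idx], 2:4)
  expect_error(selectAtoms(ref, ":bad:"), "cannot parse")
})

test_that("re-canonicalizing a canonical structure is a no-op", {
  ref <- makeToyGroove(toyGrooveSpec(label = "ref"))
  once <- canonicalOrient(transformStructure(ref, randomRotation(7), c(1, 2, 3)),
                          ref)$structure
  twice <- canonicalOrient(once, ref)$structure
  expect_lt(max(abs(coords(twice) - coords(once))), 1e-6)
})
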