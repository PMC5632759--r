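test_that("height field is the probe-inflated sphere top", {
  s <- bornSphere(q = 0, radius = 2, at = c(0, 0, 0))
  surf <- computeHeightfield(s, window = c(-8, 8, -8, 8), pixelSize = 0.5,
                             probeRadius = 1.4)
  px <- pMHCsurf:::.pixelCenters(surf@window, surf@pixelSize)
  ## pixel nearest (0,0) is offset by 0.25 A in x and y
  i <- which.min(abs(px$xs)); j <- which.min(abs(px$ys))
  d2 <- px$xs[i]^2 + px$ys[j]^2
  expect_equal(surf@height[i, j], sqrt(3.4^2 - d2), tolerance = 1e-12)
  ## 5 A away horizontally: outside the inflated radius -> background
  i5 <- which.min(abs(px$xs - 5))
  expect_false(surf@mask[i5, j])
  expect_true(is.na(surf@height[i5, j]))
  ## translation equivariance in z
  up <- computeHeightfield(transformStructure(s, diag(3), c(0, 0, 1)),
                           window = c(-8, 8, -8, 8))
  expect_equal(up@height[up@mask], surf@height[surf@mask] + 1)
  expect_equal(up@mask, surf@mask)
  ## empty overlap warns
  expect_warning(computeHeightfield(s, window = c(50, 60, 50, 60)),
                 "all background")
})

test_that("surface potential has the sign and symmetry of its charges", {
  neutral <- makeToyGroove(toyGrooveSpec(rep(0, 8), rimCharge = 0,
                                         label = "neutral"))
  surfN <- samplePotential(computeHeightfield(neutral), neutral,
                           electroModel()) |> suppressWarnings()
  expect_equal(max(abs(surfN@potential)), 0)

  spicy <- makeToyGroove(toyGrooveSpec(c(0, 0, 0, 0, 0, 0, 1, 0),
                                       label = "p7plus"))
  surf <- samplePotential(computeHeightfield(spicy), spicy, electroModel())
  a <- atoms(spicy)
  p7 <- a[a$chain == "P" & a$resno == 7, ]
  px <- pMHCsurf:::.pixelCenters(surf@window, surf@pixelSize)
  i <- which.min(abs(px$xs - p7$x)); j <- which.min(abs(px$ys - p7$y))
  expect_gt(surf@potential[i, j], 0)

  ## mirror-symmetric charges (P2 and P7 of an 8-mer) give a mirror field
  sym <- makeToyGroove(toyGrooveSpec(c(0, 1, 0, 0, 0, 0, 1, 0),
                                     label = "sym"))
  ss <- samplePotential(computeHeightfield(sym), sym, electroModel())
  flipped <- ss@potential[rev(seq_len(nrow(ss@potential))), ]
  expect_lt(max(abs(ss@potential - flipped)), 1e-9)
})

test_that("the red-white-blue colormap follows the clamp rule", {
  s <- bornSphere(q = 0)
  surf <- computeHeightfield(s, window = c(-2, 2, -2, 2))
  phi <- matrix(0, nrow(surf@height), ncol(surf@height))
  phi[1, 1] <- -7; phi[2, 1] <- 2.5; phi[3, 1] <- 5; phi[4, 1] <- -5
  phi[!surf@mask] <- 0
  surf <- initialize(surf, potential = phi)
  surf <- renderSurface(surf, clamp = 5)
  ## all four probe pixels sit on the molecule in an 8x8 window
  expect_true(all(surf@mask[cbind(1:4, 1)]))
  expect_equal(surf@rgb[1, 1, ], c(255L, 0L, 0L))        # clamped negative
  expect_equal(surf@rgb[2, 1, ], c(128L, 128L, 255L))    # +2.5, half-away
  expect_equal(surf@rgb[3, 1, ], c(0L, 0L, 255L))        # +5 saturates blue
  expect_equal(surf@rgb[4, 1, ], c(255L, 0L, 0L))        # -5 saturates red
  mid <- which(surf@mask & phi == 0, arr.ind = TRUE)[1, , drop = FALSE]
  expect_equal(surf@rgb[mid[1], mid[2], ], c(255L, 255L, 255L))
})

test_that("the colormap is bijective on the clamp range up to 8-bit steps", {
  phis <- seq(-5, 5, by = 0.04)
  fade <- pMHCsurf:::.roundHalfAway(255 * (1 - abs(phis) / 5))
  code <- ifelse(phis < 0, -fade, ifelse(phis > 0, 510 + fade, 255))
  ## distinct potentials separated by > one 8-bit step map to distinct colors
  steps <- split(phis, code)
  expect_lt(max(vapply(steps, function(v) diff(range(v)), numeric(1))),
            2 * 5 / 255 + 1e-9)
})

test_that("region features average masked pixels and honor exclusions", {
  neutral <- makeToyGroove(toyGrooveSpec(rep(0, 8), rimCharge = 0,
                                         label = "flat"))
  surf <- suppressWarnings(surfaceImage(neutral))
  g <- regionGrid()
  f <- extractFeatures(surf, g)
  expect_length(f, 8 * 4 * 3)
  expect_true(all(f == 255))   # uniform phi = 0 -> white everywhere

  ## saturate one region: pixels above P7 (+x side, central y)
  spicy <- makeToyGroove(toyGrooveSpec(c(0, 0, 0, 0, 0, 0, 1, 0),
                                       spicyPosition = 7, label = "sp"))
  surfS <- surfaceImage(spicy)
  fS <- extractFeatures(surfS, g)
  expect_false(all(fS == 255))
  ## exclusion semantics: dropping regions removes |channels| features each
  masked <- maskRegions(g, c(1, 2))
  fM <- extractFeatures(surfS, masked)
  expect_length(fM, (32 - 2) * 3)
  expect_false(any(grepl("^r0[12]_", names(fM))))
  ## excluding an empty set is the identity
  expect_equal(extractFeatures(surfS, maskRegions(g, integer())), fS)
  expect_error(maskRegions(g, 1:32), "every region")
  expect_error(maskRegions(g, 99), "out of range")
})

test_that("masking the only differing regions collapses the distance to zero", {
  ## identical charges, geometry differing only at the raised P7 bump:
  ## the height channel localizes the difference to a few regions
  a <- makeToyGroove(toyGrooveSpec(rep(0, 8), label = "a"))
  b <- makeToyGroove(toyGrooveSpec(rep(0, 8), spicyPosition = 7, label = "b"))
  g <- regionGrid()
  fm <- featureMatrix(list(surfaceImage(a), surfaceImage(b)), g,
                      channels = "height")
  differing <- which(fm[, 1] != fm[, 2])
  regs <- unique(as.integer(sub("^r(\\d+)_.*", "\\1", rownames(fm)[differing])))
  expect_lt(length(regs), 10)            # the bump is local
  fm2 <- featureMatrix(list(surfaceImage(a), surfaceImage(b)),
                       maskRegions(g, regs), channels = "height")
  expect_equal(fm2[, 1], fm2[, 2])
  expect_equal(max(correlationDistance(fm2)), 0, tolerance = 1e-12)
})

test_that("empty regions contribute neutral values; all-empty errors", {
  ## one atom in the window corner: most regions are background
  s <- bornSphere(q = 1, at = c(-14, -8, 0))
  surf <- surfaceImage(s, window = c(-16, 16, -10, 10))
  f <- extractFeatures(surf, regionGrid(), channels = c("R", "phi", "height"))
  expect_equal(unname(f["r16_R"]), 255)
  expect_equal(unname(f["r16_phi"]), 0)
  expect_equal(unname(f["r16_height"]), 0)
  ## molecule entirely outside the region window
  g2 <- regionGrid(2, 2, window = c(10, 16, 4, 10))
  expect_error(extractFeatures(surf, g2), "empty")
  ## grid must lie inside the surface window
  expect_error(extractFeatures(surf, regionGrid(window = c(-20, 20, -10, 10))),
               "beyond")
})

test_that("feature extraction is deterministic and CSV round-trips", {
  fam <- defaultToyFamily(seed = 3)
  surfs <- lapply(fam$structures, surfaceImage)
  fm1 <- featureMatrix(surfs, regionGrid())
  fm2 <- featureMatrix(surfs, regionGrid())
  expect_identical(fm1, fm2)
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  writeFeaturesCSV(fm1, p1); writeFeaturesCSV(fm2, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- readFeaturesCSV(p1)
  expect_equal(back, fm1, tolerance = 1e-12)
})

test_that("a rigidly moved structure yields the same features after canonicalization", {
  ref <- makeToyGroove(toyGrooveSpec(c(0, -1, 0, 0, 1, 0, 1, 0),
                                     spicyPosition = 7, label = "m"))
  f0 <- extractFeatures(surfaceImage(ref), regionGrid(),
                        channels = c("R", "G", "B", "phi", "height"))
  for (seed in c(21, 22)) {
    set.seed(seed + 50)
    moved <- transformStructure(ref, randomRotation(seed), rnorm(3, sd = 20))
    back <- canonicalOrient(moved, ref)$structure
    f1 <- extractFeatures(surfaceImage(back), regionGrid(),
                          channels = c("R", "G", "B", "phi", "height"))
    isRGB <- grepl("_(R|G|B)$", names(f0))
    expect_lte(max(abs(f1[isRGB] - f0[isRGB])), 1)
    expect_lt(max(abs(f1[!isRGB] - f0[!isRGB])), 1e-6)
  }
})

test_that("surface PNG export writes the expected raster", {
  s <- makeToyGroove(toyGrooveSpec(c(0, 0, 0, -1, 0, 0, 1, 0), label = "png"))
  surf <- surfaceImage(s)
  p <- tempfile(fileext = ".png")
  writeSurfacePNG(surf, p)
  img <- png::readPNG(p)
  expect_equal(dim(img), c(ncol(surf@mask), nrow(surf@mask), 3))
  ## top-left image pixel is the (min x, max y) surface pixel
  expect_equal(as.integer(round(img[1, 1, ] * 255)),
               surf@rgb[1, ncol(surf@mask), ])
})
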