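test_that("screened Coulomb matches the closed form", {
  m <- electroModel(ionicStrength = 0)
  s <- bornSphere(q = 1)
  ## q = +1 e, eps 80, kappa 0: phi = L / (80 * r); 1 kT/e at r = L/80
  r <- L_REF / 80
  phi <- screenedCoulomb(s, matrix(c(r, 0, 0), 1), m)
  expect_equal(phi, 1.0, tolerance = 2e-4)
  ## clamp below 0.5 A: potential inside the atom stays finite
  inside <- screenedCoulomb(s, matrix(c(0.01, 0, 0), 1), m)
  expect_equal(inside, L_REF / (80 * 0.5), tolerance = 1e-3)
})

test_that("screened Coulomb is linear, sign-symmetric and zero for dipole midpoints", {
  m <- electroModel()
  set.seed(4)
  pts <- matrix(rnorm(30, sd = 8), ncol = 3)
  xyz <- matrix(rnorm(15, sd = 2), ncol = 3)
  q1 <- runif(5, -1, 1); q2 <- runif(5, -1, 1)
  s1 <- pointCharges(xyz, q1); s2 <- pointCharges(xyz, q2)
  s12 <- pointCharges(xyz, q1 + q2)
  expect_equal(screenedCoulomb(s12, pts, m),
               screenedCoulomb(s1, pts, m) + screenedCoulomb(s2, pts, m),
               tolerance = 1e-12)
  expect_equal(screenedCoulomb(pointCharges(xyz, -q1), pts, m),
               -screenedCoulomb(s1, pts, m), tolerance = 1e-12)
  ## opposite unit charges, midpoint sample
  dip <- pointCharges(rbind(c(-3, 0, 0), c(3, 0, 0)), c(1, -1))
  expect_equal(screenedCoulomb(dip, matrix(0, 1, 3), m), 0, tolerance = 1e-12)
  ## empty charge set warns and returns zeros
  expect_warning(z <- screenedCoulomb(pointCharges(xyz, rep(0, 5)), pts, m),
                 "no nonzero charges")
  expect_equal(z, rep(0, nrow(pts)))
  ## unset charges are an error, not silently zero
  expect_error(screenedCoulomb(readPDB(writeTextPDB(
    onePdbLine(1, "CA", "GLY", "A", 1, 0, 0, 0))), pts, m), "unset")
})

test_that("Debye parameter follows the closed form", {
  expect_equal(debyeKappa(0), 0)
  ## frozen from kappa^2 = 8 pi (L/eps) N_A I 1e-27 at 0.145 M, eps 80
  expect_equal(1 / debyeKappa(0.145), 8.065, tolerance = 1e-3)
  ## quadrupled ionic strength doubles kappa
  expect_equal(debyeKappa(4 * 0.145), 2 * debyeKappa(0.145), tolerance = 1e-12)
})

test_that("PB solve matches the Coulomb oracle in a homogeneous dielectric", {
  s <- bornSphere()
  m <- electroModel("fd-linear-pb", epsIn = 80, epsOut = 80,
                    ionicStrength = 0, gridSpacing = 1.0, gridPadding = 10)
  g <- solveLinearPB(s, m)
  set.seed(2)
  dirs <- matrix(rnorm(150), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rs <- runif(50, 4, 11)
  pts <- dirs * rs
  rel <- abs(gridInterp(g, pts) - L_REF / (80 * rs)) / (L_REF / (80 * rs))
  expect_lt(max(rel), 0.02)
})

test_that("PB error decreases monotonically with grid refinement", {
  s <- bornSphere()
  rs <- seq(4, 10, by = 0.5)
  pts <- cbind(rs, 0, 0)
  exact <- L_REF / (80 * rs)
  err <- vapply(c(1.0, 0.5), function(h) {
    m <- electroModel("fd-linear-pb", epsIn = 80, epsOut = 80,
                      ionicStrength = 0, gridSpacing = h, gridPadding = 10)
    max(abs(gridInterp(solveLinearPB(s, m), pts) - exact) / exact)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("PB with uniform dielectric and no salt agrees with screened Coulomb", {
  ## Coulomb limit: outside twice the atom radius, within 2%
  s <- pointCharges(rbind(c(-2, 0, 0), c(2, 1, 0)), c(1, 0.5))
  m <- electroModel("fd-linear-pb", epsIn = 80, epsOut = 80,
                    ionicStrength = 0, gridSpacing = 0.5, gridPadding = 8)
  g <- solveLinearPB(s, m)
  set.seed(9)
  dirs <- matrix(rnorm(90), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pts <- dirs * runif(30, 5.5, 8)
  cm <- electroModel("coulomb-dh", epsOut = 80, ionicStrength = 0)
  ref <- screenedCoulomb(s, pts, cm)
  expect_lt(max(abs(gridInterp(g, pts) - ref) / abs(ref)), 0.02)
})

test_that("PB with zero charges returns the zero field", {
  s <- pointCharges(matrix(rnorm(9), 3), rep(0, 3))
  m <- electroModel("fd-linear-pb", gridSpacing = 1.0, gridPadding = 6)
  expect_warning(g <- solveLinearPB(s, m), NA) # no warning path here
  expect_equal(max(abs(g@values)), 0)
})

test_that("grid potentials export and interpolate consistently", {
  s <- bornSphere()
  m <- electroModel("fd-linear-pb", epsIn = 80, epsOut = 80,
                    ionicStrength = 0, gridSpacing = 1.0, gridPadding = 6)
  g <- solveLinearPB(s, m)
  ## node-exact interpolation
  node <- g@origin + c(3, 4, 5) * g@spacing
  expect_equal(gridInterp(g, matrix(node, 1)),
               g@values[4, 5, 6], tolerance = 1e-12)
  expect_error(gridInterp(g, matrix(g@origin - 5, 1)), "outside")
  ## OpenDX export carries the full field
  dx <- tempfile(fileext = ".dx")
  writeOpenDX(g, dx)
  lines <- readLines(dx)
  expect_true(any(grepl("gridpositions", lines)))
  header <- grep("data follows", lines)
  vals <- as.numeric(unlist(strsplit(trimws(
    lines[(header + 1):(length(lines) - 1)]), "\\s+")))
  expect_equal(length(vals), prod(dim(g@values)))
  expect_equal(max(vals), max(g@values), tolerance = 1e-6)
})
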