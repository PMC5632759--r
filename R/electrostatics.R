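## Electrostatic potential of a charged structure, in kT/e.
##
## Two modes: a screened-Coulomb (Debye-Hueckel) sum, the fast pipeline
## default, and a finite-difference linearized Poisson-Boltzmann solve on a
## cubic grid with Coulomb Dirichlet boundaries. Both are validated against
## closed forms (Born sphere, Debye-Hueckel sphere) in the test suite.

## Physical constants (SI)
.eCharge <- 1.602176634e-19    # C
.eps0 <- 8.8541878128e-12      # F/m
.kB <- 1.380649e-23            # J/K
.NA <- 6.02214076e23           # 1/mol

## e^2 / (4 pi eps0 kT) in Angstrom: 560.46 A at 298.15 K. Multiplying a
## charge in e by L / (eps r[A]) gives the potential in kT/e directly.
.coulombLength <- function(temperature = 298.15) {
  .eCharge^2 / (4 * pi * .eps0 * .kB * temperature) * 1e10
}

#' Construct an electrostatic model
#'
#' @param mode `"coulomb-dh"` (screened Coulomb; pipeline default) or
#'   `"fd-linear-pb"` (finite-difference linearized Poisson-Boltzmann).
#' @param epsIn,epsOut relative dielectrics of molecule interior / solvent.
#' @param ionicStrength 1:1 salt concentration, mol/L.
#' @param temperature Kelvin.
#' @param gridSpacing,gridPadding PB grid spacing and solvent padding, Angstrom.
#' @return An [ElectrostaticModel-class].
#' @export
electroModel <- function(mode = c("coulomb-dh", "fd-linear-pb"),
                         epsIn = 4, epsOut = 80, ionicStrength = 0.145,
                         temperature = 298.15, gridSpacing = 1.0,
                         gridPadding = 10) {
  new("ElectrostaticModel", mode = match.arg(mode), epsIn = epsIn,
      epsOut = epsOut, ionicStrength = ionicStrength,
      temperature = temperature, gridSpacing = gridSpacing,
      gridPadding = gridPadding)
}

#' Debye screening parameter kappa
#'
#' Inverse Debye length of a 1:1 electrolyte,
#' `kappa^2 = 8 pi l_B n_ion`, with Bjerrum length `l_B = L / epsOut` and
#' ion number density from the molar ionic strength. At 0.145 mol/L,
#' 298.15 K and `epsOut = 80` the Debye length `1/kappa` is 8.07 Angstrom.
#'
#' @param ionicStrength mol/L (>= 0).
#' @param epsOut solvent relative dielectric.
#' @param temperature Kelvin.
#' @return kappa in 1/Angstrom (0 when `ionicStrength` is 0).
#' @export
debyeKappa <- function(ionicStrength, epsOut = 80, temperature = 298.15) {
  stopifnot(ionicStrength >= 0, epsOut > 0, temperature > 0)
  if (ionicStrength == 0) return(0)
  lB <- .coulombLength(temperature) / epsOut          # Angstrom
  nIon <- .NA * ionicStrength * 1e-27                 # ions / Angstrom^3
  sqrt(8 * pi * lB * nIon)
}

.checkedCharges <- function(s) {
  q <- charges(s)
  if (any(is.na(q)))
    stop("structure '", structureLabel(s),
         "' has unset charges; run assignCharges() first")
  q
}

#' Screened-Coulomb potential at sample points
#'
#' `phi(p) = sum_i q_i * L / (epsOut * r_i) * exp(-kappa * r_i)` with
#' `L = e^2/(4 pi eps0 kT)` (560.5 Angstrom at 298.15 K) and kappa from
#' [debyeKappa()] (`kappa = 0` for zero ionic strength). Distances are
#' clamped below at 0.5 Angstrom so points inside an atom never diverge;
#' the clamp is applied identically to every complex.
#'
#' @param s a [ChargedStructure-class] with charges assigned.
#' @param points n x 3 matrix of sample coordinates, Angstrom.
#' @param model an [ElectrostaticModel-class] with mode `"coulomb-dh"`.
#' @return numeric vector of potentials, kT/e.
#' @export
screenedCoulomb <- function(s, points, model = electroModel()) {
  if (model@mode != "coulomb-dh")
    stop("screenedCoulomb requires mode 'coulomb-dh'")
  points <- matrix(as.numeric(points), ncol = 3)
  q <- .checkedCharges(s)
  nz <- which(q != 0)
  if (length(nz) == 0L) {
    warning("structure carries no nonzero charges; potentials are all zero",
            call. = FALSE)
    return(rep(0, nrow(points)))
  }
  xyz <- coords(s)[nz, , drop = FALSE]
  q <- q[nz]
  L <- .coulombLength(model@temperature)
  kap <- debyeKappa(model@ionicStrength, model@epsOut, model@temperature)
  ## r: points x atoms
  r2 <- outer(rowSums(points^2), rep(1, nrow(xyz))) +
    outer(rep(1, nrow(points)), rowSums(xyz^2)) -
    2 * points %*% t(xyz)
  r <- sqrt(pmax(r2, 0))
  r[r < 0.5] <- 0.5
  as.numeric((exp(-kap * r) / r) %*% q) * L / model@epsOut
}

## Grid geometry shared by the solver and its tests.
.pbGrid <- function(s, model) {
  a <- atoms(s)
  lo <- c(min(a$x - a$radius), min(a$y - a$radius), min(a$z - a$radius)) -
    model@gridPadding
  hi <- c(max(a$x + a$radius), max(a$y + a$radius), max(a$z + a$radius)) +
    model@gridPadding
  h <- model@gridSpacing
  dims <- pmax(3L, as.integer(ceiling((hi - lo) / h)) + 1L)
  list(origin = lo, spacing = h, dims = dims,
       xs = lo[1] + (seq_len(dims[1]) - 1) * h,
       ys = lo[2] + (seq_len(dims[2]) - 1) * h,
       zs = lo[3] + (seq_len(dims[3]) - 1) * h)
}

#' Finite-difference linearized Poisson-Boltzmann solve
#'
#' Solves `div(eps grad phi) - epsOut * kappa^2 * h_ion * phi = -4 pi L rho`
#' on a cubic grid in dimensionless kT/e form. The molecular region is the
#' union of atom spheres (van der Waals): dielectric `epsIn` and
#' ion-excluded inside, `epsOut` and ionic screening outside. Charges are
#' spread trilinearly onto the 8 nearest nodes; boundary nodes carry
#' Dirichlet values from [screenedCoulomb()]; interior nodes are relaxed by
#' SOR until the largest node update falls below `tol` (default 1e-5 kT/e)
#' or `maxSweeps` sweeps.
#'
#' @param s a [ChargedStructure-class] with charges assigned.
#' @param model an [ElectrostaticModel-class] with mode `"fd-linear-pb"`.
#' @param tol convergence tolerance on the max node update, kT/e.
#' @param maxSweeps SOR sweep cap.
#' @return A [GridPotential-class].
#' @export
solveLinearPB <- function(s, model, tol = 1e-5, maxSweeps = 10000L) {
  if (model@mode != "fd-linear-pb")
    stop("solveLinearPB requires mode 'fd-linear-pb'")
  q <- .checkedCharges(s)
  g <- .pbGrid(s, model)
  nx <- g$dims[1]; ny <- g$dims[2]; nz <- g$dims[3]
  h <- g$spacing
  a <- atoms(s)

  ## molecular region: union of vdW spheres, node-sampled
  inside <- array(FALSE, g$dims)
  for (i in seq_len(nrow(a))) {
    ix <- which(abs(g$xs - a$x[i]) <= a$radius[i])
    iy <- which(abs(g$ys - a$y[i]) <= a$radius[i])
    iz <- which(abs(g$zs - a$z[i]) <= a$radius[i])
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (g$xs[ix] - a$x[i])^2
    dy2 <- (g$ys[iy] - a$y[i])^2
    dz2 <- (g$zs[iz] - a$z[i])^2
    sub <- outer(dx2, dy2, "+")
    r2 <- a$radius[i]^2
    for (k in seq_along(iz)) {
      hit <- sub + dz2[k] <= r2
      inside[ix, iy, iz[k]][hit] <- TRUE
    }
  }
  eps <- ifelse(inside, model@epsIn, model@epsOut)
  ion <- as.integer(!inside)

  ## trilinear charge spreading
  L <- .coulombLength(model@temperature)
  qn <- array(0, g$dims)
  nzq <- which(q != 0)
  for (i in nzq) {
    fx <- (a$x[i] - g$origin[1]) / h
    fy <- (a$y[i] - g$origin[2]) / h
    fz <- (a$z[i] - g$origin[3]) / h
    i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
    if (i0 < 0 || j0 < 0 || k0 < 0 ||
        i0 >= nx - 1 || j0 >= ny - 1 || k0 >= nz - 1)
      stop("charge of atom ", i, " falls outside the PB grid")
    wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) wx else 1 - wx) * (if (dy) wy else 1 - wy) *
        (if (dz) wz else 1 - wz)
      qn[i0 + dx + 1, j0 + dy + 1, k0 + dz + 1] <-
        qn[i0 + dx + 1, j0 + dy + 1, k0 + dz + 1] + w * q[i]
    }
  }

  ## Dirichlet boundary from the screened-Coulomb far field
  phi <- array(0, g$dims)
  bnd <- array(FALSE, g$dims)
  bnd[c(1, nx), , ] <- TRUE
  bnd[, c(1, ny), ] <- TRUE
  bnd[, , c(1, nz)] <- TRUE
  bidx <- which(bnd)
  if (length(nzq)) {
    coord <- arrayInd(bidx, g$dims)
    pts <- cbind(g$xs[coord[, 1]], g$ys[coord[, 2]], g$zs[coord[, 3]])
    cm <- electroModel("coulomb-dh", epsIn = model@epsIn,
                       epsOut = model@epsOut,
                       ionicStrength = model@ionicStrength,
                       temperature = model@temperature)
    phi[bidx] <- screenedCoulomb(s, pts, cm)
  }

  kap <- debyeKappa(model@ionicStrength, model@epsOut, model@temperature)
  omega <- 2 / (1 + sin(pi / max(g$dims)))
  res <- pb_sor_cpp(as.numeric(phi), as.numeric(eps), ion,
                    as.numeric(4 * pi * L * qn / h),
                    nx, ny, nz,
                    screen = model@epsOut * kap^2 * h^2,
                    omega = omega, tol = tol, maxSweeps = maxSweeps)
  if (!res$converged)
    stop(sprintf(
      "PB solver did not converge in %d sweeps (max update %.3g kT/e)",
      maxSweeps, res$maxUpdate))
  new("GridPotential", origin = g$origin, spacing = h,
      values = array(res$phi, g$dims))
}

#' Trilinear interpolation of a GridPotential
#'
#' @param grid a [GridPotential-class].
#' @param points n x 3 matrix of coordinates, Angstrom.
#' @return numeric vector of interpolated potentials, kT/e.
#' @export
gridInterp <- function(grid, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  d <- dim(grid@values)
  f <- sweep(points, 2, grid@origin) / grid@spacing
  if (any(f < -1e-9) || any(sweep(f, 2, d - 1) > 1e-9))
    stop("sample point(s) outside the potential grid")
  f <- pmin(pmax(f, 0), matrix(rep(d - 1, each = nrow(f)), ncol = 3) - 1e-12)
  i0 <- floor(f)
  w <- f - i0
  out <- numeric(nrow(points))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ww <- (if (dx) w[, 1] else 1 - w[, 1]) *
      (if (dy) w[, 2] else 1 - w[, 2]) *
      (if (dz) w[, 3] else 1 - w[, 3])
    idx <- cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1, i0[, 3] + dz + 1)
    out <- out + ww * grid@values[idx]
  }
  out
}

#' Export a GridPotential in OpenDX scalar-field text format
#'
#' @param grid a [GridPotential-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeOpenDX <- function(grid, path) {
  d <- dim(grid@values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar field (potential, kT/e)",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", grid@origin[1], grid@origin[2], grid@origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", grid@spacing),
    sprintf("delta 0.000000 %.6f 0.000000", grid@spacing),
    sprintf("delta 0.000000 0.000000 %.6f", grid@spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  ## OpenDX runs the z index fastest
  v <- numeric(prod(d))
  idx <- 1L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    v[idx:(idx + d[3] - 1L)] <- grid@values[i, j, ]
    idx <- idx + d[3]
  }
  writeLines(format(v, trim = TRUE, digits = 7), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Potentials at sample points as CSV (x, y, z, phi_kT_e)
#'
#' @param points n x 3 matrix.
#' @param phi potentials at those points, kT/e.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePotentialCSV <- function(points, phi, path) {
  df <- data.frame(x = points[, 1], y = points[, 2], z = points[, 3],
                   phi_kT_e = phi)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
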