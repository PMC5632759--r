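## Fixed-orientation surface raster of the TCR-interacting face.
##
## The canonical-frame structure is projected orthographically top-down
## (+z towards the TCR): per pixel the height of the probe-inflated
## molecular top, the electrostatic potential sampled on that surface, and
## an 8-bit red/white/blue rendering clamped at +/- 5 kT/e, mirroring the
## conventional potential color ramp. Region means of these channels are
## the per-complex descriptors fed to the clustering.

.pixelCenters <- function(window, pixelSize) {
  nx <- max(1L, as.integer(round((window[2] - window[1]) / pixelSize)))
  ny <- max(1L, as.integer(round((window[4] - window[3]) / pixelSize)))
  list(xs = window[1] + (seq_len(nx) - 0.5) * pixelSize,
       ys = window[3] + (seq_len(ny) - 0.5) * pixelSize,
       nx = nx, ny = ny)
}

#' Compute the top-down height field of a canonical structure
#'
#' For each pixel center (x, y), the height is the maximum over atoms of
#' the top of the probe-inflated sphere (radius + probe) intersecting the
#' vertical line through the pixel; pixels no atom reaches are background
#' (`mask = FALSE`, height `NA`).
#'
#' @param s a canonically oriented [ChargedStructure-class] (TCR face = +z).
#' @param window `(x_min, x_max, y_min, y_max)` in Angstrom.
#' @param pixelSize Angstrom per pixel.
#' @param probeRadius solvent probe radius, Angstrom (default 1.4).
#' @return A [SurfaceImage-class] with height and mask filled.
#' @export
computeHeightfield <- function(s, window = c(-16, 16, -10, 10),
                               pixelSize = 0.5, probeRadius = 1.4) {
  px <- .pixelCenters(window, pixelSize)
  height <- matrix(-Inf, px$nx, px$ny)
  a <- atoms(s)
  for (i in seq_len(nrow(a))) {
    R <- a$radius[i] + probeRadius
    ix <- which(abs(px$xs - a$x[i]) <= R)
    iy <- which(abs(px$ys - a$y[i]) <= R)
    if (!length(ix) || !length(iy)) next
    d2 <- outer((px$xs[ix] - a$x[i])^2, (px$ys[iy] - a$y[i])^2, "+")
    top <- a$z[i] + sqrt(pmax(R^2 - d2, 0))
    top[d2 > R^2] <- -Inf
    height[ix, iy] <- pmax(height[ix, iy], top)
  }
  mask <- is.finite(height)
  if (!any(mask))
    warning("structure does not overlap the surface window; all background",
            call. = FALSE)
  height[!mask] <- NA_real_
  new("SurfaceImage", window = as.numeric(window), pixelSize = pixelSize,
      height = height, potential = matrix(numeric(0), 0, 0),
      rgb = array(integer(0), c(0, 0, 3)), mask = mask,
      clamp = NA_real_, label = structureLabel(s))
}

#' Sample the electrostatic potential on the surface
#'
#' Evaluates phi at (x, y, height(x, y)) for every masked pixel, via
#' [screenedCoulomb()] in `"coulomb-dh"` mode or trilinear interpolation of
#' a (possibly precomputed) [solveLinearPB()] grid in `"fd-linear-pb"`
#' mode. Background pixels get 0.
#'
#' @param surface a [SurfaceImage-class] with the height field computed.
#' @param s the (canonical) [ChargedStructure-class] with charges assigned.
#' @param model an [ElectrostaticModel-class].
#' @param grid optional precomputed [GridPotential-class] for PB mode.
#' @return the surface with the potential channel filled.
#' @export
samplePotential <- function(surface, s, model = electroModel(), grid = NULL) {
  px <- .pixelCenters(surface@window, surface@pixelSize)
  idx <- which(surface@mask, arr.ind = TRUE)
  pot <- matrix(0, px$nx, px$ny)
  if (nrow(idx)) {
    pts <- cbind(px$xs[idx[, 1]], px$ys[idx[, 2]],
                 surface@height[idx])
    vals <- if (model@mode == "coulomb-dh") {
      screenedCoulomb(s, pts, model)
    } else {
      if (is.null(grid)) grid <- solveLinearPB(s, model)
      gridInterp(grid, pts)
    }
    pot[idx] <- vals
  }
  initialize(surface, potential = pot)
}

## round half away from zero, fixed so 8-bit outputs are platform-stable
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Render the surface potential as an 8-bit red/white/blue raster
#'
#' Linear two-segment colormap: `-clamp` maps to red (255, 0, 0), 0 to
#' white (255, 255, 255), `+clamp` to blue (0, 0, 255); values beyond
#' +/- clamp saturate. Channel values are `round(255 * (1 - |phi|/clamp))`
#' on the fading channels, with half-counts rounded away from zero.
#' Background pixels are white.
#'
#' @param surface a [SurfaceImage-class] with the potential sampled.
#' @param clamp saturation limit in kT/e (default 5).
#' @return the surface with the rgb channels filled.
#' @export
renderSurface <- function(surface, clamp = 5) {
  if (!length(surface@potential))
    stop("potential channel missing; run samplePotential() first")
  phi <- pmin(pmax(surface@potential, -clamp), clamp)
  fade <- .roundHalfAway(255 * (1 - abs(phi) / clamp))
  d <- dim(surface@mask)
  rgb <- array(255L, c(d, 3L))
  neg <- phi < 0 & surface@mask
  pos <- phi > 0 & surface@mask
  R <- matrix(255, d[1], d[2]); G <- matrix(255, d[1], d[2])
  B <- matrix(255, d[1], d[2])
  G[neg] <- fade[neg]; B[neg] <- fade[neg]
  R[pos] <- fade[pos]; G[pos] <- fade[pos]
  rgb[, , 1] <- as.integer(R); rgb[, , 2] <- as.integer(G)
  rgb[, , 3] <- as.integer(B)
  initialize(surface, rgb = rgb, clamp = clamp)
}

#' One-shot surface image of a canonical structure
#'
#' Convenience wrapper: height field, surface potential, rendering.
#'
#' @inheritParams computeHeightfield
#' @inheritParams samplePotential
#' @param clamp rendering clamp, kT/e.
#' @return a fully populated [SurfaceImage-class].
#' @export
surfaceImage <- function(s, model = electroModel(),
                         window = c(-16, 16, -10, 10), pixelSize = 0.5,
                         probeRadius = 1.4, clamp = 5, grid = NULL) {
  surf <- computeHeightfield(s, window, pixelSize, probeRadius)
  surf <- samplePotential(surf, s, model, grid)
  renderSurface(surf, clamp)
}

#' Define the predetermined region grid
#'
#' @param nx,ny region counts along x and y (defaults 8 x 4).
#' @param window `(x_min, x_max, y_min, y_max)`, Angstrom; must match the
#'   surface window used for feature extraction.
#' @param excluded integer region indices to drop (row-major from
#'   (x_min, y_min)).
#' @return A [RegionGrid-class].
#' @export
regionGrid <- function(nx = 8, ny = 4, window = c(-16, 16, -10, 10),
                       excluded = integer()) {
  new("RegionGrid", nx = as.integer(nx), ny = as.integer(ny),
      window = as.numeric(window), excluded = as.integer(sort(unique(excluded))))
}

#' Exclude regions from a grid (region masking)
#'
#' Returns the grid with `indices` added to its excluded set; used to
#' re-cluster on sub-surfaces, e.g. restricting the analysis to the
#' Valpha- or Vbeta-facing half of the groove, or removing a single
#' prominent charged spot.
#'
#' @param grid a [RegionGrid-class].
#' @param indices region indices to exclude.
#' @return the masked [RegionGrid-class].
#' @export
maskRegions <- function(grid, indices) {
  indices <- as.integer(indices)
  n <- grid@nx * grid@ny
  if (length(indices) && (any(indices < 1L) || any(indices > n)))
    stop("region indices out of range 1..", n)
  excl <- sort(unique(c(grid@excluded, indices)))
  if (length(setdiff(seq_len(n), excl)) < 1L)
    stop("cannot exclude every region")
  initialize(grid, excluded = excl)
}

.channelNeutral <- c(R = 255, G = 255, B = 255, phi = 0, height = 0)

#' Extract per-region descriptors from a surface image
#'
#' For every non-excluded region and requested channel, the mean of that
#' channel over the region's masked (molecule) pixels; regions containing
#' no molecule pixels contribute the channel's neutral value (255 for
#' R/G/B, 0 for phi/height). Features are ordered region-major (regions in
#' row-major index order, channels in the given order within each region),
#' identically for every complex.
#'
#' @param surface a rendered [SurfaceImage-class].
#' @param grid a [RegionGrid-class]; its window must lie inside the
#'   surface window.
#' @param channels subset of `c("R", "G", "B", "phi", "height")`.
#' @return named numeric vector (one feature-matrix column).
#' @export
extractFeatures <- function(surface, grid, channels = c("R", "G", "B")) {
  channels <- match.arg(channels, c("R", "G", "B", "phi", "height"),
                        several.ok = TRUE)
  w <- grid@window; sw <- surface@window
  if (w[1] < sw[1] - 1e-9 || w[2] > sw[2] + 1e-9 ||
      w[3] < sw[3] - 1e-9 || w[4] > sw[4] + 1e-9)
    stop("region grid window extends beyond the surface window")
  if (any(channels %in% c("R", "G", "B")) && !length(surface@rgb))
    surface <- renderSurface(surface)
  px <- .pixelCenters(surface@window, surface@pixelSize)
  inWin <- outer(px$xs >= w[1] & px$xs <= w[2],
                 px$ys >= w[3] & px$ys <= w[4], "&")
  rx <- pmin(grid@nx, pmax(1L, ceiling((px$xs - w[1]) / ((w[2] - w[1]) / grid@nx))))
  ry <- pmin(grid@ny, pmax(1L, ceiling((px$ys - w[3]) / ((w[4] - w[3]) / grid@ny))))
  region <- outer(rx, (ry - 1L) * grid@nx, "+")
  use <- surface@mask & inWin

  chan <- list(
    R = if (length(surface@rgb)) surface@rgb[, , 1] else NULL,
    G = if (length(surface@rgb)) surface@rgb[, , 2] else NULL,
    B = if (length(surface@rgb)) surface@rgb[, , 3] else NULL,
    phi = surface@potential,
    height = surface@height)
  keep <- setdiff(seq_len(grid@nx * grid@ny), grid@excluded)
  anyPixels <- FALSE
  out <- numeric(0)
  for (reg in keep) {
    sel <- use & region == reg
    hasPx <- any(sel)
    anyPixels <- anyPixels || hasPx
    for (ch in channels) {
      v <- if (hasPx) mean(chan[[ch]][sel]) else .channelNeutral[[ch]]
      out <- c(out, v)
      names(out)[length(out)] <- sprintf("r%02d_%s", reg, ch)
    }
  }
  if (!anyPixels)
    stop("every region is empty (no molecule pixels); degenerate features")
  out
}

#' Build the feature matrix for a set of complexes
#'
#' @param surfaces list of rendered [SurfaceImage-class] objects.
#' @param grid a [RegionGrid-class].
#' @param channels channels passed to [extractFeatures()].
#' @return numeric matrix, features x complexes, with feature ids as row
#'   names and complex labels as column names.
#' @export
featureMatrix <- function(surfaces, grid = regionGrid(),
                          channels = c("R", "G", "B")) {
  cols <- lapply(surfaces, extractFeatures, grid = grid, channels = channels)
  ids <- names(cols[[1]])
  for (cc in cols) if (!identical(names(cc), ids))
    stop("inconsistent feature ids across complexes")
  m <- do.call(cbind, cols)
  rownames(m) <- ids
  colnames(m) <- unname(vapply(surfaces, structureLabel, character(1)))
  if (anyDuplicated(colnames(m))) stop("duplicate complex labels")
  if (nrow(m) < 4L) stop("need at least 4 features")
  m
}

#' Write / read a feature matrix as CSV
#'
#' One row per feature (row names = feature ids), one column per complex.
#' Output is deterministic for identical inputs.
#'
#' @param features feature matrix from [featureMatrix()].
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
writeFeaturesCSV <- function(features, path) {
  df <- data.frame(feature = rownames(features), features,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeFeaturesCSV
#' @export
readFeaturesCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Export the rendered surface as an 8-bit RGB PNG
#'
#' @param surface a rendered [SurfaceImage-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSurfacePNG <- function(surface, path) {
  if (!length(surface@rgb)) stop("surface not rendered")
  d <- dim(surface@rgb)
  ## image rows run top-down: row 1 = largest y
  img <- aperm(surface@rgb[, d[2]:1, , drop = FALSE], c(2, 1, 3)) / 255
  png::writePNG(img, path)
  invisible(path)
}
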