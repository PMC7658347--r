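## Density-grid machinery: Gaussian map simulation, MRC2014 I/O, masked
## cross-correlation, local rigid-body fitting, zone masking and
## nucleotide-site density scoring.
##
## Grid convention: values[i, j, k] sits at world position
## origin + (i-1, j-1, k-1) * voxelSize (axes X, Y, Z).

.DEFAULT_SIGMA_FACTOR <- 1 / (pi * sqrt(2))

.ATOMIC_NUMBERS <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16,
                     MG = 12, K = 19, NA. = 11, FE = 26, ZN = 30, CA = 20)

#' Density simulation parameters
#'
#' The Gaussian width is sigma = sigmaFactor * resolution; the default
#' sigmaFactor 1/(pi*sqrt(2)) ~ 0.225 is the common Gaussian-resolution
#' convention of interactive map-simulation tools.
#'
#' @param resolution Nominal resolution, Angstrom.
#' @param sigmaFactor Dimensionless width factor.
#' @param amplitudeMode "unit" (every atom weight 1) or "atomic_number".
#' @param padding Grid padding beyond the atom bounding box, Angstrom;
#'   default 3 * sigma.
#' @return A list of class "SimulationParams".
#' @export
simulationParams <- function(resolution = 3.6,
                             sigmaFactor = .DEFAULT_SIGMA_FACTOR,
                             amplitudeMode = c("unit", "atomic_number"),
                             padding = NULL) {
  stopifnot(resolution > 0, sigmaFactor > 0)
  amplitudeMode <- match.arg(amplitudeMode)
  structure(list(resolution = resolution, sigmaFactor = sigmaFactor,
                 amplitudeMode = amplitudeMode,
                 padding = padding %||% 3 * sigmaFactor * resolution),
            class = "SimulationParams")
}

#' Construct a DensityMap
#'
#' @param values 3D numeric array.
#' @param voxelSize Isotropic voxel edge, Angstrom.
#' @param origin World position of voxel (1,1,1) center, Angstrom.
#' @return A [DensityMap-class].
#' @export
densityMap <- function(values, voxelSize, origin = c(0, 0, 0)) {
  new("DensityMap", values = values, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

.atomWeights <- function(elesy, mode) {
  if (mode == "unit") return(rep(1, length(elesy)))
  z <- .ATOMIC_NUMBERS[toupper(trimws(elesy))]
  z[is.na(z)] <- 6
  unname(z)
}

.coordsOf <- function(s) {
  if (is(s, "AtomicStructure")) coords(s)
  else .assertFiniteMatrix(as.matrix(s), "atom coordinates")
}

#' Simulate a density map from atomic coordinates
#'
#' Places an isotropic 3D Gaussian of width sigma = sigmaFactor *
#' resolution at every atom position and sums them on a regular grid
#' covering the atom bounding box plus padding. The per-atom kernel is
#' truncated at 6 sigma (relative error < 1e-7).
#'
#' @param s An [AtomicStructure-class] or an n x 3 coordinate matrix.
#' @param params A [simulationParams()] list.
#' @param voxelSize Grid voxel edge, Angstrom; must satisfy
#'   resolution >= 2 * voxelSize (sampling guard).
#' @return A [DensityMap-class].
#' @export
simulateDensity <- function(s, params = simulationParams(),
                            voxelSize = 1.0) {
  xyz <- .coordsOf(s)
  if (!nrow(xyz)) stop("need at least one atom")
  if (params$resolution < 2 * voxelSize)
    stop("resolution (", params$resolution, " A) must be >= 2 * voxelSize (",
         2 * voxelSize, " A) to avoid aliasing")
  sigma <- params$sigmaFactor * params$resolution
  w <- if (is(s, "AtomicStructure"))
    .atomWeights(atoms(s)$elesy, params$amplitudeMode)
  else rep(1, nrow(xyz))

  lo <- apply(xyz, 2, min) - params$padding
  hi <- apply(xyz, 2, max) + params$padding
  n <- pmax(2L, as.integer(ceiling((hi - lo) / voxelSize)) + 1L)
  vals <- array(0, dim = n)
  ax <- lapply(1:3, function(d) lo[d] + (seq_len(n[d]) - 1L) * voxelSize)

  cut <- 6 * sigma
  inv2s2 <- 1 / (2 * sigma^2)
  for (i in seq_len(nrow(xyz))) {
    rng <- lapply(1:3, function(d) {
      which(ax[[d]] >= xyz[i, d] - cut & ax[[d]] <= xyz[i, d] + cut)
    })
    if (!all(lengths(rng))) next
    gx <- exp(-(ax[[1]][rng[[1]]] - xyz[i, 1])^2 * inv2s2)
    gy <- exp(-(ax[[2]][rng[[2]]] - xyz[i, 2])^2 * inv2s2)
    gz <- exp(-(ax[[3]][rng[[3]]] - xyz[i, 3])^2 * inv2s2)
    vals[rng[[1]], rng[[2]], rng[[3]]] <-
      vals[rng[[1]], rng[[2]], rng[[3]]] +
      w[i] * (gx %o% gy %o% gz)
  }
  densityMap(vals, voxelSize, lo)
}

## world -> fractional zero-based grid index
.worldToGrid <- function(m, xyz) {
  sweep(xyz, 2, m@origin) / m@voxelSize
}

#' Trilinear interpolation of a map
#'
#' @param m A [DensityMap-class].
#' @param xyz n x 3 matrix of world coordinates, Angstrom.
#' @param outside Value returned for points outside the grid (default 0).
#' @return Numeric vector of interpolated values.
#' @export
mapInterpolate <- function(m, xyz, outside = 0) {
  g <- .worldToGrid(m, .assertFiniteMatrix(as.matrix(xyz), "points"))
  d <- dim(m@values)
  i0 <- floor(g)
  f <- g - i0
  ok <- i0[, 1] >= 0 & i0[, 2] >= 0 & i0[, 3] >= 0 &
    i0[, 1] <= d[1] - 2 & i0[, 2] <= d[2] - 2 & i0[, 3] <= d[3] - 2
  out <- rep(outside, nrow(g))
  if (!any(ok)) return(out)
  i <- i0[ok, , drop = FALSE] + 1L
  fx <- f[ok, 1]; fy <- f[ok, 2]; fz <- f[ok, 3]
  v <- m@values
  idx <- function(a, b, c) v[cbind(i[, 1] + a, i[, 2] + b, i[, 3] + c)]
  out[ok] <-
    idx(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    idx(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    idx(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    idx(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    idx(1, 1, 0) * fx * fy * (1 - fz) +
    idx(1, 0, 1) * fx * (1 - fy) * fz +
    idx(0, 1, 1) * (1 - fx) * fy * fz +
    idx(1, 1, 1) * fx * fy * fz
  out
}

## voxel centers of a map as an n x 3 matrix (column-major order)
.voxelCenters <- function(m) {
  d <- dim(m@values)
  g <- as.matrix(expand.grid(x = seq_len(d[1]) - 1L,
                             y = seq_len(d[2]) - 1L,
                             z = seq_len(d[3]) - 1L))
  sweep(g * m@voxelSize, 2, m@origin, "+")
}

#' Resample a map onto the grid of another
#'
#' Trilinear interpolation of `m` at the voxel centers of `onto`.
#'
#' @param m,onto [DensityMap-class] objects.
#' @return A [DensityMap-class] on the grid of `onto`.
#' @export
resampleMap <- function(m, onto) {
  vals <- mapInterpolate(m, .voxelCenters(onto))
  densityMap(array(vals, dim = dim(onto@values)), onto@voxelSize,
             onto@origin)
}

.boundsOverlap <- function(a, b) {
  hiA <- a@origin + (dim(a@values) - 1L) * a@voxelSize
  hiB <- b@origin + (dim(b@values) - 1L) * b@voxelSize
  all(a@origin <= hiB + 1e-9) && all(b@origin <= hiA + 1e-9)
}

#' Cross-correlation of two density maps
#'
#' Normalized inner product of the two value vectors over the (optionally
#' masked) voxels of `a`'s grid; `b` is resampled onto `a`'s grid by
#' trilinear interpolation when the grids differ. With `aboutMean = TRUE`
#' the masked means are subtracted first (Pearson-style correlation,
#' invariant to positive affine rescaling of either map).
#'
#' @param a,b [DensityMap-class] objects.
#' @param mask Optional logical array on `a`'s grid selecting voxels.
#' @param aboutMean Subtract masked means before normalising (default TRUE).
#' @return A [CorrelationResult-class].
#' @export
crossCorrelation <- function(a, b, mask = NULL, aboutMean = TRUE) {
  sameGrid <- identical(dim(a@values), dim(b@values)) &&
    isTRUE(all.equal(a@voxelSize, b@voxelSize)) &&
    max(abs(a@origin - b@origin)) < 1e-9
  if (!sameGrid) {
    if (!.boundsOverlap(a, b))
      stop("map bounding boxes are disjoint; cannot correlate")
    b <- resampleMap(b, a)
  }
  va <- as.vector(a@values); vb <- as.vector(b@values)
  if (!is.null(mask)) {
    mk <- as.vector(mask)
    if (length(mk) != length(va)) stop("mask does not match the grid of 'a'")
    if (!any(mk)) stop("mask selects no voxels")
    va <- va[mk]; vb <- vb[mk]
  }
  if (aboutMean) {
    va <- va - mean(va); vb <- vb - mean(vb)
  }
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) {
    if (aboutMean) stop("zero-variance input under about-mean correlation")
    stop("cannot normalise an all-zero map")
  }
  new("CorrelationResult", cc = sum(va * vb) / (na * nb),
      nVoxels = length(va), aboutMean = aboutMean)
}

#' Gaussian-smooth a density map
#'
#' Separable Gaussian convolution on the grid (kernel truncated at
#' 3 sigma), used for coarse-to-fine rigid-body fitting.
#'
#' @param m A [DensityMap-class].
#' @param sigma Smoothing width in Angstrom.
#' @return The smoothed [DensityMap-class].
#' @export
smoothMap <- function(m, sigma) {
  if (sigma <= 0) return(m)
  sv <- sigma / m@voxelSize
  hw <- max(1L, ceiling(3 * sv))
  k <- exp(-(seq(-hw, hw))^2 / (2 * sv^2))
  k <- k / sum(k)
  v <- m@values
  d <- dim(v)
  conv1 <- function(x) {                  # convolve columns of a matrix
    n <- nrow(x)
    pad <- rbind(matrix(0, hw, ncol(x)), x, matrix(0, hw, ncol(x)))
    out <- matrix(0, n, ncol(x))
    for (j in seq_along(k))
      out <- out + k[j] * pad[j:(j + n - 1), , drop = FALSE]
    out
  }
  v <- array(conv1(matrix(v, d[1])), d)
  v <- aperm(array(conv1(matrix(aperm(v, c(2, 1, 3)), d[2])),
                   d[c(2, 1, 3)]), c(2, 1, 3))
  v <- aperm(array(conv1(matrix(aperm(v, c(3, 1, 2)), d[3])),
                   d[c(3, 1, 2)]), c(2, 3, 1))
  densityMap(v, m@voxelSize, m@origin)
}

## 6-dof parameterisation about the atom centroid:
## x' = R(angles) (x - c0) + c0 + shift
.paramTransform <- function(par, c0) {
  R <- rotationMatrix(c(1, 0, 0), par[4] * 180 / pi) %*%
    rotationMatrix(c(0, 1, 0), par[5] * 180 / pi) %*%
    rotationMatrix(c(0, 0, 1), par[6] * 180 / pi)
  rigidTransform(R, c0 + par[1:3] - as.vector(R %*% c0))
}

#' Local rigid-body fit of a model segment into a density map
#'
#' Maximizes the mean trilinearly interpolated map value at the atom
#' positions over the 6 rigid-body degrees of freedom. The search is
#' strictly local but coarse-to-fine: the placement is first refined
#' against Gaussian-smoothed copies of the map (default 6, 3, 1.5, 0
#' Angstrom extra width), which widens the attraction basin, then
#' polished on the unsmoothed map. Within each level, derivative-free
#' optimization (Nelder-Mead) is restarted until the placement moves by
#' less than 0.01 Angstrom and 0.01 degrees.
#'
#' @param s An [AtomicStructure-class] segment or n x 3 coordinate matrix.
#' @param m A [DensityMap-class].
#' @param start A [RigidTransform-class] start placement (default
#'   identity).
#' @param smoothSchedule Decreasing smoothing widths in Angstrom, ending
#'   at 0 (the original map).
#' @param maxRestarts Maximum optimizer restarts per smoothing level.
#' @return List with components `transform` ([RigidTransform-class]),
#'   `score` (mean map value at the fitted positions), and `converged`.
#' @export
rigidBodyFit <- function(s, m, start = rigidTransform(),
                         smoothSchedule = c(6, 3, 1.5, 0),
                         maxRestarts = 20L) {
  xyz0 <- .coordsOf(s)
  xyz <- applyTransform(xyz0, start)
  if (sum(mapInterpolate(m, xyz, outside = NA_real_) > -Inf,
          na.rm = TRUE) < 3)
    stop("fewer than 3 atoms inside the map bounds at the start placement")
  c0 <- colMeans(xyz)
  ctrl <- list(maxit = 2000, reltol = 1e-12,
               parscale = c(1, 1, 1, 0.05, 0.05, 0.05))
  par <- rep(0, 6)
  converged <- FALSE
  for (sg in sort(unique(c(smoothSchedule, 0)), decreasing = TRUE)) {
    lvl <- smoothMap(m, sg)
    objective <- function(p)
      -mean(mapInterpolate(lvl, applyTransform(xyz, .paramTransform(p, c0))))
    converged <- FALSE
    for (it in seq_len(maxRestarts)) {
      opt <- stats::optim(par, objective, method = "Nelder-Mead",
                          control = ctrl)
      dShift <- sqrt(sum((opt$par[1:3] - par[1:3])^2))
      dRot <- rotationDifference(.paramTransform(opt$par, c0)@rotation,
                                 .paramTransform(par, c0)@rotation)
      par <- opt$par
      if (dShift < 0.01 && dRot < 0.01) { converged <- TRUE; break }
    }
  }
  ## fine polish on the unsmoothed map with a shrinking simplex
  objective <- function(p)
    -mean(mapInterpolate(m, applyTransform(xyz, .paramTransform(p, c0))))
  for (sc in c(0.2, 0.05)) {
    ctrl2 <- ctrl
    ctrl2$parscale <- ctrl$parscale * sc
    for (it in seq_len(5L)) {
      opt <- stats::optim(par, objective, method = "Nelder-Mead",
                          control = ctrl2)
      mv <- sqrt(sum((opt$par[1:3] - par[1:3])^2))
      par <- opt$par
      if (mv < 0.002) break
    }
  }
  if (!converged)
    warning("rigid-body fit did not converge; returning best placement")
  refine <- .paramTransform(par, c0)
  list(transform = composeTransform(refine, start),
       score = mean(mapInterpolate(m, applyTransform(
         xyz, .paramTransform(par, c0)))),
       converged = converged)
}

## logical array marking voxels whose center is within radius of any atom
.zoneSelect <- function(m, xyz, radius) {
  d <- dim(m@values)
  sel <- array(FALSE, dim = d)
  if (!nrow(xyz) || radius < 0) return(sel)
  vs <- m@voxelSize
  ax <- lapply(1:3, function(dd) m@origin[dd] + (seq_len(d[dd]) - 1L) * vs)
  r2 <- radius^2
  for (i in seq_len(nrow(xyz))) {
    rng <- lapply(1:3, function(dd)
      which(abs(ax[[dd]] - xyz[i, dd]) <= radius))
    if (!all(lengths(rng))) next
    dx2 <- (ax[[1]][rng[[1]]] - xyz[i, 1])^2
    dy2 <- (ax[[2]][rng[[2]]] - xyz[i, 2])^2
    dz2 <- (ax[[3]][rng[[3]]] - xyz[i, 3])^2
    within <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r2
    sel[rng[[1]], rng[[2]], rng[[3]]] <-
      sel[rng[[1]], rng[[2]], rng[[3]]] | within
  }
  sel
}

#' Zone-mask a density map around a set of atoms
#'
#' Voxels whose center lies within `radius` of any atom are zeroed
#' (`mode = "remove"`) or exclusively retained (`mode = "keep"`); all
#' other values are unchanged. The remove and keep outputs of the same
#' call partition the map: they sum voxel-wise to the original.
#'
#' @param m A [DensityMap-class].
#' @param s An [AtomicStructure-class] or n x 3 coordinate matrix.
#' @param radius Zone radius, Angstrom (>= 0).
#' @param mode "remove" or "keep".
#' @return A [DensityMap-class].
#' @export
zoneMask <- function(m, s, radius, mode = c("remove", "keep")) {
  mode <- match.arg(mode)
  if (radius < 0) stop("radius must be >= 0")
  xyz <- if (is.null(s)) matrix(0, 0, 3) else .coordsOf(s)
  sel <- .zoneSelect(m, xyz, radius)
  vals <- m@values
  if (mode == "remove") vals[sel] <- 0 else vals[!sel] <- 0
  densityMap(vals, m@voxelSize, m@origin)
}

#' Score ligand-moiety density occupancy
#'
#' For each moiety (e.g. guanosine + alpha/beta phosphates vs the
#' gamma-phosphate) reports the mean map value over voxels within
#' `radius` of the moiety atoms, plus the ratio of the probe moiety's
#' mean to the mean of the remaining moieties. A ratio below `threshold`
#' labels the site "GDP-like" (probe moiety not covered by density); a
#' zero-density map gives an indeterminate call.
#'
#' @param m A [DensityMap-class].
#' @param moieties Named list of n x 3 coordinate matrices (or
#'   [AtomicStructure-class] objects), ligand atoms grouped by moiety.
#' @param radius Zone radius, Angstrom.
#' @param probe Name of the moiety whose occupancy is questioned
#'   (default "gamma_phosphate").
#' @param threshold Ratio below which the site is called "GDP-like".
#' @return List with `means` (named numeric), `ratio`, and `label`
#'   ("GDP-like", "not-GDP-like" or "indeterminate").
#' @export
ligandSiteScore <- function(m, moieties, radius = 2.5,
                            probe = "gamma_phosphate", threshold = 0.5) {
  if (is.null(names(moieties)) || !probe %in% names(moieties))
    stop("moieties must be a named list containing '", probe, "'")
  means <- vapply(names(moieties), function(nm) {
    xyz <- .coordsOf(moieties[[nm]])
    if (!nrow(xyz)) stop("moiety '", nm, "' has no atoms")
    sel <- .zoneSelect(m, xyz, radius)
    if (!any(sel)) return(0)
    mean(m@values[sel])
  }, numeric(1))
  rest <- mean(means[setdiff(names(means), probe)])
  if (!is.finite(rest) || abs(rest) < 1e-12) {
    return(list(means = means, ratio = NA_real_, label = "indeterminate"))
  }
  ratio <- means[[probe]] / rest
  list(means = means, ratio = ratio,
       label = if (ratio < threshold) "GDP-like" else "not-GDP-like")
}

## ---- MRC2014 I/O --------------------------------------------------------
## Mode-2 (float32) MRC/CCP4 maps. Axis order (MAPC/MAPR/MAPS) is
## normalized to X,Y,Z on read; the origin is taken from the ORIGIN
## header fields, falling back to N*START * voxel when ORIGIN is all zero.

#' Read an MRC/CCP4 density map
#'
#' @param path Path to an MRC2014 file (modes 0, 1, 2, 6 supported).
#' @return A [DensityMap-class] with axes normalized to X, Y, Z.
#' @export
readMRC <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdrInt <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdrFlt <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nxyz <- hdrInt[1:3]
  mode <- hdrInt[4]
  nstart <- hdrInt[5:7]
  mxyz <- hdrInt[8:10]
  cella <- hdrFlt[11:13]
  mapcrs <- hdrInt[17:19]
  originXYZ <- hdrFlt[50:52]
  nsymbt <- hdrInt[24]
  if (any(nxyz <= 0) || any(nxyz > 4000)) stop("implausible MRC dimensions")
  seek(con, 1024 + nsymbt)
  nvox <- prod(nxyz)
  vals <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = nvox, size = 1, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = nvox, size = 2, endian = "little"),
    "2" = readBin(con, "numeric", n = nvox, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n = nvox, size = 2, signed = FALSE,
                  endian = "little"),
    stop("unsupported MRC mode: ", mode))
  if (length(vals) < nvox) stop("truncated MRC data block")
  arr <- array(as.numeric(vals), dim = nxyz)
  vsize <- cella / ifelse(mxyz > 0, mxyz, nxyz)
  if (max(vsize) - min(vsize) > 1e-3)
    warning("anisotropic voxels; using the mean voxel size")
  ## permute stored axes (columns/rows/sections) to X, Y, Z
  perm <- order(mapcrs)
  if (!identical(mapcrs, c(1L, 2L, 3L))) {
    arr <- aperm(arr, perm)
    nstart <- nstart[perm]
  }
  vs <- mean(vsize)
  org <- if (any(abs(originXYZ) > 1e-6)) originXYZ else nstart * vs
  densityMap(arr, vs, org)
}

#' Write a density map as MRC2014 (mode 2)
#'
#' @param m A [DensityMap-class].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
writeMRC <- function(m, path) {
  d <- dim(m@values)
  con <- file(path, "wb")
  on.exit(close(con))
  wI <- function(x) writeBin(as.integer(x), con, size = 4,
                             endian = "little")
  wF <- function(x) writeBin(as.numeric(x), con, size = 4,
                             endian = "little")
  vals <- as.vector(m@values)
  wI(d)                        # NX NY NZ
  wI(2)                        # MODE 2 float
  wI(c(0, 0, 0))               # NXSTART..
  wI(d)                        # MX MY MZ
  wF(d * m@voxelSize)          # CELLA
  wF(c(90, 90, 90))            # CELLB
  wI(c(1, 2, 3))               # MAPC MAPR MAPS
  wF(c(min(vals), max(vals), mean(vals)))  # DMIN DMAX DMEAN
  wI(1)                        # ISPG
  wI(0)                        # NSYMBT
  wI(rep(0, 25))               # EXTRA (words 25..49)
  wF(m@origin)                 # ORIGIN X Y Z
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wF(stats::sd(vals))          # RMS
  wI(0)                        # NLABL
  writeBin(raw(800), con)      # labels
  wF(vals)
  invisible(path)
}
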