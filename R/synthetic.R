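## Synthetic two-spoke Y-shaped assemblies with known ground truth.
## Each spoke is three rigid blocks (GRIP1, GRIP2, gamma-body) of ideal
## poly-alanine Calpha helices (rise 1.5 A, 100 degree twist, 2.3 A
## radius). Between the "open" and "closed" states the spoke-2
## GRIP2 + gamma block is tilted by a known angle about a known hinge,
## so per-segment displacement has a closed form.

.TOY_SEGMENTS <- c("Spc97-GRIP1", "Spc97-GRIP2", "Spc97-gamma",
                   "Spc98-GRIP1", "Spc98-GRIP2", "Spc98-gamma")

#' Parameters of the synthetic two-spoke generator
#'
#' @param nHelicesPerDomain Helices per rigid block (default 3).
#' @param helixLength Residues per helix (default 20).
#' @param tiltAngle Tilt in degrees (in [0, 60], default 15) applied to
#'   the spoke-2 GRIP2 + gamma block between the two states.
#' @param noiseSigma Per-coordinate Gaussian noise added to the closed
#'   state, Angstrom (default 0).
#' @param seed Integer RNG seed (default 1).
#' @return A [ToySpokeParams-class].
#' @export
toySpokeParams <- function(nHelicesPerDomain = 3L, helixLength = 20L,
                           tiltAngle = 15, noiseSigma = 0, seed = 1L) {
  new("ToySpokeParams", nHelicesPerDomain = as.integer(nHelicesPerDomain),
      helixLength = as.integer(helixLength), tiltAngle = tiltAngle,
      noiseSigma = noiseSigma, seed = as.integer(seed))
}

## Calpha trace of one ideal helix along unit direction d from base
.helixTrace <- function(base, d, u, L) {
  v <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  i <- seq_len(L) - 1
  phi <- i * 100 * pi / 180
  t(vapply(seq_len(L), function(k)
    base + d * (1.5 * i[k]) + 2.3 * (cos(phi[k]) * u + sin(phi[k]) * v),
    numeric(3)))
}

## one rigid block: a small bundle of parallel helices
.helixBlock <- function(base, d, u, nHelices, L) {
  v <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  do.call(rbind, lapply(seq_len(nHelices) - 1L, function(j)
    .helixTrace(base + u * (9 * j) + v * (4 * (j %% 2)), d, u, L)))
}

## deterministic geometry of the open state; returns per-segment coords
.toyGeometry <- function(p) {
  nh <- p@nHelicesPerDomain; L <- p@helixLength
  blockRise <- (L - 1) * 1.5 + 6          # block height + inter-block gap
  mk <- function(base, d) {
    u <- c(d[3], 0, -d[1])                 # in-plane normal to d
    u <- u / sqrt(sum(u^2))
    list(GRIP1 = .helixBlock(base, d, u, nh, L),
         GRIP2 = .helixBlock(base + d * blockRise, d, u, nh, L),
         gamma = .helixBlock(base + d * 2 * blockRise, d, u, nh, L),
         hinge = base + d * blockRise)
  }
  a1 <- -12 * pi / 180; a2 <- 12 * pi / 180
  s1 <- mk(c(-14, 0, 0), c(sin(a1), 0, cos(a1)))
  s2 <- mk(c(14, 0, 0), c(sin(a2), 0, cos(a2)))
  list(
    segs = list(
      "Spc97-GRIP1" = s1$GRIP1, "Spc97-GRIP2" = s1$GRIP2,
      "Spc97-gamma" = s1$gamma,
      "Spc98-GRIP1" = s2$GRIP1, "Spc98-GRIP2" = s2$GRIP2,
      "Spc98-gamma" = s2$gamma),
    hinge2 = s2$hinge)
}

## map segment name -> (chain, residue offset)
.toyLayout <- function(p) {
  nRes <- p@nHelicesPerDomain * p@helixLength
  list("Spc97-GRIP1" = list(chain = "A", offset = 0L),
       "Spc97-GRIP2" = list(chain = "A", offset = nRes),
       "Spc97-gamma" = list(chain = "C", offset = 0L),
       "Spc98-GRIP1" = list(chain = "B", offset = 0L),
       "Spc98-GRIP2" = list(chain = "B", offset = nRes),
       "Spc98-gamma" = list(chain = "D", offset = 0L),
       nRes = nRes)
}

.toyStructure <- function(id, segs, p) {
  lay <- .toyLayout(p)
  rows <- lapply(.TOY_SEGMENTS, function(nm) {
    xyz <- segs[[nm]]
    data.frame(chain = lay[[nm]]$chain,
               resno = lay[[nm]]$offset + seq_len(nrow(xyz)),
               insert = "", resid = "ALA", elety = "CA", elesy = "C",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1,
               het = FALSE, stringsAsFactors = FALSE)
  })
  atomicStructure(id, do.call(rbind, rows))
}

#' Segment definitions of the synthetic assembly
#'
#' @param p A [toySpokeParams()] object.
#' @param atomSubset Atom subset for the specs (default "CA_ONLY"; the
#'   toy models carry Calpha atoms only).
#' @return Named list of six [SegmentSpec-class] objects.
#' @export
toySegmentSpecs <- function(p = toySpokeParams(),
                            atomSubset = "CA_ONLY") {
  lay <- .toyLayout(p)
  out <- lapply(.TOY_SEGMENTS, function(nm)
    segmentSpec(nm, chain = lay[[nm]]$chain,
                first = lay[[nm]]$offset + 1L,
                last = lay[[nm]]$offset + lay$nRes,
                atomSubset = atomSubset))
  names(out) <- .TOY_SEGMENTS
  out
}

#' Generate a synthetic open/closed conformational pair
#'
#' Builds the two-spoke assembly in an "open" state and a "closed" state
#' that differs only by a rigid tilt of the spoke-2 GRIP2 + gamma block
#' about the spoke-2 inter-domain hinge (plus optional seeded Gaussian
#' coordinate noise on the closed state). Ground-truth per-segment
#' transforms and the analytic displacement they imply are returned
#' alongside.
#'
#' @param p A [toySpokeParams()] object.
#' @return List with components `open` and `closed`
#'   ([AtomicStructure-class]), `segments` (named [SegmentSpec-class]
#'   list), and `groundTruth`: per-segment [RigidTransform-class] list,
#'   `expectedRmsd` and `expectedMeanDisp` (named, Angstrom, noise-free
#'   closed form), the `tiltAngle`, hinge and axis, and the analytic
#'   inter-gamma centroid distances `dOpen`/`dClosed`.
#' @export
#' @examples
#' pair <- makeToyPair(toySpokeParams(tiltAngle = 15))
#' pair$groundTruth$expectedRmsd
makeToyPair <- function(p = toySpokeParams()) {
  geo <- .toyGeometry(p)
  axis <- c(0, 1, 0)
  R <- rotationMatrix(axis, -p@tiltAngle)
  hinge <- geo$hinge2
  tiltTr <- rigidTransform(R, hinge - as.vector(R %*% hinge))
  moved <- c("Spc98-GRIP2", "Spc98-gamma")

  closedSegs <- geo$segs
  for (nm in moved)
    closedSegs[[nm]] <- applyTransform(closedSegs[[nm]], tiltTr)

  trs <- lapply(.TOY_SEGMENTS, function(nm)
    if (nm %in% moved) tiltTr else rigidTransform())
  names(trs) <- .TOY_SEGMENTS
  expectedRmsd <- vapply(.TOY_SEGMENTS, function(nm) {
    d <- closedSegs[[nm]] - geo$segs[[nm]]
    sqrt(mean(rowSums(d^2)))
  }, numeric(1))
  expectedMeanDisp <- vapply(.TOY_SEGMENTS, function(nm) {
    d <- closedSegs[[nm]] - geo$segs[[nm]]
    mean(sqrt(rowSums(d^2)))
  }, numeric(1))

  open <- .toyStructure("toy-open", geo$segs, p)
  closed <- .toyStructure("toy-closed", closedSegs, p)
  if (p@noiseSigma > 0) {
    noisy <- .withSeed(p@seed, coords(closed) +
                         matrix(stats::rnorm(3 * nAtoms(closed),
                                             sd = p@noiseSigma),
                                ncol = 3))
    closed@atoms$x <- noisy[, 1]
    closed@atoms$y <- noisy[, 2]
    closed@atoms$z <- noisy[, 3]
  }

  cen <- function(segs, nm) colMeans(segs[[nm]])
  list(open = open, closed = closed, segments = toySegmentSpecs(p),
       groundTruth = list(
         transforms = trs, expectedRmsd = expectedRmsd,
         expectedMeanDisp = expectedMeanDisp, tiltAngle = p@tiltAngle,
         hinge = hinge, axis = axis,
         dOpen = sqrt(sum((cen(geo$segs, "Spc97-gamma") -
                             cen(geo$segs, "Spc98-gamma"))^2)),
         dClosed = sqrt(sum((cen(closedSegs, "Spc97-gamma") -
                               cen(closedSegs, "Spc98-gamma"))^2))))
}

#' Simulate a noisy density map of a structure
#'
#' [simulateDensity()] followed by seeded i.i.d. Gaussian voxel noise.
#'
#' @param s An [AtomicStructure-class] or n x 3 coordinate matrix.
#' @param resolution Nominal resolution, Angstrom (default 3.6).
#' @param voxelSize Grid voxel edge, Angstrom (default 1.2).
#' @param noiseSigma Voxel noise standard deviation, map units.
#' @param seed Integer RNG seed.
#' @return A [DensityMap-class].
#' @export
makeToyMap <- function(s, resolution = 3.6, voxelSize = 1.2,
                       noiseSigma = 0, seed = 1L) {
  m <- simulateDensity(s, simulationParams(resolution = resolution),
                       voxelSize)
  if (noiseSigma > 0) {
    noise <- .withSeed(seed, stats::rnorm(length(m@values),
                                          sd = noiseSigma))
    m@values <- m@values + array(noise, dim = dim(m@values))
  }
  m
}

#' Mutate residue identities (coordinates untouched)
#'
#' Renames a random fraction of residues to a different standard amino
#' acid; used to exercise sequence-matched superposition on homologs with
#' identical folds.
#'
#' @param s An [AtomicStructure-class].
#' @param fraction Fraction of residues to mutate, in [0, 1].
#' @param seed Integer RNG seed.
#' @return The mutated [AtomicStructure-class].
#' @export
mutateResidues <- function(s, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  aaNames <- setdiff(names(kdHydropathy), "GLY")
  a <- atoms(s)
  key <- .resKey(a$chain, a$resno, a$insert)
  resKeys <- unique(key)
  .withSeed(seed, {
    pick <- sample(resKeys, size = round(fraction * length(resKeys)))
    for (k in pick) {
      old <- a$resid[key == k][1]
      a$resid[key == k] <- sample(setdiff(aaNames, old), 1)
    }
  })
  s@atoms <- a
  s
}
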