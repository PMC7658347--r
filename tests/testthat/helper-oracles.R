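## Independent oracles and fixture builders used across the test files.

rdiff <- TuSCmorph:::rotationDifference

## Brute-force quaternion grid search for the optimal rigid fit:
## seeded quaternion sampling with hierarchically shrinking neighborhood
## around the best rotation found; the optimal translation for each
## rotation is the centroid match. Independent of the SVD route used by
## kabsch().
quatToRot <- function(q) {
  matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[4] * q[1]),
    2 * (q[2] * q[4] + q[3] * q[1]),
    2 * (q[2] * q[3] + q[4] * q[1]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[2] * q[1]),
    2 * (q[2] * q[4] - q[3] * q[1]), 2 * (q[3] * q[4] + q[2] * q[1]),
    1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
}

quaternionGridRmsd <- function(mobile, target, perLevel = 3000,
                               levels = 8, seed = 42) {
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  rmsdOf <- function(R) sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  bestQ <- c(1, 0, 0, 0)
  best <- rmsdOf(quatToRot(bestQ))
  width <- 1
  withr::with_seed(seed, {
    for (lvl in seq_len(levels)) {
      qs <- matrix(rnorm(4 * perLevel), ncol = 4) * width +
        matrix(bestQ, perLevel, 4, byrow = TRUE)
      qs <- qs / sqrt(rowSums(qs^2))
      for (i in seq_len(perLevel)) {
        r <- rmsdOf(quatToRot(qs[i, ]))
        if (r < best) { best <- r; bestQ <- qs[i, ] }
      }
      width <- width * 0.35
    }
  })
  best
}

## a random proper rotation (seeded)
randomRotation <- function(seed, maxAngle = 180) {
  withr::with_seed(seed, {
    ax <- rnorm(3)
    rotationMatrix(ax, runif(1, 0, maxAngle))
  })
}

## hand-written minimal PDB text (three atoms, one residue)
threeAtomPDB <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      12.759   7.096  -4.973  1.00  0.00           C",
    "TER",
    "END"), path)
  path
}

## altloc fixture: one atom with conformers A (occ .6) and B (occ .4)
altlocPDB <- function(path, occA = 0.60, occB = 0.40) {
  writeLines(c(
    sprintf("ATOM      1  CA AALA A   1       1.000   0.000   0.000%6.2f  0.00           C", occA),
    sprintf("ATOM      2  CA BALA A   1       2.000   0.000   0.000%6.2f  0.00           C", occB),
    "ATOM      3  CB  ALA A   1       3.000   0.000   0.000  1.00  0.00           C",
    "TER", "END"), path)
  path
}

## straight poly-X chain: one residue per index, CA at (3.8 i, 0, z)
## with optional extra named side-chain atoms at fixed offsets
polyChain <- function(resids, chain = "A", z = 0,
                      sideAtoms = list(), spacing = 3.8) {
  rows <- list()
  for (i in seq_along(resids)) {
    x <- spacing * i
    rows[[length(rows) + 1]] <- data.frame(
      chain = chain, resno = i, insert = "", resid = resids[i],
      elety = "CA", elesy = "C", x = x, y = 0, z = z, o = 1, het = FALSE)
    for (nm in names(sideAtoms)) {
      off <- sideAtoms[[nm]]
      rows[[length(rows) + 1]] <- data.frame(
        chain = chain, resno = i, insert = "", resid = resids[i],
        elety = nm, elesy = substr(nm, 1, 1),
        x = x + off[1], y = off[2], z = z + off[3], o = 1, het = FALSE)
    }
  }
  atomicStructure(paste0("poly-", chain), do.call(rbind, rows))
}

## jittered blob of nRes single-atom residues (for contact stress tests)
randomResidueCloud <- function(nRes, chain, seed, center = c(0, 0, 0),
                               spread = 12) {
  withr::with_seed(seed, {
    xyz <- matrix(rnorm(3 * nRes, sd = spread), ncol = 3)
  })
  xyz <- sweep(xyz, 2, center, "+")
  atomicStructure(paste0("cloud-", chain), data.frame(
    chain = chain, resno = seq_len(nRes), insert = "", resid = "GLY",
    elety = "CA", elesy = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    o = 1, het = FALSE))
}

## sorted canonical form of a contact table, for set comparisons
contactKey <- function(ct) {
  sort(paste(ct$chainA, ct$resnoA, ct$chainB, ct$resnoB,
             round(ct$minDist, 9)))
}

## small classification fixture: one two-helix bundle as the "subunit";
## the "curved" reference differs INTERNALLY (second helix shifted
## relative to the body), mirroring how the curved and straight tubulin
## conformations differ in their helix arrangement. A rigidly moved copy
## would be useless here because rigid docking undoes rigid differences.
.classifyFixture <- function() {
  p <- toySpokeParams(nHelicesPerDomain = 2L, helixLength = 12L)
  pair <- makeToyPair(p)
  gamma <- selectSegment(pair$open, pair$segments[["Spc97-gamma"]])
  hr <- helixRanges("C", a6 = c(1, 12), a7 = c(13, 24))
  a <- atoms(gamma)
  sel <- a$resno >= 13
  a$x[sel] <- a$x[sel] + 1.8
  a$z[sel] <- a$z[sel] + 1.0
  curved <- atomicStructure("curved-ref", a)
  dens <- simulateDensity(gamma, simulationParams(), 0.9)
  list(gamma = gamma, hr = hr, curved = curved, dens = dens)
}

## expected rmsd inflation when rigid transforms are estimated from
## noisy targets: each 6-parameter fit adds ~ 6 sigma^2 / n to the mean
## squared per-atom placement error (first-order propagation), once for
## the segment fit and once for the anchor re-fit.
noisyTiltExpectedRmsd <- function(cleanRmsd, sigma, nSeg, nAnchor) {
  sqrt(cleanRmsd^2 + 6 * sigma^2 / nSeg + 6 * sigma^2 / nAnchor)
}
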