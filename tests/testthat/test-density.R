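test_that("a single-atom map peaks at the atom and decays monotonically along axes", {
  m <- simulateDensity(matrix(0, 1, 3), simulationParams(resolution = 4),
                       voxelSize = 1)
  v <- mapValues(m)
  peak <- which(v == max(v), arr.ind = TRUE)[1, ]
  ctr <- TuSCmorph:::.worldToGrid(m, matrix(0, 1, 3)) + 1
  expect_true(all(abs(peak - ctr) <= 0.5 + 1e-9))
  ray <- v[peak[1]:dim(v)[1], peak[2], peak[3]]
  expect_true(all(diff(ray) < 0))
  ray2 <- v[peak[1], peak[2], peak[3]:dim(v)[3]]
  expect_true(all(diff(ray2) < 0))
})

test_that("two identical atoms far apart give two equal peaks", {
  xyz <- rbind(c(0, 0, 0), c(50, 0, 0))
  m <- simulateDensity(xyz, simulationParams(resolution = 4), 1)
  v <- mapValues(m)
  left <- v[TuSCmorph:::.worldToGrid(m, matrix(c(0, 0, 0), 1))[1] + 1, , ]
  right <- v[TuSCmorph:::.worldToGrid(m, matrix(c(50, 0, 0), 1))[1] + 1, , ]
  expect_lt(abs(max(left) - max(right)), 1e-9)
})

test_that("simulated maps conserve total Gaussian mass within 1%", {
  pair <- makeToyPair(toySpokeParams())
  seg <- selectSegment(pair$open, pair$segments[["Spc97-gamma"]])
  p <- simulationParams(resolution = 3.6)
  sigma <- p$sigmaFactor * p$resolution
  m <- simulateDensity(seg, simulationParams(resolution = 3.6,
                                             padding = 4 * sigma), 1.0)
  mass <- sum(mapValues(m)) * voxelSize(m)^3
  expect_equal(mass, nAtoms(seg) * (2 * pi * sigma^2)^1.5,
               tolerance = 0.01)
})

test_that("the sampling guard refuses aliased simulation", {
  expect_error(simulateDensity(matrix(0, 1, 3),
                               simulationParams(resolution = 1.5), 1.0),
               "aliasing")
})

test_that("self-correlation is 1 and negation gives -1 about the mean", {
  pair <- makeToyPair(toySpokeParams())
  m <- makeToyMap(selectSegment(pair$open, pair$segments[["Spc97-GRIP1"]]))
  expect_equal(correlation(crossCorrelation(m, m)), 1.0, tolerance = 1e-12)
  neg <- densityMap(-mapValues(m), voxelSize(m), mapOrigin(m))
  expect_equal(correlation(crossCorrelation(m, neg, aboutMean = TRUE)),
               -1.0, tolerance = 1e-12)
})

test_that("correlation is symmetric and invariant to positive affine rescaling", {
  pair <- makeToyPair(toySpokeParams())
  a <- makeToyMap(selectSegment(pair$open, pair$segments[["Spc97-GRIP1"]]))
  b <- makeToyMap(selectSegment(pair$open, pair$segments[["Spc97-GRIP1"]]),
                  noiseSigma = 0.05, seed = 9)
  expect_lt(abs(correlation(crossCorrelation(a, b)) -
                  correlation(crossCorrelation(b, a))), 1e-9)
  b2 <- densityMap(3.7 * mapValues(b) + 0.4, voxelSize(b), mapOrigin(b))
  expect_lt(abs(correlation(crossCorrelation(a, b2, aboutMean = TRUE)) -
                  correlation(crossCorrelation(a, b, aboutMean = TRUE))),
            1e-9)
})

test_that("correlation under additive voxel noise follows the SNR closed form within 2%", {
  pair <- makeToyPair(toySpokeParams())
  seg <- selectSegment(pair$open, pair$segments[["Spc97-GRIP1"]])
  clean <- makeToyMap(seg, voxelSize = 1.2)
  snr <- 10
  sigma <- stats::sd(as.vector(mapValues(clean))) / snr
  ccs <- vapply(1:10, function(sd) {
    noisy <- makeToyMap(seg, voxelSize = 1.2, noiseSigma = sigma, seed = sd)
    correlation(crossCorrelation(clean, noisy, aboutMean = TRUE))
  }, numeric(1))
  expect_equal(mean(ccs), snr / sqrt(snr^2 + 1), tolerance = 0.02)
})

test_that("zero-variance input under about-mean correlation errors", {
  flat <- densityMap(array(1, c(4, 4, 4)), 1)
  expect_error(crossCorrelation(flat, flat, aboutMean = TRUE),
               "zero-variance")
})

test_that("disjoint maps refuse to correlate", {
  a <- densityMap(array(runif(64), c(4, 4, 4)), 1, c(0, 0, 0))
  b <- densityMap(array(runif(64), c(4, 4, 4)), 1, c(100, 0, 0))
  expect_error(crossCorrelation(a, b), "disjoint")
})

test_that("simulation commutes with rigid motion", {
  pair <- makeToyPair(toySpokeParams())
  seg <- selectSegment(pair$open, pair$segments[["Spc98-gamma"]])
  tr <- rigidTransform(rotationMatrix(c(0, 0, 1), 40), c(5, -3, 2))
  ## a 6 A map on a 1 A grid is well sampled, so interpolation error is
  ## far below the structure signal
  sim <- simulateDensity(seg, simulationParams(resolution = 6), 1.0)
  movedSim <- simulateDensity(applyTransform(seg, tr),
                              simulationParams(resolution = 6), 1.0)
  ## predict the moved simulation by sampling the static one through the
  ## inverse motion, then correlate the two value vectors
  centers <- TuSCmorph:::.voxelCenters(movedSim)
  predicted <- mapInterpolate(sim, applyTransform(centers,
                                                  invertTransform(tr)))
  cc <- stats::cor(predicted, as.vector(mapValues(movedSim)))
  expect_gt(cc, 0.999)
})

test_that("rigid-body fit from the true placement stays put", {
  pair <- makeToyPair(toySpokeParams())
  seg <- selectSegment(pair$open, pair$segments[["Spc97-GRIP1"]])
  m <- simulateDensity(seg, simulationParams(), 0.9)
  fit <- rigidBodyFit(seg, m)
  shift <- sqrt(sum((colMeans(coords(applyTransform(seg, fit$transform))) -
                       colMeans(coords(seg)))^2))
  expect_lt(shift, 0.05)
  expect_true(fit$converged)
})

test_that("rigid-body fit recovers a 2 A / 5 degree perturbation within 0.1 A / 0.5 degrees", {
  pair <- makeToyPair(toySpokeParams())
  seg <- selectSegment(pair$open, pair$segments[["Spc97-GRIP2"]])
  m <- simulateDensity(seg, simulationParams(), 0.9)
  pert <- rigidTransform(rotationMatrix(c(0.3, 1, 0.2), 5),
                         c(1.2, -1.0, 1.0))   # |shift| ~ 1.86 A
  fit <- rigidBodyFit(seg, m, start = pert)
  placed <- coords(applyTransform(seg, fit$transform))
  expect_lt(sqrt(sum((colMeans(placed) - colMeans(coords(seg)))^2)), 0.1)
  expect_lt(rdiff(rotation(fit$transform), diag(3)), 0.5)
})

test_that("the fitted placement scores at least as well as nearby random placements", {
  pair <- makeToyPair(toySpokeParams())
  seg <- selectSegment(pair$open, pair$segments[["Spc97-GRIP1"]])
  m <- simulateDensity(seg, simulationParams(), 0.9)
  fit <- rigidBodyFit(seg, m)
  base <- coords(applyTransform(seg, fit$transform))
  c0 <- colMeans(base)
  scores <- withr::with_seed(21, vapply(1:50, function(i) {
    R <- rotationMatrix(rnorm(3), runif(1, 0.2, 2))
    shift <- rnorm(3)
    shift <- shift / sqrt(sum(shift^2)) * runif(1, 0.2, 1)
    pxyz <- sweep(sweep(base, 2, c0) %*% t(R), 2, c0 + shift, "+")
    mean(mapInterpolate(m, pxyz))
  }, numeric(1)))
  expect_true(all(fit$score >= scores - 1e-9))
})

test_that("zone masking zeroes exactly the enumerated voxels and partitions the map", {
  g <- densityMap(array(seq_len(125), c(5, 5, 5)), 1, c(0, 0, 0))
  atom <- matrix(c(2, 2, 2), 1, 3)
  rm15 <- zoneMask(g, atom, 1.5, "remove")
  expect_equal(sum(mapValues(rm15) == 0), 19)   # enumeration: 1 + 6 + 12
  keep15 <- zoneMask(g, atom, 1.5, "keep")
  expect_equal(mapValues(rm15) + mapValues(keep15), mapValues(g))

  offcenter <- matrix(c(2.3, 2.3, 2.3), 1, 3)
  expect_equal(mapValues(zoneMask(g, offcenter, 0, "remove")),
               mapValues(g))
  ## remove is idempotent
  expect_equal(mapValues(zoneMask(rm15, atom, 1.5, "remove")),
               mapValues(rm15))
})

test_that("nucleotide-site scoring separates GDP-like from GTP-like density", {
  core <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0))
  gamma <- matrix(c(4.5, 0, 0), 1, 3)
  p <- simulationParams(resolution = 3)
  mGDP <- simulateDensity(core, p, 1.0)
  callGDP <- ligandSiteScore(mGDP, list(core = core,
                                        gamma_phosphate = gamma),
                             radius = 1.2)
  expect_lt(callGDP$ratio, 0.5)
  expect_equal(callGDP$label, "GDP-like")

  mGTP <- simulateDensity(rbind(core, gamma), p, 1.0)
  callGTP <- ligandSiteScore(mGTP, list(core = core,
                                        gamma_phosphate = gamma),
                             radius = 1.2)
  expect_equal(callGTP$ratio, 1, tolerance = 0.2)
  expect_equal(callGTP$label, "not-GDP-like")

  zero <- densityMap(array(0, c(8, 8, 8)), 1, c(-2, -2, -2))
  callZero <- ligandSiteScore(zero, list(core = core,
                                         gamma_phosphate = gamma),
                              radius = 1.2)
  expect_equal(callZero$label, "indeterminate")
  expect_true(is.na(callZero$ratio))
})

test_that("MRC round-trip preserves grid, origin and values", {
  pair <- makeToyPair(toySpokeParams())
  m <- makeToyMap(selectSegment(pair$open, pair$segments[["Spc97-GRIP1"]]),
                  noiseSigma = 0.02, seed = 5)
  f <- tempfile(fileext = ".mrc")
  writeMRC(m, f)
  m2 <- readMRC(f)
  expect_equal(dim(mapValues(m2)), dim(mapValues(m)))
  expect_equal(voxelSize(m2), voxelSize(m), tolerance = 1e-6)
  expect_lt(max(abs(mapOrigin(m2) - mapOrigin(m))), 1e-4)
  expect_lt(max(abs(mapValues(m2) - mapValues(m))), 1e-5)
})
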