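test_that("kabsch recovers identity and pure translations exactly", {
  set.seed(11)
  m <- matrix(rnorm(60), 20, 3)
  fId <- kabsch(m, m)
  expect_lt(rmsd(fId), 1e-12)
  expect_lt(max(abs(rotation(transform(fId)) - diag(3))), 1e-12)

  fT <- kabsch(m, sweep(m, 2, c(1, 2, 3), "+"))
  expect_lt(rmsd(fT), 1e-12)
  expect_equal(translation(transform(fT)), c(1, 2, 3), tolerance = 1e-12)
  expect_lt(max(abs(rotation(transform(fT)) - diag(3))), 1e-12)
})

test_that("kabsch rejects degenerate input", {
  expect_error(kabsch(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "at least 3")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(kabsch(line, line), "collinear")
})

test_that("kabsch matches a brute-force quaternion-grid oracle on noisy rotated points", {
  withr::with_seed(7, {
    m <- matrix(rnorm(300), 100, 3) * 5
    R <- rotationMatrix(c(1, 0.5, -0.2), 30)
    tgt <- m %*% t(R) + matrix(rnorm(300, sd = 0.1), 100, 3)
  })
  f <- kabsch(m, tgt)
  expect_lt(rdiff(rotation(transform(f)), R), 1.0)     # within 1 degree
  oracle <- quaternionGridRmsd(m, tgt)
  expect_gte(oracle + 1e-12, rmsd(f))                  # oracle can't beat LSQ
  expect_lt(abs(rmsd(f) - oracle) / oracle, 0.20)      # within 20%
})

test_that("kabsch rmsd is invariant under common rigid motions and never exceeds the raw deviation", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      m <- matrix(rnorm(90), 30, 3) * 4
      tgt <- m %*% t(randomRotation(seed + 100)) +
        matrix(rnorm(90, sd = 0.5), 30, 3)
    })
    base <- rmsd(kabsch(m, tgt))
    Rc <- randomRotation(seed + 200); tc <- c(seed, -seed, 2 * seed)
    mc <- sweep(m %*% t(Rc), 2, tc, "+")
    tc2 <- sweep(tgt %*% t(Rc), 2, tc, "+")
    expect_lt(abs(rmsd(kabsch(mc, tc2)) - base), 1e-6)
    raw <- sqrt(mean(rowSums((m - tgt)^2)))
    expect_lte(base, raw + 1e-12)
  }
})

test_that("matched superposition inverts a rigid motion of a structure onto itself", {
  pair <- makeToyPair(toySpokeParams())
  seg <- selectSegment(pair$open, pair$segments[["Spc98-GRIP1"]])
  R <- rotationMatrix(c(0, 1, 1), 25); tv <- c(3, -2, 5)
  moved <- applyTransform(seg, rigidTransform(R, tv))
  fit <- matchedSuperpose(moved, seg)
  expect_lt(rmsd(fit), 1e-9)
  expect_lt(rdiff(rotation(transform(fit)), t(R)), 1e-4)
})

test_that("10% mutated homolog with identical fold superposes at rmsd 0", {
  pair <- makeToyPair(toySpokeParams())
  seg <- selectSegment(pair$open, pair$segments[["Spc97-gamma"]])
  mut <- mutateResidues(seg, 0.10, seed = 7)
  fit <- matchedSuperpose(seg, mut)
  expect_lt(rmsd(fit), 1e-9)
  expect_equal(unname(fit@coverage["query"]), 1.0)
})

test_that("single-pass pruning drops exactly the displaced residues and lowers the rmsd", {
  pair <- makeToyPair(toySpokeParams())
  seg <- selectSegment(pair$open, pair$segments[["Spc97-GRIP1"]])
  a <- atoms(seg)
  nDisp <- ceiling(0.05 * nrow(a))
  moved <- withr::with_seed(3, sample(nrow(a), nDisp))
  a$x[moved] <- a$x[moved] + 10
  broken <- atomicStructure("broken", a)
  plain <- matchedSuperpose(seg, broken)
  pruned <- matchedSuperpose(seg, broken, prune = TRUE)
  expect_lt(rmsd(pruned), rmsd(plain))
  expect_equal(nAtoms(pruned), nAtoms(seg) - nDisp)
})

test_that("morph comparison of a model against itself is all zeros", {
  pair <- makeToyPair(toySpokeParams())
  rep0 <- morphCompare(pair$open, pair$open, pair$segments,
                       anchor = c("Spc97-GRIP1", "Spc97-GRIP2",
                                  "Spc97-gamma"))
  expect_true(all(rmsd(rep0) < 1e-9))
})

test_that("morph comparison recovers the analytic displacement of a known tilt", {
  anchors <- c("Spc97-GRIP1", "Spc97-GRIP2", "Spc97-gamma")
  for (tilt in c(5, 15, 30)) {
    pair <- makeToyPair(toySpokeParams(tiltAngle = tilt))
    rep <- morphCompare(pair$open, pair$closed, pair$segments,
                        anchor = anchors)
    expect_lt(max(rmsd(rep)[anchors]), 1e-6)
    moved <- c("Spc98-GRIP2", "Spc98-gamma")
    expect_lt(max(abs(rmsd(rep)[moved] -
                        pair$groundTruth$expectedRmsd[moved])), 1e-6)
    ## the per-segment placement recovers the tilt angle itself
    expect_equal(rotationAngle(rotation(
      rep@segmentTransforms[["Spc98-gamma"]])), tilt, tolerance = 1e-6)
  }
})

test_that("swapping query and reference recovers the inverse tilt angle", {
  pair <- makeToyPair(toySpokeParams(tiltAngle = 15))
  anchors <- c("Spc97-GRIP1", "Spc97-GRIP2", "Spc97-gamma")
  fwd <- morphCompare(pair$open, pair$closed, pair$segments, anchors)
  rev <- morphCompare(pair$closed, pair$open, pair$segments, anchors)
  aF <- rotationAngle(rotation(fwd@segmentTransforms[["Spc98-gamma"]]))
  aR <- rotationAngle(rotation(rev@segmentTransforms[["Spc98-gamma"]]))
  expect_lt(abs(aF - aR), 1e-3)
  Rprod <- rotation(fwd@segmentTransforms[["Spc98-gamma"]]) %*%
    rotation(rev@segmentTransforms[["Spc98-gamma"]])
  expect_lt(rotationAngle(Rprod), 1e-3)    # transforms are mutual inverses
})

test_that("morph report serializes one row per segment with anchors flagged", {
  pair <- makeToyPair(toySpokeParams())
  rep <- morphCompare(pair$open, pair$closed, pair$segments,
                      anchor = c("Spc97-GRIP1", "Spc97-GRIP2",
                                 "Spc97-gamma"))
  f <- tempfile(fileext = ".tsv")
  writeMorphReport(rep, f)
  df <- read.delim(f)
  expect_equal(nrow(df), 6)
  expect_equal(sum(df$anchor), 3)
  expect_equal(df$segment, names(rmsd(rep)))
})
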