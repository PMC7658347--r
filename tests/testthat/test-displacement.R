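test_that("identical models give a zero displacement field", {
  pair <- makeToyPair(toySpokeParams())
  fld <- displacementField(pair$open, pair$open, pair$segments)
  expect_true(all(entries(fld)$mag == 0))
})

test_that("a pure translation gives a uniform field equal to the shift", {
  pair <- makeToyPair(toySpokeParams())
  t <- c(2, -1, 4)
  moved <- applyTransform(pair$open, rigidTransform(diag(3), t))
  fld <- displacementField(pair$open, moved, pair$segments)
  e <- entries(fld)
  expect_equal(unique(round(e$dx, 9)), t[1])
  expect_equal(unique(round(e$dy, 9)), t[2])
  expect_equal(unique(round(e$dz, 9)), t[3])
  arrow <- meanArrow(fld, "Spc98-GRIP1")
  expect_equal(arrow$vector, t, tolerance = 1e-9)
  expect_false(arrow$rotational)
})

test_that("rotation displacements follow the 2 r sin(theta/2) closed form", {
  pair <- makeToyPair(toySpokeParams())
  theta <- 20
  axisPoint <- c(0, 0, 50); axisDir <- c(0, 1, 0)
  R <- rotationMatrix(axisDir, theta)
  tr <- rigidTransform(R, axisPoint - as.vector(R %*% axisPoint))
  moved <- applyTransform(pair$open, tr)
  fld <- displacementField(pair$open, moved, pair$segments)
  e <- entries(fld)
  p0 <- cbind(e$x0, e$y0, e$z0)
  rel <- sweep(p0, 2, axisPoint)
  axialPart <- rel %*% axisDir %*% t(axisDir)
  rAxis <- sqrt(rowSums((rel - axialPart)^2))
  expect_equal(e$mag, 2 * rAxis * sin(theta / 2 * pi / 180),
               tolerance = 1e-6)
})

test_that("the mean arrow is exactly the component-wise mean and flags rotational fields", {
  e <- data.frame(segment = "s", chain = "A", resno = 1:4, insert = "",
                  x0 = c(0, 1, 2, 3), y0 = 0, z0 = 0,
                  dx = c(1, -1, 1, -1), dy = c(2, -2, 2, -2), dz = 0,
                  mag = sqrt(5))
  fld <- new("DisplacementField", entries = e)
  arrow <- meanArrow(fld, "s")
  expect_equal(arrow$vector, c(mean(e$dx), mean(e$dy), mean(e$dz)))
  expect_equal(arrow$anchor, c(1.5, 0, 0))
  expect_true(arrow$rotational)            # vectors cancel pairwise
  expect_error(meanArrow(fld, "nope"), "unknown segment")
})

test_that("displacement magnitudes are invariant under a common rigid motion", {
  pair <- makeToyPair(toySpokeParams(tiltAngle = 12))
  fld <- displacementField(pair$open, pair$closed, pair$segments)
  common <- rigidTransform(rotationMatrix(c(1, 2, 3), 65), c(10, -4, 7))
  fld2 <- displacementField(applyTransform(pair$open, common),
                            applyTransform(pair$closed, common),
                            pair$segments)
  expect_equal(entries(fld2)$mag, entries(fld)$mag, tolerance = 1e-9)
})

test_that("pure segment translation links morph rmsd and field magnitude", {
  pair <- makeToyPair(toySpokeParams(tiltAngle = 0))
  ## translate the Spc98-gamma block only
  a <- atoms(pair$closed)
  sel <- a$chain == "D"
  a$x[sel] <- a$x[sel] + 3
  moved <- atomicStructure("moved", a)
  anchors <- c("Spc97-GRIP1", "Spc97-GRIP2", "Spc97-gamma")
  rep <- morphCompare(pair$open, moved, pair$segments, anchors)
  fld <- reportDisplacementField(rep)
  e <- entries(fld)
  mags <- e$mag[e$segment == "Spc98-gamma"]
  expect_lt(max(mags) - min(mags), 1e-9)   # uniform field
  expect_equal(rmsd(rep)[["Spc98-gamma"]], mags[1], tolerance = 1e-6)
})

test_that("centroid distance change detects a constructed 5 A approach", {
  pair <- makeToyPair(toySpokeParams(tiltAngle = 0))
  g1 <- pair$segments[["Spc97-gamma"]]
  g2 <- pair$segments[["Spc98-gamma"]]
  same <- centroidDistanceChange(pair$open, pair$open, g1, g2)
  expect_equal(same@delta, 0)
  expect_equal(same@direction, "unchanged")

  ## move gamma-2 exactly 5 A toward gamma-1
  cen <- function(s, sp) colMeans(coords(selectSegment(s, sp)))
  dir <- cen(pair$open, g1) - cen(pair$open, g2)
  dir <- dir / sqrt(sum(dir^2))
  a <- atoms(pair$open)
  sel <- a$chain == "D"
  a$x[sel] <- a$x[sel] + 5 * dir[1]
  a$y[sel] <- a$y[sel] + 5 * dir[2]
  a$z[sel] <- a$z[sel] + 5 * dir[3]
  closedIn <- atomicStructure("approached", a)
  rep <- centroidDistanceChange(pair$open, closedIn, g1, g2)
  expect_equal(rep@delta, 5.0, tolerance = 1e-9)
  expect_equal(rep@direction, "closer")
})

test_that("the toy tilt moves the gamma-tubulins closer by the analytic amount", {
  pair <- makeToyPair(toySpokeParams(tiltAngle = 15))
  anchors <- c("Spc97-GRIP1", "Spc97-GRIP2", "Spc97-gamma")
  rep <- morphCompare(pair$open, pair$closed, pair$segments, anchors)
  cr <- centroidDistanceChange(pair$open, rep@composite,
                               pair$segments[["Spc97-gamma"]],
                               pair$segments[["Spc98-gamma"]])
  gt <- pair$groundTruth
  expect_equal(cr@delta, gt$dOpen - gt$dClosed, tolerance = 1e-6)
  expect_equal(cr@direction, "closer")
})

test_that("field and arrow writers emit well-formed TSV", {
  pair <- makeToyPair(toySpokeParams(tiltAngle = 15))
  fld <- displacementField(pair$open, pair$closed, pair$segments)
  f1 <- tempfile(fileext = ".tsv"); writeDisplacementField(fld, f1)
  df <- read.delim(f1)
  expect_equal(nrow(df), 360)
  expect_true(all(c("segment", "dx", "mag") %in% names(df)))
  f2 <- tempfile(fileext = ".tsv"); writeArrows(fld, f2)
  ar <- read.delim(f2)
  expect_equal(nrow(ar), 6)
  sm <- displacementSummary(fld)
  expect_equal(sort(sm$segment), sort(names(pair$segments)))
})
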