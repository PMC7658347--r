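test_that("a hand-written three-atom PDB parses to one chain, one residue, three atoms", {
  f <- threeAtomPDB(tempfile(fileext = ".pdb"))
  s <- readStructure(f)
  a <- atoms(s)
  expect_equal(nrow(a), 3)
  expect_equal(unique(a$chain), "A")
  expect_equal(unique(a$resno), 1L)
  expect_equal(trimws(a$elety), c("N", "CA", "C"))
  expect_equal(a$x[2], 11.639)
})

test_that("altloc resolution keeps the highest-occupancy conformer, ties alphabetical", {
  f <- altlocPDB(tempfile(fileext = ".pdb"))
  s <- readStructure(f)
  a <- atoms(s)
  expect_equal(nrow(a), 2)                 # CA resolved + CB
  expect_equal(a$x[trimws(a$elety) == "CA"], 1.0)   # conformer A kept

  fTie <- altlocPDB(tempfile(fileext = ".pdb"), occA = 0.5, occB = 0.5)
  sTie <- readStructure(fTie)
  expect_equal(atoms(sTie)$x[trimws(atoms(sTie)$elety) == "CA"], 1.0)

  ## occupancy beats altloc order: B wins when it is the major conformer
  fB <- altlocPDB(tempfile(fileext = ".pdb"), occA = 0.4, occB = 0.6)
  sB <- readStructure(fB)
  expect_equal(atoms(sB)$x[trimws(atoms(sB)$elety) == "CA"], 2.0)
})

test_that("PDB write/read round-trip preserves atoms within text precision", {
  pair <- makeToyPair(toySpokeParams(tiltAngle = 10))
  f <- tempfile(fileext = ".pdb")
  writeStructure(pair$open, f)
  s <- readStructure(f)
  expect_equal(nAtoms(s), nAtoms(pair$open))
  expect_lt(max(abs(coords(s) - coords(pair$open))), 1e-3)
  expect_equal(atoms(s)$resno, atoms(pair$open)$resno)
  expect_equal(atoms(s)$chain, atoms(pair$open)$chain)
})

test_that("unreadable and empty inputs raise parse errors", {
  expect_error(readStructure(tempfile()), "not found")
  f <- tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), f)
  expect_error(readStructure(f))
})

test_that("segment selection honours ranges, counts and gaps", {
  s <- polyChain(rep("ALA", 50))
  spec <- segmentSpec("mid", "A", 10, 20)
  seg <- selectSegment(s, spec)
  expect_equal(nAtoms(seg), 11)            # inclusive range, CA per residue

  whole <- selectSegment(s, segmentSpec("all", "A", 1, 50))
  expect_equal(nAtoms(whole), 50)

  ## numbering gap: residues 15-18 absent from the file
  a <- atoms(s)
  gap <- atomicStructure("gap", a[!a$resno %in% 15:18, ])
  expect_equal(nAtoms(selectSegment(gap, spec)), 7)

  expect_error(selectSegment(s, segmentSpec("off", "B", 1, 10)),
               "no residues")
  expect_error(selectSegment(s, segmentSpec("off2", "A", 60, 70)),
               "60-70")
})

test_that("segment selection is idempotent and excludes waters/hetero", {
  pair <- makeToyPair(toySpokeParams())
  spec <- pair$segments[["Spc98-GRIP2"]]
  once <- selectSegment(pair$open, spec)
  twice <- selectSegment(once, spec)
  expect_equal(atoms(twice), atoms(once))

  a <- atoms(polyChain(rep("ALA", 5)))
  a <- rbind(a, data.frame(chain = "A", resno = 3, insert = "",
                           resid = "HOH", elety = "O", elesy = "O",
                           x = 0, y = 5, z = 0, o = 1, het = TRUE))
  s <- atomicStructure("wat", a)
  expect_equal(nAtoms(selectSegment(s, segmentSpec("x", "A", 1, 5),
                                    "ALL_HEAVY")), 5)
})

test_that("aligning a chain to itself gives the identity mapping at full coverage", {
  pair <- makeToyPair(toySpokeParams())
  seg <- selectSegment(pair$open, pair$segments[["Spc97-gamma"]])
  co <- alignResidues(seg, seg)
  p <- residuePairs(co)
  expect_equal(nrow(p), 60)
  expect_equal(p$resnoA, p$resnoB)
  expect_equal(co@coverageA, 1.0)
  expect_equal(co@coverageB, 1.0)
})

test_that("a single internal deletion aligns flanking residues in order", {
  seqs <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I")
  full <- polyChain(bio3d::aa123(seqs))
  del <- atoms(full)[atoms(full)$resno != 5, ]
  co <- alignResidues(full, atomicStructure("del", del))
  p <- residuePairs(co)
  expect_equal(nrow(p), 9)                 # n - 1 pairs
  expect_false(5 %in% p$resnoA)            # the deleted residue is unpaired
  expect_equal(p$resnoA[order(p$resnoA)], sort(p$resnoA))
  expect_true(all(diff(p$resnoB[order(p$resnoA)]) > 0))  # no crossings
})

test_that("alignment of unrelated sequences stays one-to-one and order-preserving", {
  a <- polyChain(bio3d::aa123(c("W", "F", "Y", "M", "L")))
  b <- polyChain(bio3d::aa123(c("G", "P", "S", "T", "N")), chain = "B")
  co <- alignResidues(a, b)
  p <- residuePairs(co)
  expect_false(anyDuplicated(p$resnoA) > 0)
  expect_false(anyDuplicated(p$resnoB) > 0)
  expect_true(all(diff(p$resnoB[order(p$resnoA)]) > 0))
})

test_that("non-standard residue names map to X with a warning", {
  a <- polyChain(c("ALA", "GLY", "XYZ", "LEU", "VAL"))
  w <- capture_warnings(co <- alignResidues(a, a))
  expect_true(any(grepl("non-standard", w)))
  expect_equal(nrow(residuePairs(co)), 5)  # X aligns to itself
})

test_that("segment config files round-trip through the YAML schema", {
  f <- system.file("extdata", "segments_toy.yaml", package = "TuSCmorph")
  segs <- readSegmentConfig(f)
  expect_length(segs, 6)
  expect_s4_class(segs[["Spc98-gamma"]], "SegmentSpec")
  expect_equal(segs[["Spc97-GRIP2"]]@selections$first, 61L)
})
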