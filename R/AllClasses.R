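#' @import methods
NULL

.ATOM_COLS <- c("chain", "resno", "insert", "resid", "elety", "elesy",
                "x", "y", "z", "o", "het")

#' AtomicStructure: a hierarchical atomic model
#'
#' Holds an atomic model (chains, residues, atoms) with coordinates in
#' Angstrom, as parsed from PDB/mmCIF or built synthetically. Atoms are
#' stored as a flat data.frame in file order; a residue is uniquely
#' identified by (chain, resno, insert).
#'
#' @slot id Character label for the model.
#' @slot atoms data.frame with columns chain, resno, insert, resid, elety
#'   (atom name), elesy (element), x, y, z (Angstrom), o (occupancy),
#'   het (logical HETATM flag).
#' @export
setClass("AtomicStructure",
  representation(id = "character", atoms = "data.frame"))

setValidity("AtomicStructure", function(object) {
  a <- object@atoms
  missing <- setdiff(.ATOM_COLS, names(a))
  if (length(missing))
    return(paste("atoms is missing columns:", paste(missing, collapse = ", ")))
  if (nrow(a) && !all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("all atom coordinates must be finite")
  dup <- duplicated(paste(.resKey(a$chain, a$resno, a$insert), a$elety))
  if (any(dup))
    return("duplicate (residue, atom name) after altloc resolution")
  TRUE
})

#' SegmentSpec: a named residue-range selection
#'
#' Defines one comparison segment (e.g. a GRIP domain or one gamma-tubulin
#' copy) as inclusive author-numbered residue ranges on one or more chains.
#'
#' @slot name Segment name, e.g. "Spc97-GRIP2".
#' @slot selections data.frame with columns chain, first, last (inclusive
#'   residue numbers as deposited).
#' @slot atomSubset One of "CA_ONLY", "BACKBONE", "ALL_HEAVY".
#' @export
setClass("SegmentSpec",
  representation(name = "character", selections = "data.frame",
                 atomSubset = "character"),
  prototype(atomSubset = "CA_ONLY"))

setValidity("SegmentSpec", function(object) {
  s <- object@selections
  if (!all(c("chain", "first", "last") %in% names(s)))
    return("selections needs columns chain, first, last")
  if (!nrow(s)) return("selections must contain at least one range")
  if (any(s$last < s$first)) return("ranges must satisfy first <= last")
  if (!object@atomSubset %in% c("CA_ONLY", "BACKBONE", "ALL_HEAVY"))
    return("atomSubset must be CA_ONLY, BACKBONE or ALL_HEAVY")
  ## non-overlap within a chain
  for (ch in unique(s$chain)) {
    r <- s[s$chain == ch, , drop = FALSE]
    r <- r[order(r$first), , drop = FALSE]
    if (nrow(r) > 1 && any(r$first[-1] <= r$last[-nrow(r)]))
      return(paste("overlapping ranges on chain", ch))
  }
  TRUE
})

#' RigidTransform: proper rotation plus translation
#'
#' Applied to a coordinate row vector x as x' = R x + t.
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation Numeric length-3 translation, Angstrom.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0)))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation must be orthonormal (tolerance 1e-8)")
  if (abs(det(R) - 1) > 1e-8) return("rotation must have determinant +1")
  if (length(object@translation) != 3 || !all(is.finite(object@translation)))
    return("translation must be a finite length-3 vector")
  TRUE
})

#' SuperpositionResult: outcome of a least-squares rigid fit
#'
#' @slot transform The [RigidTransform-class] mapping mobile onto target.
#' @slot rmsd Post-fit root-mean-square deviation, Angstrom.
#' @slot nAtoms Number of paired atoms used.
#' @slot atomSubset Atom subset used ("CA_ONLY", "BACKBONE", "ALL_HEAVY").
#' @slot coverage Fraction of residues of each input covered by the pairing
#'   (named numeric, possibly empty for bare coordinate fits).
#' @export
setClass("SuperpositionResult",
  representation(transform = "RigidTransform", rmsd = "numeric",
                 nAtoms = "integer", atomSubset = "character",
                 coverage = "numeric"),
  prototype(coverage = numeric(0)))

setValidity("SuperpositionResult", function(object) {
  if (object@rmsd < 0) return("rmsd must be >= 0")
  if (object@nAtoms < 3L) return("nAtoms must be >= 3")
  TRUE
})

#' Correspondence: a one-to-one, order-preserving residue pairing
#'
#' @slot pairs data.frame with columns chainA, resnoA, insertA, chainB,
#'   resnoB, insertB, one row per aligned (non-gap) position.
#' @slot alignmentScore Alignment score (BLOSUM62, affine gaps).
#' @slot coverageA,coverageB Fraction of each input's residues that are
#'   paired, in [0, 1].
#' @export
setClass("Correspondence",
  representation(pairs = "data.frame", alignmentScore = "numeric",
                 coverageA = "numeric", coverageB = "numeric"))

setValidity("Correspondence", function(object) {
  p <- object@pairs
  need <- c("chainA", "resnoA", "insertA", "chainB", "resnoB", "insertB")
  if (!all(need %in% names(p))) return("pairs is missing columns")
  keyA <- .resKey(p$chainA, p$resnoA, p$insertA)
  keyB <- .resKey(p$chainB, p$resnoB, p$insertB)
  if (anyDuplicated(keyA) || anyDuplicated(keyB))
    return("pairing must be one-to-one in both directions")
  if (object@coverageA < 0 || object@coverageA > 1 ||
      object@coverageB < 0 || object@coverageB > 1)
    return("coverage must lie in [0, 1]")
  TRUE
})

#' DensityMap: scalar values on a regular 3D grid
#'
#' World coordinates relate to zero-based grid indices by
#' world = origin + index * voxelSize (isotropic voxels, axes X, Y, Z).
#'
#' @slot values 3D numeric array (nx, ny, nz).
#' @slot voxelSize Isotropic voxel edge, Angstrom.
#' @slot origin World position of grid index (0, 0, 0), Angstrom.
#' @export
setClass("DensityMap",
  representation(values = "array", voxelSize = "numeric",
                 origin = "numeric"))

setValidity("DensityMap", function(object) {
  if (length(dim(object@values)) != 3) return("values must be a 3D array")
  if (length(object@voxelSize) != 1 || object@voxelSize <= 0)
    return("voxelSize must be a single positive number")
  if (length(object@origin) != 3 || !all(is.finite(object@origin)))
    return("origin must be a finite length-3 vector")
  if (!all(is.finite(object@values))) return("all map values must be finite")
  TRUE
})

#' CorrelationResult: normalized map cross-correlation
#'
#' @slot cc Correlation coefficient in [-1, 1].
#' @slot nVoxels Number of voxels entering the sum.
#' @slot aboutMean Whether means were subtracted before normalisation.
#' @export
setClass("CorrelationResult",
  representation(cc = "numeric", nVoxels = "integer", aboutMean = "logical"))

setValidity("CorrelationResult", function(object) {
  if (abs(object@cc) > 1 + 1e-9) return("|cc| must be <= 1")
  if (object@nVoxels < 1L) return("nVoxels must be >= 1")
  TRUE
})

#' MorphCompareReport: per-segment displacement of a morph comparison
#'
#' The machine-readable result of [morphCompare()]: per-segment RMSD of the
#' query model against its copy placed into the reference conformation and
#' re-anchored on the anchor segments, plus per-residue displacement
#' vectors and the composite model itself.
#'
#' @slot perSegment Named numeric, RMSD (Angstrom) per configured segment.
#' @slot nAtomsPerSegment Named integer, atoms used per segment.
#' @slot coverage Named numeric, aligned-residue coverage of the query
#'   segment in the segment-wise fit.
#' @slot anchorSegments Names of the segments used for re-anchoring.
#' @slot queryId,referenceId Model labels.
#' @slot segmentTransforms Named list of [RigidTransform-class], the
#'   per-segment placements (query segment onto reference segment).
#' @slot displacements data.frame of per-residue displacement vectors
#'   (segment, chain, resno, insert, x0, y0, z0, dx, dy, dz).
#' @slot composite The assembled, re-anchored composite
#'   [AtomicStructure-class].
#' @export
setClass("MorphCompareReport",
  representation(perSegment = "numeric", nAtomsPerSegment = "integer",
                 coverage = "numeric", anchorSegments = "character",
                 queryId = "character", referenceId = "character",
                 segmentTransforms = "list", displacements = "data.frame",
                 composite = "AtomicStructure"))

setValidity("MorphCompareReport", function(object) {
  if (!length(object@anchorSegments)) return("anchor segments must be non-empty")
  if (is.null(names(object@perSegment)) || anyDuplicated(names(object@perSegment)))
    return("perSegment must carry one uniquely named rmsd per segment")
  if (any(object@perSegment < 0)) return("rmsd values must be >= 0")
  TRUE
})

#' ConformationCall: straight/curved tubulin classification
#'
#' The label is "straight" iff the straight reference wins on both the RMSD
#' and the cross-correlation criterion, "curved" iff both are reversed, and
#' "indeterminate" otherwise (including ties).
#'
#' @slot label "straight", "curved" or "indeterminate".
#' @slot rmsdStraight,rmsdCurved Helix Calpha RMSD (Angstrom) against the
#'   docked straight/curved reference, positions as docked.
#' @slot ccStraight,ccCurved Masked cross-correlation of the simulated
#'   helix density of each docked reference against the experimental map.
#' @export
setClass("ConformationCall",
  representation(label = "character",
                 rmsdStraight = "numeric", rmsdCurved = "numeric",
                 ccStraight = "numeric", ccCurved = "numeric"))

setValidity("ConformationCall", function(object) {
  expect <- conformationLabel(object@rmsdStraight, object@rmsdCurved,
                              object@ccStraight, object@ccCurved)
  if (!identical(object@label, expect))
    return(sprintf("label '%s' inconsistent with scores (rule gives '%s')",
                   object@label, expect))
  TRUE
})

#' DisplacementField: per-residue displacement vectors
#'
#' @slot entries data.frame with columns segment, chain, resno, insert,
#'   x0, y0, z0 (start position), dx, dy, dz (vector), mag (length).
#' @export
setClass("DisplacementField", representation(entries = "data.frame"))

setValidity("DisplacementField", function(object) {
  e <- object@entries
  need <- c("segment", "chain", "resno", "insert",
            "x0", "y0", "z0", "dx", "dy", "dz", "mag")
  if (!all(need %in% names(e))) return("entries is missing columns")
  if (nrow(e)) {
    if (!all(is.finite(as.matrix(e[, c("dx", "dy", "dz")]))))
      return("all displacement vectors must be finite")
    if (anyDuplicated(.resKey(e$chain, e$resno, e$insert)))
      return("entries must be keyed uniquely by residue")
  }
  TRUE
})

#' CentroidReport: inter-gamma-tubulin centroid distance change
#'
#' @slot dQuery Centroid distance in the query conformation, Angstrom.
#' @slot dReference Centroid distance in the reference conformation.
#' @slot delta dQuery - dReference, Angstrom.
#' @slot direction "closer" (query wider, activation moves the subunits
#'   closer), "apart", or "unchanged" (|delta| < 0.05 Angstrom).
#' @export
setClass("CentroidReport",
  representation(dQuery = "numeric", dReference = "numeric",
                 delta = "numeric", direction = "character"))

setValidity("CentroidReport", function(object) {
  d <- object@delta
  dir <- if (abs(d) < 0.05) "unchanged" else if (d > 0) "closer" else "apart"
  if (!identical(object@direction, dir))
    return("direction inconsistent with delta")
  if (abs(object@dQuery - object@dReference - d) > 1e-9)
    return("delta must equal dQuery - dReference")
  TRUE
})

#' InterfaceReport: contacts and physicochemical character of an interface
#'
#' @slot contacts data.frame of residue pairs in contact (chainA, resnoA,
#'   insertA, residA, chainB, resnoB, insertB, residB, minDist).
#' @slot cutoff Heavy-atom contact cutoff used, Angstrom.
#' @slot hydrophobicFractionA,hydrophobicFractionB Fraction of interface
#'   residues on each side with Kyte-Doolittle hydropathy > 0.
#' @slot saltBridges data.frame of Asp/Glu side-chain O to Lys/Arg/His
#'   side-chain N pairs within the salt-bridge cutoff.
#' @export
setClass("InterfaceReport",
  representation(contacts = "data.frame", cutoff = "numeric",
                 hydrophobicFractionA = "numeric",
                 hydrophobicFractionB = "numeric",
                 saltBridges = "data.frame"))

setValidity("InterfaceReport", function(object) {
  if (nrow(object@contacts) &&
      any(object@contacts$minDist > object@cutoff + 1e-9))
    return("contact distances must not exceed the cutoff")
  for (f in c(object@hydrophobicFractionA, object@hydrophobicFractionB))
    if (length(f) && (f < 0 || f > 1))
      return("hydrophobic fractions must lie in [0, 1]")
  TRUE
})

#' ToySpokeParams: parameters of the synthetic two-spoke generator
#'
#' @slot nHelicesPerDomain Alpha-helices per rigid block.
#' @slot helixLength Residues per helix.
#' @slot tiltAngle Tilt (degrees, in [0, 60]) applied to the spoke-2
#'   GRIP2 + gamma-tubulin block between the open and closed states.
#' @slot noiseSigma Per-coordinate Gaussian noise added to the closed
#'   state, Angstrom.
#' @slot seed Integer RNG seed; identical seeds give identical output.
#' @export
setClass("ToySpokeParams",
  representation(nHelicesPerDomain = "integer", helixLength = "integer",
                 tiltAngle = "numeric", noiseSigma = "numeric",
                 seed = "integer"))

setValidity("ToySpokeParams", function(object) {
  if (object@tiltAngle < 0 || object@tiltAngle > 60)
    return("tiltAngle must lie in [0, 60] degrees")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (object@nHelicesPerDomain < 1 || object@helixLength < 4)
    return("need >= 1 helix per domain and >= 4 residues per helix")
  TRUE
})
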