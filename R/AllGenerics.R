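#' @include AllClasses.R
NULL

#' Accessors for TuSCmorph classes
#'
#' Small accessor generics; slots are never reached into directly by user
#' code.
#'
#' @param x An object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setMethod("atoms", "AtomicStructure", function(x) x@atoms)

#' @rdname accessors
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))
#' @rdname accessors
#' @export
setMethod("structureId", "AtomicStructure", function(x) x@id)

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setMethod("nAtoms", "AtomicStructure", function(x) nrow(x@atoms))
#' @rdname accessors
#' @export
setMethod("nAtoms", "SuperpositionResult", function(x) x@nAtoms)

#' Coordinate matrix of a structure
#'
#' @param x An [AtomicStructure-class].
#' @return n x 3 numeric matrix of atom positions (Angstrom).
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname coords
#' @export
setMethod("coords", "AtomicStructure",
  function(x) as.matrix(x@atoms[, c("x", "y", "z")]))

#' @rdname accessors
#' @export
setGeneric("segmentName", function(x) standardGeneric("segmentName"))
#' @rdname accessors
#' @export
setMethod("segmentName", "SegmentSpec", function(x) x@name)

#' @rdname accessors
#' @export
setGeneric("rotation", function(x) standardGeneric("rotation"))
#' @rdname accessors
#' @export
setMethod("rotation", "RigidTransform", function(x) x@rotation)

#' @rdname accessors
#' @export
setGeneric("translation", function(x) standardGeneric("translation"))
#' @rdname accessors
#' @export
setMethod("translation", "RigidTransform", function(x) x@translation)

#' @rdname accessors
#' @export
setGeneric("rmsd", function(x, ...) standardGeneric("rmsd"))
#' @rdname accessors
#' @export
setMethod("rmsd", "SuperpositionResult", function(x, ...) x@rmsd)
#' @rdname accessors
#' @export
setMethod("rmsd", "MorphCompareReport", function(x, ...) x@perSegment)

#' @rdname accessors
#' @export
setGeneric("transform", function(x) standardGeneric("transform"))
#' @rdname accessors
#' @export
setMethod("transform", "SuperpositionResult", function(x) x@transform)

#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setMethod("mapValues", "DensityMap", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setMethod("voxelSize", "DensityMap", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setGeneric("mapOrigin", function(x) standardGeneric("mapOrigin"))
#' @rdname accessors
#' @export
setMethod("mapOrigin", "DensityMap", function(x) x@origin)

#' @rdname accessors
#' @export
setGeneric("correlation", function(x) standardGeneric("correlation"))
#' @rdname accessors
#' @export
setMethod("correlation", "CorrelationResult", function(x) x@cc)

#' @rdname accessors
#' @export
setGeneric("residuePairs", function(x) standardGeneric("residuePairs"))
#' @rdname accessors
#' @export
setMethod("residuePairs", "Correspondence", function(x) x@pairs)

#' @rdname accessors
#' @export
setGeneric("entries", function(x) standardGeneric("entries"))
#' @rdname accessors
#' @export
setMethod("entries", "DisplacementField", function(x) x@entries)

#' @rdname accessors
#' @export
setGeneric("contacts", function(x) standardGeneric("contacts"))
#' @rdname accessors
#' @export
setMethod("contacts", "InterfaceReport", function(x) x@contacts)

#' @rdname accessors
#' @export
setGeneric("saltBridges", function(x) standardGeneric("saltBridges"))
#' @rdname accessors
#' @export
setMethod("saltBridges", "InterfaceReport", function(x) x@saltBridges)

#' @rdname accessors
#' @export
setGeneric("conformation", function(x) standardGeneric("conformation"))
#' @rdname accessors
#' @export
setMethod("conformation", "ConformationCall", function(x) x@label)

#' Apply a rigid transform
#'
#' @param x A coordinate matrix (n x 3), [AtomicStructure-class] or
#'   [DensityMap-class] (for a map, only pure translations are supported:
#'   the grid origin is shifted).
#' @param tr A [RigidTransform-class].
#' @return The transformed object of the same class.
#' @export
setGeneric("applyTransform", function(x, tr) standardGeneric("applyTransform"))

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "matrix", function(x, tr) {
  .assertFiniteMatrix(x, "coordinates")
  sweep(x %*% t(tr@rotation), 2, tr@translation, "+")
})

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "AtomicStructure", function(x, tr) {
  xyz <- applyTransform(coords(x), tr)
  x@atoms$x <- xyz[, 1]; x@atoms$y <- xyz[, 2]; x@atoms$z <- xyz[, 3]
  x
})

## ---- show methods -------------------------------------------------------

setMethod("show", "AtomicStructure", function(object) {
  a <- object@atoms
  cat("AtomicStructure '", object@id, "': ",
      length(unique(a$chain)), " chain(s), ",
      length(unique(.resKey(a$chain, a$resno, a$insert))), " residues, ",
      nrow(a), " atoms\n", sep = "")
})

setMethod("show", "SegmentSpec", function(object) {
  rng <- apply(object@selections, 1, function(r)
    sprintf("%s:%s-%s", r[["chain"]], r[["first"]], r[["last"]]))
  cat("SegmentSpec '", object@name, "' [", object@atomSubset, "] ",
      paste(rng, collapse = ", "), "\n", sep = "")
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: rotation %.3f deg, |t| = %.3f A\n",
              rotationAngle(object@rotation),
              sqrt(sum(object@translation^2))))
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: rmsd %.4f A over %d atoms (%s)\n",
              object@rmsd, object@nAtoms, object@atomSubset))
})

setMethod("show", "DensityMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("DensityMap: %d x %d x %d voxels, %.3f A/voxel, origin (%.2f, %.2f, %.2f)\n",
              d[1], d[2], d[3], object@voxelSize,
              object@origin[1], object@origin[2], object@origin[3]))
})

setMethod("show", "MorphCompareReport", function(object) {
  cat("MorphCompareReport: '", object@queryId, "' vs '", object@referenceId,
      "', anchor = {", paste(object@anchorSegments, collapse = ", "),
      "}\n", sep = "")
  print(round(object@perSegment, 3))
})

setMethod("show", "ConformationCall", function(object) {
  cat(sprintf(
    "ConformationCall: %s (rmsd straight/curved %.3f/%.3f A, cc %.4f/%.4f)\n",
    object@label, object@rmsdStraight, object@rmsdCurved,
    object@ccStraight, object@ccCurved))
})

setMethod("show", "CentroidReport", function(object) {
  cat(sprintf("CentroidReport: %.3f -> %.3f A (delta %.3f A, %s)\n",
              object@dQuery, object@dReference, object@delta,
              object@direction))
})

setMethod("show", "InterfaceReport", function(object) {
  cat(sprintf(
    "InterfaceReport: %d contacts (cutoff %.1f A), hydrophobic fraction %.2f/%.2f, %d salt bridge(s)\n",
    nrow(object@contacts), object@cutoff, object@hydrophobicFractionA,
    object@hydrophobicFractionB, nrow(object@saltBridges)))
})
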