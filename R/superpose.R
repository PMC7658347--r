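## Rigid-body least-squares superposition and the six-segment
## morph-compare procedure: each query segment is placed into the
## reference conformation, the placed copies are reassembled into a
## composite model, the composite is re-anchored on the anchor segments
## (one whole spoke) and per-segment displacement is measured.

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation Numeric length-3, Angstrom.
#' @return A [RigidTransform-class].
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' Invert a rigid transform
#'
#' @param tr A [RigidTransform-class].
#' @return The inverse transform.
#' @export
invertTransform <- function(tr) {
  Rt <- t(tr@rotation)
  rigidTransform(Rt, -as.vector(Rt %*% tr@translation))
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#'
#' @param second,first [RigidTransform-class] objects.
#' @return A [RigidTransform-class].
#' @export
composeTransform <- function(second, first) {
  rigidTransform(second@rotation %*% first@rotation,
                 as.vector(second@rotation %*% first@translation) +
                   second@translation)
}

#' Optimal rigid superposition of paired coordinates (Kabsch)
#'
#' Computes the least-squares optimal proper rotation and translation
#' mapping `mobile` onto `target` (SVD with reflection correction), and
#' the post-fit RMSD.
#'
#' @param mobile,target n x 3 coordinate matrices, paired row-wise, n >= 3.
#' @param atomSubset Label recorded in the result (bookkeeping only).
#' @return A [SuperpositionResult-class].
#' @export
#' @examples
#' m <- matrix(rnorm(30), 10, 3)
#' kabsch(m, sweep(m, 2, c(1, 2, 3), "+"))
kabsch <- function(mobile, target, atomSubset = "COORDS") {
  .assertFiniteMatrix(mobile, "mobile")
  .assertFiniteMatrix(target, "target")
  n <- nrow(mobile)
  if (nrow(target) != n) stop("mobile and target must have equal rows")
  if (n < 3) stop("need at least 3 paired atoms, got ", n)
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  svP <- svd(P)$d
  if (svP[2] < 1e-8 * max(svP[1], 1))
    stop("degenerate point cloud: mobile coordinates are collinear (rank < 2)")
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- ct - as.vector(R %*% cm)
  tr <- rigidTransform(R, t)
  dev <- applyTransform(mobile, tr) - target
  new("SuperpositionResult", transform = tr,
      rmsd = sqrt(mean(rowSums(dev^2))), nAtoms = as.integer(n),
      atomSubset = atomSubset)
}

## collect paired atom coordinates of a given subset for a Correspondence
.pairedCoords <- function(a, b, corr, atomSubset) {
  aa <- atoms(a); ab <- atoms(b)
  aa <- aa[.subsetFilter(aa, atomSubset), , drop = FALSE]
  ab <- ab[.subsetFilter(ab, atomSubset), , drop = FALSE]
  p <- corr@pairs
  keyA <- paste(.resKey(aa$chain, aa$resno, aa$insert), trimws(aa$elety))
  keyB <- paste(.resKey(ab$chain, ab$resno, ab$insert), trimws(ab$elety))
  wantA <- paste(.resKey(p$chainA, p$resnoA, p$insertA))
  wantB <- paste(.resKey(p$chainB, p$resnoB, p$insertB))
  ## for each pair, intersect the atom names present on both sides
  mobile <- target <- NULL
  rows <- list()
  iA <- split(seq_len(nrow(aa)), .resKey(aa$chain, aa$resno, aa$insert))
  iB <- split(seq_len(nrow(ab)), .resKey(ab$chain, ab$resno, ab$insert))
  dropped <- 0L
  for (k in seq_len(nrow(p))) {
    ra <- iA[[wantA[k]]]; rb <- iB[[wantB[k]]]
    if (is.null(ra) || is.null(rb)) { dropped <- dropped + 1L; next }
    common <- intersect(trimws(aa$elety[ra]), trimws(ab$elety[rb]))
    if (!length(common)) { dropped <- dropped + 1L; next }
    ra <- ra[match(common, trimws(aa$elety[ra]))]
    rb <- rb[match(common, trimws(ab$elety[rb]))]
    rows[[length(rows) + 1L]] <- cbind(ra, rb, k)
  }
  if (dropped > 0)
    warning(dropped, " aligned residue pair(s) lack ", atomSubset,
            " atoms and were dropped")
  idx <- do.call(rbind, rows)
  if (is.null(idx)) idx <- matrix(integer(0), 0, 3)
  list(mobile = as.matrix(aa[idx[, 1], c("x", "y", "z")]),
       target = as.matrix(ab[idx[, 2], c("x", "y", "z")]),
       pairIndex = idx[, 3])
}

#' Sequence-matched rigid superposition of two segments
#'
#' Aligns the residues of the two selections ([alignResidues()]), collects
#' the paired atoms of the requested subset and superposes them with
#' [kabsch()]. Optional single-pass pruning (off by default) drops pairs
#' with post-fit distance above `pruneCutoff` and refits once.
#'
#' @param query,target [AtomicStructure-class] objects (typically outputs
#'   of [selectSegment()]).
#' @param querySpec,targetSpec Optional [SegmentSpec-class]; when given,
#'   the selections are made here.
#' @param atomSubset "CA_ONLY" (default), "BACKBONE" or "ALL_HEAVY".
#' @param prune Logical, enable the one-pass prune-and-refit.
#' @param pruneCutoff Post-fit distance cutoff for pruning, Angstrom.
#' @return A [SuperpositionResult-class]; coverage reports the aligned
#'   fraction of each input.
#' @export
matchedSuperpose <- function(query, target, querySpec = NULL,
                             targetSpec = NULL, atomSubset = "CA_ONLY",
                             prune = FALSE, pruneCutoff = 2.0) {
  if (!is.null(querySpec)) query <- selectSegment(query, querySpec, atomSubset)
  if (!is.null(targetSpec)) target <- selectSegment(target, targetSpec, atomSubset)
  corr <- alignResidues(query, target)
  pc <- .pairedCoords(query, target, corr, atomSubset)
  if (nrow(pc$mobile) < 3)
    stop("fewer than 3 aligned atom pairs between '", structureId(query),
         "' and '", structureId(target), "'")
  fit <- kabsch(pc$mobile, pc$target, atomSubset)
  if (prune) {
    dev <- applyTransform(pc$mobile, fit@transform) - pc$target
    keep <- sqrt(rowSums(dev^2)) <= pruneCutoff
    if (sum(keep) >= 3 && any(!keep))
      fit <- kabsch(pc$mobile[keep, , drop = FALSE],
                    pc$target[keep, , drop = FALSE], atomSubset)
  }
  fit@coverage <- c(query = corr@coverageA, target = corr@coverageB)
  fit
}

## bind the atom tables of several structures into one model
.assembleStructures <- function(parts, id) {
  atomicStructure(id, do.call(rbind, lapply(parts, atoms)))
}

#' Segment-wise morph comparison of two conformations
#'
#' Implements the segment-placement comparison: (1) each query segment is
#' superposed onto the corresponding reference segment and a copy of the
#' query segment is placed there; (2) the placed copies are assembled into
#' a composite model; (3) the composite is superposed back onto the
#' original query using only the union of the anchor segments (one whole
#' spoke); (4) per-segment RMSD between composite and original query is
#' reported, along with per-residue displacement vectors.
#'
#' @param query,reference [AtomicStructure-class] models.
#' @param segments Named list; each element is a list with components
#'   `query` and `reference`, both [SegmentSpec-class]. A bare
#'   [SegmentSpec-class] is used for both models.
#' @param anchor Character vector of segment names forming the anchor
#'   (non-empty subset of `names(segments)`).
#' @param atomSubset Atom subset for fitting and RMSD ("CA_ONLY" default).
#' @param prune Passed to [matchedSuperpose()] for the segment fits.
#' @return A [MorphCompareReport-class].
#' @export
morphCompare <- function(query, reference, segments, anchor,
                         atomSubset = "CA_ONLY", prune = FALSE) {
  if (!length(anchor)) stop("anchor must name at least one segment")
  if (is.null(names(segments)) || !all(anchor %in% names(segments)))
    stop("anchor names must match named segments")
  segPair <- lapply(segments, function(sp) {
    if (is(sp, "SegmentSpec")) list(query = sp, reference = sp) else sp
  })

  placed <- list(); trs <- list(); cov <- numeric(0)
  for (nm in names(segPair)) {
    qSeg <- selectSegment(query, segPair[[nm]]$query, atomSubset)
    fit <- tryCatch(
      matchedSuperpose(qSeg,
                       selectSegment(reference, segPair[[nm]]$reference,
                                     atomSubset),
                       atomSubset = atomSubset, prune = prune),
      error = function(e) stop("segment '", nm, "' superposition failed: ",
                               conditionMessage(e), call. = FALSE))
    ## place a full-subset copy of the query segment into the reference frame
    placed[[nm]] <- applyTransform(qSeg, fit@transform)
    trs[[nm]] <- fit@transform
    cov[nm] <- unname(fit@coverage["query"])
  }

  composite <- .assembleStructures(placed, paste0(structureId(query),
                                                  ":composite"))
  ## step 3: re-anchor the composite on the original query
  anchorComposite <- do.call(rbind, lapply(anchor, function(nm)
    coords(placed[[nm]])))
  anchorQuery <- do.call(rbind, lapply(anchor, function(nm)
    coords(selectSegment(query, segPair[[nm]]$query, atomSubset))))
  anchorFit <- kabsch(anchorComposite, anchorQuery, atomSubset)
  composite <- applyTransform(composite, anchorFit@transform)

  ## step 4: per-segment rmsd composite vs original query + displacements
  perSeg <- numeric(0); nAt <- integer(0); disp <- list()
  for (nm in names(segPair)) {
    qSeg <- selectSegment(query, segPair[[nm]]$query, atomSubset)
    cSeg <- applyTransform(placed[[nm]], anchorFit@transform)
    dxyz <- coords(cSeg) - coords(qSeg)
    perSeg[nm] <- sqrt(mean(rowSums(dxyz^2)))
    nAt[nm] <- nAtoms(qSeg)
    qa <- atoms(qSeg)
    isCA <- trimws(qa$elety) == "CA"
    rep <- if (any(isCA)) isCA else !duplicated(.resKey(qa$chain, qa$resno,
                                                        qa$insert))
    disp[[nm]] <- data.frame(
      segment = nm, chain = qa$chain[rep], resno = qa$resno[rep],
      insert = qa$insert[rep],
      x0 = qa$x[rep], y0 = qa$y[rep], z0 = qa$z[rep],
      dx = dxyz[rep, 1], dy = dxyz[rep, 2], dz = dxyz[rep, 3],
      stringsAsFactors = FALSE)
  }

  new("MorphCompareReport",
      perSegment = perSeg, nAtomsPerSegment = nAt, coverage = cov,
      anchorSegments = anchor, queryId = structureId(query),
      referenceId = structureId(reference), segmentTransforms = trs,
      displacements = do.call(rbind, disp), composite = composite)
}

#' Write a morph-compare report as TSV
#'
#' One row per segment: segment, n_atoms, coverage, rmsd_A.
#'
#' @param report A [MorphCompareReport-class].
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
writeMorphReport <- function(report, path) {
  df <- data.frame(segment = names(report@perSegment),
                   n_atoms = as.integer(report@nAtomsPerSegment),
                   coverage = round(report@coverage, 4),
                   rmsd_A = round(report@perSegment, 4),
                   anchor = names(report@perSegment) %in%
                     report@anchorSegments)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
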