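## Per-residue displacement fields, mean-displacement arrows and
## inter-gamma-tubulin centroid geometry.

#' Per-residue displacement field between two models
#'
#' One vector per residue shared between the two models (matched by
#' chain/resno/insertion code): composite position minus original
#' position at the Calpha representative atom.
#'
#' @param original,composite [AtomicStructure-class] models sharing
#'   residue identities (e.g. a query and the composite from
#'   [morphCompare()]).
#' @param segments Optional named list of [SegmentSpec-class] used to
#'   label entries by segment; unlabelled residues get segment "".
#' @return A [DisplacementField-class].
#' @export
displacementField <- function(original, composite, segments = NULL) {
  repAtoms <- function(s) {
    a <- atoms(s)
    ca <- a[trimws(a$elety) == "CA", , drop = FALSE]
    if (!nrow(ca)) ca <- a[!duplicated(.resKey(a$chain, a$resno, a$insert)),
                           , drop = FALSE]
    ca
  }
  ao <- repAtoms(original); ac <- repAtoms(composite)
  ko <- .resKey(ao$chain, ao$resno, ao$insert)
  kc <- .resKey(ac$chain, ac$resno, ac$insert)
  shared <- intersect(ko, kc)
  if (!length(shared)) stop("the two models share no residues")
  io <- match(shared, ko); ic <- match(shared, kc)
  dx <- ac$x[ic] - ao$x[io]; dy <- ac$y[ic] - ao$y[io]
  dz <- ac$z[ic] - ao$z[io]
  seg <- rep("", length(shared))
  if (!is.null(segments)) {
    for (nm in names(segments)) {
      sel <- segments[[nm]]@selections
      for (r in seq_len(nrow(sel))) {
        hit <- ao$chain[io] == sel$chain[r] &
          ao$resno[io] >= sel$first[r] & ao$resno[io] <= sel$last[r]
        seg[hit] <- nm
      }
    }
  }
  new("DisplacementField", entries = data.frame(
    segment = seg, chain = ao$chain[io], resno = ao$resno[io],
    insert = ao$insert[io],
    x0 = ao$x[io], y0 = ao$y[io], z0 = ao$z[io],
    dx = dx, dy = dy, dz = dz, mag = sqrt(dx^2 + dy^2 + dz^2),
    stringsAsFactors = FALSE))
}

#' Displacement field of a morph-compare report
#'
#' @param report A [MorphCompareReport-class].
#' @return A [DisplacementField-class] built from the per-residue vectors
#'   recorded by [morphCompare()].
#' @export
reportDisplacementField <- function(report) {
  d <- report@displacements
  d$mag <- sqrt(d$dx^2 + d$dy^2 + d$dz^2)
  new("DisplacementField", entries = d)
}

#' Per-segment displacement magnitude summary
#'
#' @param field A [DisplacementField-class].
#' @return data.frame with segment, n, min, mean, max magnitude (Angstrom).
#' @export
displacementSummary <- function(field) {
  e <- entries(field)
  out <- do.call(rbind, lapply(split(e$mag, e$segment), function(m)
    data.frame(n = length(m), min = min(m), mean = mean(m), max = max(m))))
  out$segment <- rownames(out)
  rownames(out) <- NULL
  out[, c("segment", "n", "min", "mean", "max")]
}

#' Mean displacement arrow of a segment
#'
#' The arrow is anchored at the centroid of the start positions; its
#' vector is the component-wise mean of the displacement vectors. When
#' the mean vector is shorter than 10 percent of the mean per-residue
#' magnitude the motion is predominantly rotational and the mean is
#' flagged as uninformative.
#'
#' @param field A [DisplacementField-class].
#' @param segment Segment name present in the field.
#' @return List with `anchor`, `vector` (length-3 numerics, Angstrom) and
#'   `rotational` (logical flag).
#' @export
meanArrow <- function(field, segment) {
  e <- entries(field)
  e <- e[e$segment == segment, , drop = FALSE]
  if (!nrow(e)) stop("unknown segment: ", segment)
  v <- c(mean(e$dx), mean(e$dy), mean(e$dz))
  list(anchor = c(mean(e$x0), mean(e$y0), mean(e$z0)), vector = v,
       rotational = sqrt(sum(v^2)) < 0.1 * mean(e$mag) && mean(e$mag) > 0)
}

#' Inter-gamma-tubulin centroid distance change
#'
#' Measures the distance between the centroids of two subunit segments in
#' the query model and in the composite (reference-conformation) model.
#' `delta = dQuery - dReference`; a positive delta means the query is
#' wider, i.e. the transition to the reference conformation moves the two
#' subunits closer together.
#'
#' @param query,composite [AtomicStructure-class] models.
#' @param gamma1,gamma2 [SegmentSpec-class] for the two subunits (must
#'   resolve in both models).
#' @param weighted Use an occupancy-weighted all-atom centroid instead of
#'   the unweighted Calpha centroid.
#' @return A [CentroidReport-class].
#' @export
centroidDistanceChange <- function(query, composite, gamma1, gamma2,
                                   weighted = FALSE) {
  centroid <- function(s, spec) {
    seg <- selectSegment(s, spec,
                         atomSubset = if (weighted) "ALL_HEAVY" else "CA_ONLY")
    w <- if (weighted) atoms(seg)$o else rep(1, nAtoms(seg))
    colSums(coords(seg) * w) / sum(w)
  }
  dQ <- sqrt(sum((centroid(query, gamma1) - centroid(query, gamma2))^2))
  dR <- sqrt(sum((centroid(composite, gamma1) -
                    centroid(composite, gamma2))^2))
  delta <- dQ - dR
  dir <- if (abs(delta) < 0.05) "unchanged" else if (delta > 0) "closer"
  else "apart"
  new("CentroidReport", dQuery = dQ, dReference = dR, delta = delta,
      direction = dir)
}

#' Write a displacement field as TSV
#'
#' Columns: segment, chain, resnum, x0, y0, z0, dx, dy, dz, mag.
#'
#' @param field A [DisplacementField-class].
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
writeDisplacementField <- function(field, path) {
  e <- entries(field)
  e[, c("x0", "y0", "z0", "dx", "dy", "dz", "mag")] <-
    round(e[, c("x0", "y0", "z0", "dx", "dy", "dz", "mag")], 4)
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write mean-displacement arrows as a plain-text marker file
#'
#' One line per segment: segment, then the arrow start and end points
#' (anchor, anchor + vector), usable by any renderer.
#'
#' @param field A [DisplacementField-class].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeArrows <- function(field, path) {
  segs <- setdiff(unique(entries(field)$segment), "")
  rows <- lapply(segs, function(nm) {
    a <- meanArrow(field, nm)
    data.frame(segment = nm,
               x0 = a$anchor[1], y0 = a$anchor[2], z0 = a$anchor[3],
               x1 = a$anchor[1] + a$vector[1],
               y1 = a$anchor[2] + a$vector[2],
               z1 = a$anchor[3] + a$vector[3],
               rotational = a$rotational)
  })
  df <- do.call(rbind, rows)
  df[, 2:7] <- round(df[, 2:7], 4)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
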