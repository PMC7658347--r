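## Contact detection and physicochemical character of subunit interfaces.

#' Kyte-Doolittle hydropathy values
#'
#' Named numeric vector over the 20 standard amino acids (three-letter
#' codes); residues with a positive value (A, C, F, I, L, M, V) count as
#' hydrophobic.
#'
#' @export
kdHydropathy <- c(
  ILE = 4.5, VAL = 4.2, LEU = 3.8, PHE = 2.8, CYS = 2.5, MET = 1.9,
  ALA = 1.8, GLY = -0.4, THR = -0.7, SER = -0.8, TRP = -0.9, TYR = -1.3,
  PRO = -1.6, HIS = -3.2, GLU = -3.5, GLN = -3.5, ASP = -3.5, ASN = -3.5,
  LYS = -3.9, ARG = -4.5)

.ACIDIC_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.BASIC_N <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                 HIS = c("ND1", "NE2"))

.heavyAtoms <- function(s) {
  a <- atoms(s)
  a <- a[toupper(trimws(a$elesy)) != "H" & !a$resid %in% .WATER_NAMES,
         , drop = FALSE]
  if (!nrow(a)) stop("selection contains no heavy atoms")
  a
}

## all-pairs reference implementation; used as the oracle in tests
.contactsBrute <- function(aa, ab, cutoff) {
  ca <- as.matrix(aa[, c("x", "y", "z")])
  cb <- as.matrix(ab[, c("x", "y", "z")])
  d2 <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * ca %*% t(cb)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= cutoff^2 + 1e-9, arr.ind = TRUE)
  if (!nrow(hit)) return(NULL)
  data.frame(ia = hit[, 1], ib = hit[, 2],
             dist = sqrt(d2[hit]), stringsAsFactors = FALSE)
}

## spatial-grid (cell list) neighbour search, near-linear in atoms
.contactsGrid <- function(aa, ab, cutoff) {
  ca <- as.matrix(aa[, c("x", "y", "z")])
  cb <- as.matrix(ab[, c("x", "y", "z")])
  cellOf <- function(x) floor(x / cutoff)
  keyOf <- function(cells) paste(cells[, 1], cells[, 2], cells[, 3])
  cellsB <- cellOf(cb)
  bIndex <- split(seq_len(nrow(cb)), keyOf(cellsB))
  cellsA <- cellOf(ca)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- vector("list", nrow(ca))
  for (i in seq_len(nrow(ca))) {
    neigh <- sweep(offs, 2, cellsA[i, ], "+")
    cand <- unlist(bIndex[keyOf(neigh)], use.names = FALSE)
    if (!length(cand)) next
    d2 <- colSums((t(cb[cand, , drop = FALSE]) - ca[i, ])^2)
    keep <- d2 <= cutoff^2 + 1e-9
    if (any(keep))
      out[[i]] <- data.frame(ia = i, ib = cand[keep],
                             dist = sqrt(d2[keep]))
  }
  res <- do.call(rbind, out)
  if (is.null(res)) NULL else res
}

#' Residue-residue contacts across an interface
#'
#' All residue pairs of the two selections having any heavy-atom pair at
#' distance <= cutoff (inclusive), with the minimum heavy-atom distance.
#' Uses a spatial cell grid so cost is near-linear in atom count; the
#' all-pairs scan is available as `method = "brute"` for verification.
#'
#' @param a,b [AtomicStructure-class] selections forming the two sides.
#' @param cutoff Heavy-atom distance cutoff, Angstrom (default 4.5).
#' @param method "grid" (default) or "brute".
#' @return data.frame with columns chainA, resnoA, insertA, residA,
#'   chainB, resnoB, insertB, residB, minDist.
#' @export
interfaceContacts <- function(a, b, cutoff = 4.5,
                              method = c("grid", "brute")) {
  method <- match.arg(method)
  if (cutoff <= 0) stop("cutoff must be > 0")
  aa <- .heavyAtoms(a); ab <- .heavyAtoms(b)
  hits <- if (method == "grid") .contactsGrid(aa, ab, cutoff)
  else .contactsBrute(aa, ab, cutoff)
  empty <- data.frame(chainA = character(0), resnoA = integer(0),
                      insertA = character(0), residA = character(0),
                      chainB = character(0), resnoB = integer(0),
                      insertB = character(0), residB = character(0),
                      minDist = numeric(0))
  if (is.null(hits)) return(empty)
  keyA <- .resKey(aa$chain[hits$ia], aa$resno[hits$ia], aa$insert[hits$ia])
  keyB <- .resKey(ab$chain[hits$ib], ab$resno[hits$ib], ab$insert[hits$ib])
  grp <- paste(keyA, keyB, sep = "::")
  minIdx <- vapply(split(seq_along(grp), grp),
                   function(ix) ix[which.min(hits$dist[ix])], integer(1))
  o <- minIdx[order(hits$ia[minIdx], hits$ib[minIdx])]
  data.frame(
    chainA = aa$chain[hits$ia[o]], resnoA = aa$resno[hits$ia[o]],
    insertA = aa$insert[hits$ia[o]], residA = aa$resid[hits$ia[o]],
    chainB = ab$chain[hits$ib[o]], resnoB = ab$resno[hits$ib[o]],
    insertB = ab$insert[hits$ib[o]], residB = ab$resid[hits$ib[o]],
    minDist = hits$dist[o], row.names = NULL, stringsAsFactors = FALSE)
}

.saltBridgePairs <- function(aa, ab, cutoff) {
  pick <- function(at, table) {
    keep <- rep(FALSE, nrow(at))
    for (res in names(table))
      keep <- keep | (at$resid == res & trimws(at$elety) %in% table[[res]])
    at[keep, , drop = FALSE]
  }
  rows <- list()
  for (side in 1:2) {
    acid <- pick(if (side == 1) aa else ab, .ACIDIC_O)
    base <- pick(if (side == 1) ab else aa, .BASIC_N)
    if (!nrow(acid) || !nrow(base)) next
    hits <- .contactsBrute(acid, base, cutoff)
    if (is.null(hits)) next
    grp <- paste(.resKey(acid$chain[hits$ia], acid$resno[hits$ia],
                         acid$insert[hits$ia]),
                 .resKey(base$chain[hits$ib], base$resno[hits$ib],
                         base$insert[hits$ib]))
    best <- vapply(split(seq_along(grp), grp),
                   function(ix) ix[which.min(hits$dist[ix])], integer(1))
    rows[[side]] <- data.frame(
      acidChain = acid$chain[hits$ia[best]],
      acidResno = acid$resno[hits$ia[best]],
      acidResid = acid$resid[hits$ia[best]],
      baseChain = base$chain[hits$ib[best]],
      baseResno = base$resno[hits$ib[best]],
      baseResid = base$resid[hits$ib[best]],
      dist = hits$dist[best], row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(acidChain = character(0),
                               acidResno = integer(0),
                               acidResid = character(0),
                               baseChain = character(0),
                               baseResno = integer(0),
                               baseResid = character(0),
                               dist = numeric(0))
  else out[order(out$acidChain, out$acidResno), , drop = FALSE]
}

#' Full interface report: contacts plus physicochemical character
#'
#' Detects residue contacts ([interfaceContacts()]), computes the
#' hydrophobic fraction of the interface residues on each side
#' (Kyte-Doolittle hydropathy > 0) and lists salt bridges (Asp/Glu
#' side-chain O to Lys/Arg/His side-chain N within the salt-bridge
#' cutoff).
#'
#' @param a,b [AtomicStructure-class] selections forming the two sides.
#' @param cutoff Heavy-atom contact cutoff, Angstrom (default 4.5).
#' @param saltBridgeCutoff Salt-bridge N-O cutoff, Angstrom (default 4.0).
#' @param hydropathy Named hydropathy table; defaults to [kdHydropathy].
#' @return An [InterfaceReport-class].
#' @export
interfaceReport <- function(a, b, cutoff = 4.5, saltBridgeCutoff = 4.0,
                            hydropathy = kdHydropathy) {
  ct <- interfaceContacts(a, b, cutoff)
  if (!nrow(ct)) stop("no contacts within ", cutoff, " A")
  hydroFrac <- function(resid) {
    kd <- hydropathy[resid]
    kd[is.na(kd)] <- 0
    mean(kd > 0)
  }
  uA <- !duplicated(.resKey(ct$chainA, ct$resnoA, ct$insertA))
  uB <- !duplicated(.resKey(ct$chainB, ct$resnoB, ct$insertB))
  sb <- .saltBridgePairs(.heavyAtoms(a), .heavyAtoms(b), saltBridgeCutoff)
  new("InterfaceReport", contacts = ct, cutoff = cutoff,
      hydrophobicFractionA = hydroFrac(ct$residA[uA]),
      hydrophobicFractionB = hydroFrac(ct$residB[uB]),
      saltBridges = sb)
}

#' Write an interface report as TSV
#'
#' Writes the contact table and appends a one-line summary as a trailing
#' comment (n_contacts, hydrophobic fractions, n_salt_bridges).
#'
#' @param report An [InterfaceReport-class].
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
writeInterfaceReport <- function(report, path) {
  ct <- contacts(report)
  ct$minDist <- round(ct$minDist, 3)
  utils::write.table(ct, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cat(sprintf(
    "# n_contacts=%d hydrophobic_fraction_A=%.3f hydrophobic_fraction_B=%.3f n_salt_bridges=%d\n",
    nrow(ct), report@hydrophobicFractionA, report@hydrophobicFractionB,
    nrow(saltBridges(report))), file = path, append = TRUE)
  invisible(path)
}
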