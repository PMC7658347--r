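## Atomic model I/O, segment selection and residue correspondence.
## Parsing goes through bio3d; this layer enforces altloc resolution and
## the residue-identity conventions used by the comparison machinery.

.BACKBONE_ATOMS <- c("N", "CA", "C", "O")
.WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Construct an AtomicStructure from an atom table
#'
#' Low-level constructor used by the parsers and the synthetic generator.
#'
#' @param id Model label.
#' @param atoms data.frame with columns chain, resno, insert, resid, elety,
#'   elesy, x, y, z, o, het (missing insert/o/het/elesy are filled with
#'   defaults).
#' @return An [AtomicStructure-class].
#' @export
atomicStructure <- function(id, atoms) {
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$elesy))
    atoms$elesy <- substr(trimws(atoms$elety), 1, 1)
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  new("AtomicStructure", id = id, atoms = atoms[, .ATOM_COLS])
}

## keep the highest-occupancy altloc; ties broken by alphabetical altloc id
.resolveAltlocs <- function(at) {
  alt <- at$alt %||% rep("", nrow(at))
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(.resKey(at$chain, at$resno, at$insert), at$elety)
  ord <- order(key, -occ, alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  ## restore file order
  at[order(as.integer(rownames(at))), , drop = FALSE]
}

#' Read an atomic model from PDB or mmCIF
#'
#' Altloc duplicates are resolved to the highest-occupancy conformer
#' (ties: alphabetically first altloc id). HETATM records are retained and
#' flagged.
#'
#' @param path Path to a PDB or mmCIF file.
#' @param format "pdb", "cif" or "auto" (by file extension).
#' @param id Model label; defaults to the file name.
#' @return An [AtomicStructure-class].
#' @export
#' @examples
#' p <- makeToyPair(toySpokeParams(tiltAngle = 0))
#' f <- tempfile(fileext = ".pdb")
#' writeStructure(p$open, f)
#' s <- readStructure(f)
readStructure <- function(path, format = c("auto", "pdb", "cif"),
                          id = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE,
                                         rm.alt = FALSE)
    else bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  if (is.null(at) || !nrow(at)) stop("empty model in ", path)
  rownames(at) <- seq_len(nrow(at))
  at <- .resolveAltlocs(at)
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- ""
  at$o[is.na(at$o)] <- 1
  atomicStructure(id, data.frame(
    chain = at$chain, resno = at$resno, insert = at$insert,
    resid = at$resid, elety = at$elety,
    elesy = at$elesy %||% substr(at$elety, 1, 1),
    x = at$x, y = at$y, z = at$z, o = at$o,
    het = at$type == "HETATM", stringsAsFactors = FALSE))
}

#' Write an atomic model as PDB
#'
#' @param s An [AtomicStructure-class].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
writeStructure <- function(s, path) {
  a <- atoms(s)
  if (!nrow(a)) stop("refusing to write an empty structure")
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(coords(s))),
    type = ifelse(a$het, "HETATM", "ATOM"),
    resno = a$resno, resid = a$resid, chain = a$chain,
    insert = ifelse(a$insert == "", NA, a$insert),
    elety = a$elety, elesy = a$elesy,
    o = a$o, b = rep(0, nrow(a)))
  invisible(path)
}

#' Define a comparison segment
#'
#' @param name Segment name (e.g. "Spc98-GRIP2").
#' @param chain Chain id(s), recycled against `first`/`last`.
#' @param first,last Inclusive author residue numbers of each range.
#' @param atomSubset "CA_ONLY" (default), "BACKBONE" or "ALL_HEAVY".
#' @return A [SegmentSpec-class].
#' @export
segmentSpec <- function(name, chain, first, last, atomSubset = "CA_ONLY") {
  sel <- data.frame(chain = as.character(chain),
                    first = as.integer(first), last = as.integer(last),
                    stringsAsFactors = FALSE)
  new("SegmentSpec", name = name, selections = sel, atomSubset = atomSubset)
}

.subsetFilter <- function(a, atomSubset) {
  switch(atomSubset,
    CA_ONLY  = trimws(a$elety) == "CA",
    BACKBONE = trimws(a$elety) %in% .BACKBONE_ATOMS,
    ALL_HEAVY = toupper(trimws(a$elesy)) != "H",
    stop("unknown atom subset: ", atomSubset))
}

#' Select the atoms of a segment
#'
#' Filters a structure down to the residue ranges of a [SegmentSpec-class]
#' and the requested atom subset, preserving residue order. Waters and
#' ligands (HETATM) are excluded. Residues present in a range but missing
#' the requested atoms are skipped with a warning.
#'
#' @param s An [AtomicStructure-class].
#' @param spec A [SegmentSpec-class].
#' @param atomSubset Atom subset override; defaults to the spec's.
#' @return An [AtomicStructure-class] containing only the selected atoms.
#' @export
selectSegment <- function(s, spec, atomSubset = NULL) {
  atomSubset <- atomSubset %||% spec@atomSubset
  a <- atoms(s)
  sel <- spec@selections
  keep <- rep(FALSE, nrow(a))
  unmatched <- character(0)
  for (i in seq_len(nrow(sel))) {
    hit <- a$chain == sel$chain[i] & a$resno >= sel$first[i] &
      a$resno <= sel$last[i] & !a$het & !(a$resid %in% .WATER_NAMES)
    if (!any(hit))
      unmatched <- c(unmatched, sprintf("%s:%d-%d", sel$chain[i],
                                        sel$first[i], sel$last[i]))
    keep <- keep | hit
  }
  if (!any(keep))
    stop("segment '", spec@name, "' matched no residues (ranges: ",
         paste(unmatched, collapse = ", "), ")")
  inRange <- a[keep, , drop = FALSE]
  nResBefore <- length(unique(.resKey(inRange$chain, inRange$resno,
                                      inRange$insert)))
  out <- inRange[.subsetFilter(inRange, atomSubset), , drop = FALSE]
  nResAfter <- length(unique(.resKey(out$chain, out$resno, out$insert)))
  if (nResAfter < nResBefore)
    warning(nResBefore - nResAfter, " residue(s) in segment '", spec@name,
            "' lack ", atomSubset, " atoms and were skipped")
  if (!nrow(out))
    stop("segment '", spec@name, "' has no atoms of subset ", atomSubset)
  atomicStructure(paste0(structureId(s), ":", spec@name), out)
}

## one-letter sequence of the unique residues of a selection, in order
.residueTable <- function(s) {
  a <- atoms(s)
  key <- .resKey(a$chain, a$resno, a$insert)
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             insert = a$insert[first], resid = a$resid[first],
             stringsAsFactors = FALSE)
}

.oneLetter <- function(resid3) {
  one <- bio3d::aa321(resid3)
  bad <- is.na(one) | one == "X"
  if (any(bad & !resid3 %in% c("UNK"))) {
    warning("non-standard residue name(s) mapped to 'X': ",
            paste(unique(resid3[bad]), collapse = ", "))
  }
  one[is.na(one)] <- "X"
  one
}

#' Align the residues of two selections
#'
#' Global sequence alignment (Needleman-Wunsch, BLOSUM62, affine gap
#' penalties: open 10, extend 1) of the one-letter sequences of two
#' structure selections, yielding a one-to-one, order-preserving residue
#' correspondence. Non-standard residues are mapped to 'X' with a warning.
#'
#' @param a,b [AtomicStructure-class] selections with >= 2 standard
#'   residues each.
#' @return A [Correspondence-class].
#' @export
alignResidues <- function(a, b) {
  ta <- .residueTable(a); tb <- .residueTable(b)
  if (nrow(ta) < 2 || nrow(tb) < 2)
    stop("both selections need >= 2 residues to align")
  sa <- paste(.oneLetter(ta$resid), collapse = "")
  sb <- paste(.oneLetter(tb$resid), collapse = "")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = 10, gapExtension = 1, type = "global")
  ca <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  cb <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  ia <- cumsum(ca != "-"); ib <- cumsum(cb != "-")
  paired <- ca != "-" & cb != "-"
  idxA <- ia[paired]; idxB <- ib[paired]
  pairs <- data.frame(
    chainA = ta$chain[idxA], resnoA = ta$resno[idxA],
    insertA = ta$insert[idxA],
    chainB = tb$chain[idxB], resnoB = tb$resno[idxB],
    insertB = tb$insert[idxB], stringsAsFactors = FALSE)
  new("Correspondence", pairs = pairs,
      alignmentScore = Biostrings::score(pa),
      coverageA = nrow(pairs) / nrow(ta),
      coverageB = nrow(pairs) / nrow(tb))
}

#' Read a set of segment definitions from a YAML config
#'
#' The config is a mapping from segment name to a list of inclusive
#' residue ranges, e.g.
#' \preformatted{
#' atom_subset: CA_ONLY
#' segments:
#'   Spc97-GRIP1:
#'     - {chain: A, first: 92, last: 430}
#' }
#'
#' @param path Path to a YAML file.
#' @return Named list of [SegmentSpec-class].
#' @export
readSegmentConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$segments)) stop("config has no 'segments' mapping")
  subset <- cfg$atom_subset %||% "CA_ONLY"
  out <- lapply(names(cfg$segments), function(nm) {
    ranges <- cfg$segments[[nm]]
    segmentSpec(nm,
      chain = vapply(ranges, function(r) as.character(r$chain), ""),
      first = vapply(ranges, function(r) as.integer(r$first), 0L),
      last = vapply(ranges, function(r) as.integer(r$last), 0L),
      atomSubset = subset)
  })
  names(out) <- names(cfg$segments)
  out
}
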