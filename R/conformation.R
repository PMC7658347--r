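## Straight/curved tubulin classification against density, the three-way
## evidence scheme: dock each complete reference beta-tubulin into the
## gamma-tubulin density, then compare helices alpha6/alpha7 by (i) Calpha
## RMSD in the docked positions and (ii) masked cross-correlation of
## simulated helix density against the experimental map.

#' Conformation label rule
#'
#' "straight" iff the straight reference wins on both criteria
#' (rmsdStraight < rmsdCurved AND ccStraight > ccCurved); "curved" iff
#' both are reversed; otherwise (including any tie) "indeterminate".
#'
#' @param rmsdStraight,rmsdCurved Helix RMSD against each docked
#'   reference, Angstrom.
#' @param ccStraight,ccCurved Density cross-correlation for each docked
#'   reference.
#' @return "straight", "curved" or "indeterminate".
#' @export
#' @examples
#' conformationLabel(1.3, 2.1, 0.83, 0.79)
conformationLabel <- function(rmsdStraight, rmsdCurved,
                              ccStraight, ccCurved) {
  if (rmsdStraight < rmsdCurved && ccStraight > ccCurved) return("straight")
  if (rmsdCurved < rmsdStraight && ccCurved > ccStraight) return("curved")
  "indeterminate"
}

#' Helix range definition for tubulin classification
#'
#' Residue ranges of tubulin helices alpha6 and alpha7 on a given chain.
#' These are configuration: helix boundaries follow each structure's own
#' numbering and should be verified by the user.
#'
#' @param chain Chain id carrying the tubulin subunit.
#' @param a6,a7 Integer length-2 vectors, inclusive residue ranges.
#' @return A named list of class "HelixRanges".
#' @export
helixRanges <- function(chain, a6, a7) {
  stopifnot(length(a6) == 2, length(a7) == 2, a6[1] <= a6[2],
            a7[1] <= a7[2])
  if (a6[1] <= a7[2] && a7[1] <= a6[2] && a6[1] <= a6[2])
    if (max(a6[1], a7[1]) <= min(a6[2], a7[2]))
      stop("alpha6 and alpha7 ranges must not overlap")
  structure(list(chain = chain, a6 = as.integer(a6), a7 = as.integer(a7)),
            class = "HelixRanges")
}

.helixSpec <- function(name, h) {
  segmentSpec(name, chain = c(h$chain, h$chain),
              first = c(h$a6[1], h$a7[1]), last = c(h$a6[2], h$a7[2]),
              atomSubset = "CA_ONLY")
}

## docked-position Calpha rmsd between two helix selections, no refit
.dockedRmsd <- function(a, b) {
  corr <- alignResidues(a, b)
  pc <- .pairedCoords(a, b, corr, "CA_ONLY")
  if (nrow(pc$mobile) < 3) stop("fewer than 3 paired helix residues")
  sqrt(mean(rowSums((pc$mobile - pc$target)^2)))
}

#' Classify a tubulin subunit as straight or curved
#'
#' Docks each complete reference tubulin model into the subunit's density
#' segment as a rigid body ([rigidBodyFit()], started from the
#' sequence-matched superposition onto the subunit model), then scores
#' helices alpha6/alpha7 of each docked reference by (i) Calpha RMSD
#' against the corresponding helices of the subunit model, positions as
#' docked with no re-superposition, and (ii) cross-correlation between
#' simulated density of the docked helices and the experimental map,
#' masked to within `maskRadius` of the docked helix atoms.
#'
#' @param gammaModel [AtomicStructure-class], the subunit model (e.g. one
#'   gamma-tubulin copy).
#' @param gammaDensity [DensityMap-class] covering the subunit region.
#' @param straightRef,curvedRef [AtomicStructure-class] complete reference
#'   tubulin models in the straight and curved conformations.
#' @param helices List with components `gamma`, `straight`, `curved`, each
#'   a [helixRanges()] definition in the respective structure's numbering.
#' @param params [simulationParams()] for the simulated helix density.
#' @param voxelSize Simulation grid voxel, Angstrom.
#' @param maskRadius Mask radius around docked helix atoms, Angstrom.
#' @return A [ConformationCall-class].
#' @export
classifyTubulin <- function(gammaModel, gammaDensity, straightRef,
                            curvedRef, helices,
                            params = simulationParams(), voxelSize = 1.2,
                            maskRadius = 3.0) {
  stopifnot(all(c("gamma", "straight", "curved") %in% names(helices)))
  gammaHel <- selectSegment(gammaModel,
                            .helixSpec("gamma-helices", helices$gamma))
  scoreRef <- function(ref, hr) {
    ## start placement: sequence-matched superposition onto the model
    startFit <- matchedSuperpose(ref, gammaModel, atomSubset = "CA_ONLY")
    fit <- rigidBodyFit(ref, gammaDensity, start = startFit@transform)
    docked <- applyTransform(ref, fit$transform)
    dockedHel <- selectSegment(docked, .helixSpec("ref-helices", hr))
    r <- .dockedRmsd(dockedHel, gammaHel)
    sim <- simulateDensity(dockedHel, params, voxelSize)
    msk <- .zoneSelect(sim, coords(dockedHel), maskRadius)
    cc <- crossCorrelation(sim, gammaDensity, mask = msk,
                           aboutMean = TRUE)@cc
    list(rmsd = r, cc = cc)
  }
  s <- scoreRef(straightRef, helices$straight)
  c <- scoreRef(curvedRef, helices$curved)
  new("ConformationCall",
      label = conformationLabel(s$rmsd, c$rmsd, s$cc, c$cc),
      rmsdStraight = s$rmsd, rmsdCurved = c$rmsd,
      ccStraight = s$cc, ccCurved = c$cc)
}

#' Write a conformation call as one-row TSV
#'
#' @param call A [ConformationCall-class].
#' @param path Output TSV path.
#' @param subunit Label for the classified subunit.
#' @return Invisibly, the path.
#' @export
writeConformationCall <- function(call, path, subunit = "tubulin") {
  df <- data.frame(subunit = subunit,
                   rmsd_curved_A = round(call@rmsdCurved, 3),
                   rmsd_straight_A = round(call@rmsdStraight, 3),
                   cc_curved = round(call@ccCurved, 4),
                   cc_straight = round(call@ccStraight, 4),
                   label = call@label)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
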