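## Config-driven orchestration of the pipeline stages with a reproducible
## run record. The exported functions are the programmatic entry point;
## inst/scripts/run_pipeline.R wraps them for shell use.

.RUN_COMMANDS <- c("synthetic", "compare", "classify", "displacement",
                   "interface")

#' Read and validate a run configuration
#'
#' YAML schema (all paths relative to the config file's directory):
#' \preformatted{
#' seed: 1
#' output_dir: out
#' atom_subset: CA_ONLY
#' synthetic: {tilt_angle: 15, noise_sigma: 0, helix_length: 20,
#'             n_helices: 3, resolution: 3.6, voxel_size: 1.2}
#' compare: {query: open.pdb, reference: closed.pdb,
#'           segments: segments.yaml,
#'           anchor: [Spc97-GRIP1, Spc97-GRIP2, Spc97-gamma]}
#' interface: {side_a: {chain: A}, side_b: {chain: B},
#'             cutoff: 4.5, salt_bridge_cutoff: 4.0}
#' }
#'
#' @param path Path to the YAML config.
#' @return A validated config list (class "RunConfig") with absolute
#'   paths resolved.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output_dir <- cfg$output_dir %||% "tuscmorph-out"
  if (!grepl("^/", cfg$output_dir))
    cfg$output_dir <- file.path(base, cfg$output_dir)
  cfg$atom_subset <- cfg$atom_subset %||% "CA_ONLY"
  if (!cfg$atom_subset %in% c("CA_ONLY", "BACKBONE", "ALL_HEAVY"))
    stop("config field atom_subset: must be CA_ONLY, BACKBONE or ALL_HEAVY")
  resolve <- function(p) if (is.null(p) || grepl("^/", p)) p
  else file.path(base, p)
  for (f in c("query", "reference", "segments"))
    cfg$compare[[f]] <- resolve(cfg$compare[[f]])
  cfg$interface$structure <- resolve(cfg$interface$structure)
  cfg$configPath <- normalizePath(path)
  class(cfg) <- "RunConfig"
  cfg
}

.checkInputs <- function(paths) {
  missing <- paths[!vapply(paths, file.exists, TRUE)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
}

.runLog <- function(cfg, outDir, outputs, warnings) {
  log <- list(
    package = as.character(utils::packageVersion("TuSCmorph")),
    r_version = R.version.string,
    config = cfg$configPath,
    config_md5 = unname(tools::md5sum(cfg$configPath)),
    seed = cfg$seed,
    outputs = outputs,
    warnings = warnings,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(log, file.path(outDir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run a pipeline stage from a configuration
#'
#' Commands: `synthetic` generates the toy open/closed pair and its
#' ground-truth record; `compare` runs [morphCompare()] between two
#' models; `displacement` additionally writes the per-residue field,
#' arrows, and the inter-gamma centroid report; `interface` writes an
#' [interfaceReport()]; `classify` runs the straight/curved classifier on
#' the synthetic self-consistency setup. All outputs are TSV/JSON files
#' in the configured output directory, plus a run log with the config
#' hash and captured warnings.
#'
#' @param config A "RunConfig" from [readRunConfig()] (or a path to one).
#' @param command One of "synthetic", "compare", "displacement",
#'   "interface", "classify".
#' @return Invisibly, a character vector of the report files written.
#' @export
runPipeline <- function(config, command = .RUN_COMMANDS) {
  command <- match.arg(command)
  if (is.character(config)) config <- readRunConfig(config)
  outDir <- config$output_dir
  warnings <- character(0)
  outputs <- withCallingHandlers(
    .runStage(config, command, outDir),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  .runLog(config, outDir, outputs, warnings)
  invisible(outputs)
}

.syntheticParams <- function(config) {
  sc <- config$synthetic %||% list()
  toySpokeParams(
    nHelicesPerDomain = sc$n_helices %||% 3L,
    helixLength = sc$helix_length %||% 20L,
    tiltAngle = sc$tilt_angle %||% 15,
    noiseSigma = sc$noise_sigma %||% 0,
    seed = config$seed)
}

.compareInputs <- function(config) {
  cc <- config$compare
  if (is.null(cc$query) || is.null(cc$reference))
    stop("config fields compare.query and compare.reference are required")
  .checkInputs(c(cc$query, cc$reference, cc$segments))
  segs <- readSegmentConfig(cc$segments)
  list(query = readStructure(cc$query), reference = readStructure(cc$reference),
       segments = segs,
       anchor = unlist(cc$anchor) %||% names(segs)[1])
}

.runStage <- function(config, command, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  p <- .syntheticParams(config)
  sc <- config$synthetic %||% list()

  if (command == "synthetic") {
    pair <- makeToyPair(p)
    openPath <- file.path(outDir, "toy_open.pdb")
    closedPath <- file.path(outDir, "toy_closed.pdb")
    writeStructure(pair$open, openPath)
    writeStructure(pair$closed, closedPath)
    mapPath <- file.path(outDir, "toy_open.mrc")
    writeMRC(makeToyMap(pair$open,
                        resolution = sc$resolution %||% 3.6,
                        voxelSize = sc$voxel_size %||% 1.2,
                        noiseSigma = sc$map_noise %||% 0,
                        seed = config$seed), mapPath)
    gt <- pair$groundTruth
    gtPath <- file.path(outDir, "ground_truth.json")
    jsonlite::write_json(list(
      tilt_angle_deg = gt$tiltAngle, hinge = gt$hinge, axis = gt$axis,
      expected_rmsd_A = as.list(gt$expectedRmsd),
      expected_mean_disp_A = as.list(gt$expectedMeanDisp),
      d_open_A = gt$dOpen, d_closed_A = gt$dClosed),
      gtPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    segPath <- file.path(outDir, "segments.yaml")
    lay <- lapply(pair$segments, function(sp) {
      apply(sp@selections, 1, function(r)
        list(chain = unname(r[["chain"]]),
             first = as.integer(r[["first"]]),
             last = as.integer(r[["last"]])), simplify = FALSE)
    })
    yaml::write_yaml(list(atom_subset = "CA_ONLY", segments = lay), segPath)
    return(c(openPath, closedPath, mapPath, gtPath, segPath))
  }

  if (command %in% c("compare", "displacement")) {
    inp <- .compareInputs(config)
    report <- morphCompare(inp$query, inp$reference, inp$segments,
                           anchor = inp$anchor,
                           atomSubset = config$atom_subset)
    rptPath <- file.path(outDir, "morph_compare.tsv")
    writeMorphReport(report, rptPath)
    out <- rptPath
    if (command == "displacement") {
      fld <- reportDisplacementField(report)
      fldPath <- file.path(outDir, "displacement_field.tsv")
      writeDisplacementField(fld, fldPath)
      arrPath <- file.path(outDir, "arrows.tsv")
      writeArrows(fld, arrPath)
      out <- c(out, fldPath, arrPath)
      g1 <- config$compare$gamma1 %||% "Spc97-gamma"
      g2 <- config$compare$gamma2 %||% "Spc98-gamma"
      if (all(c(g1, g2) %in% names(inp$segments))) {
        cr <- centroidDistanceChange(inp$query, report@composite,
                                     inp$segments[[g1]],
                                     inp$segments[[g2]])
        cenPath <- file.path(outDir, "centroids.tsv")
        utils::write.table(data.frame(
          d_query_A = round(cr@dQuery, 4),
          d_reference_A = round(cr@dReference, 4),
          delta_A = round(cr@delta, 4), direction = cr@direction),
          cenPath, sep = "\t", quote = FALSE, row.names = FALSE)
        out <- c(out, cenPath)
      }
    }
    return(out)
  }

  if (command == "interface") {
    ic <- config$interface
    if (is.null(ic$structure))
      stop("config field interface.structure is required")
    .checkInputs(ic$structure)
    s <- readStructure(ic$structure)
    side <- function(sd) {
      a <- atoms(s)
      keep <- a$chain %in% unlist(sd$chain)
      if (!any(keep)) stop("interface side selects no atoms (chain ",
                           paste(unlist(sd$chain), collapse = ","), ")")
      atomicStructure(paste(unlist(sd$chain), collapse = ""), a[keep, ])
    }
    rpt <- interfaceReport(side(ic$side_a), side(ic$side_b),
                           cutoff = ic$cutoff %||% 4.5,
                           saltBridgeCutoff = ic$salt_bridge_cutoff %||% 4.0)
    rptPath <- file.path(outDir, "interface.tsv")
    writeInterfaceReport(rpt, rptPath)
    return(rptPath)
  }

  ## classify: synthetic self-consistency classification
  pair <- makeToyPair(p)
  gammaSeg <- selectSegment(pair$open, pair$segments[["Spc97-gamma"]])
  dens <- makeToyMap(gammaSeg, resolution = sc$resolution %||% 3.6,
                     voxelSize = sc$voxel_size %||% 1.2,
                     noiseSigma = sc$map_noise %||% 0, seed = config$seed)
  hr <- helixRanges("C", a6 = c(1, p@helixLength),
                    a7 = c(p@helixLength + 1, 2 * p@helixLength))
  curved <- applyTransform(gammaSeg, rigidTransform(
    rotationMatrix(c(0, 0, 1), 8), c(1.5, 0, 0)))
  call <- classifyTubulin(gammaSeg, dens, straightRef = gammaSeg,
                          curvedRef = curved,
                          helices = list(gamma = hr, straight = hr,
                                         curved = hr),
                          params = simulationParams(
                            resolution = sc$resolution %||% 3.6),
                          voxelSize = sc$voxel_size %||% 1.2)
  rptPath <- file.path(outDir, "conformation.tsv")
  writeConformationCall(call, rptPath, subunit = "Spc97-gamma")
  rptPath
}
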