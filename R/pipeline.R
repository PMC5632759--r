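## End-to-end orchestration: structures -> surfaces -> features ->
## supported dendrogram -> threshold partition -> network agreement.
##
## One config object carries every stage default; a single seed fans out
## to per-stage seeds by fixed offsets so each stage is independently
## reproducible. Identical inputs + config + seed give byte-identical
## outputs.

.seedOffsets <- c(family = 1L, bootstrap = 2L)

#' Assemble and validate a pipeline configuration
#'
#' @param window surface window `(x_min, x_max, y_min, y_max)`, Angstrom.
#' @param pixelSize,probeRadius,clamp surface raster parameters.
#' @param regionNx,regionNy,excludeRegions region grid parameters.
#' @param channels feature channels (subset of R, G, B, phi, height).
#' @param mode,epsIn,epsOut,ionicStrength,temperature,gridSpacing,gridPadding
#'   electrostatic model parameters (see [electroModel()]).
#' @param nBoot,scales bootstrap parameters (see [msBootstrap()]).
#' @param threshold dendrogram cut height for the reported partition.
#' @param fitSelection,fitAtomNames canonical-orientation fit set
#'   (see [canonicalOrient()]).
#' @param seed master seed.
#' @return validated named list of class `pmhcPipelineConfig`.
#' @export
pipelineConfig <- function(window = c(-16, 16, -10, 10), pixelSize = 0.5,
                           probeRadius = 1.4, clamp = 5,
                           regionNx = 8, regionNy = 4,
                           excludeRegions = integer(),
                           channels = c("R", "G", "B"),
                           mode = "coulomb-dh", epsIn = 4, epsOut = 80,
                           ionicStrength = 0.145, temperature = 298.15,
                           gridSpacing = 1.0, gridPadding = 10,
                           nBoot = 1000, scales = seq(0.5, 1.4, by = 0.1),
                           threshold = NULL, fitSelection = NULL,
                           fitAtomNames = NULL, seed = 1) {
  cfg <- list(window = as.numeric(window), pixelSize = pixelSize,
              probeRadius = probeRadius, clamp = clamp,
              regionNx = as.integer(regionNx), regionNy = as.integer(regionNy),
              excludeRegions = as.integer(excludeRegions),
              channels = channels, mode = mode, epsIn = epsIn,
              epsOut = epsOut, ionicStrength = ionicStrength,
              temperature = temperature, gridSpacing = gridSpacing,
              gridPadding = gridPadding, nBoot = as.integer(nBoot),
              scales = as.numeric(scales), threshold = threshold,
              fitSelection = fitSelection, fitAtomNames = fitAtomNames,
              seed = as.integer(seed))
  ## fail before any computation, with field-level messages
  electroModel(cfg$mode, cfg$epsIn, cfg$epsOut, cfg$ionicStrength,
               cfg$temperature, cfg$gridSpacing, cfg$gridPadding)
  regionGrid(cfg$regionNx, cfg$regionNy, cfg$window, cfg$excludeRegions)
  if (!all(cfg$channels %in% c("R", "G", "B", "phi", "height")))
    stop("config field 'channels' must be a subset of R, G, B, phi, height")
  if (cfg$pixelSize <= 0) stop("config field 'pixelSize' must be > 0")
  if (cfg$nBoot < 100) stop("config field 'nBoot' must be >= 100")
  if (!any(abs(cfg$scales - 1) < 1e-9))
    stop("config field 'scales' must include 1.0")
  if (!is.null(cfg$threshold) && cfg$threshold < 0)
    stop("config field 'threshold' must be >= 0")
  class(cfg) <- "pmhcPipelineConfig"
  cfg
}

.stageLog <- function(stage, t0, seed = NA) {
  message(sprintf("[pMHCsurf] stage=%s wall=%.2fs seed=%s", stage,
                  as.numeric(proc.time()[3] - t0),
                  if (is.na(seed)) "-" else seed))
}

#' Run the full surface-similarity pipeline
#'
#' Canonically orients every structure onto the reference, renders the
#' fixed-orientation surfaces, extracts region features, clusters with
#' multiscale-bootstrap support, optionally cuts at the configured
#' threshold and scores the partition against an observed network. All
#' artefacts are written under `outDir` (surfaces/, features.csv,
#' distances.csv, dendrogram.nwk, edge_report.csv, partition.csv,
#' agreement.json, config.json).
#'
#' @param structures named list of [ChargedStructure-class] with charges
#'   assigned (e.g. from [makeToyFamily()] or [readPDB()] +
#'   [assignCharges()]).
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if missing); `NULL` for no
#'   file output.
#' @param reference canonical reference structure; default: the first.
#' @param network optional [CrossReactivityNetwork-class] for agreement
#'   scoring (labels must match structure labels).
#' @return list with `surfaces`, `features`, `dendrogram`, `partition`
#'   (if a threshold is configured), `agreement` (if a network is given).
#' @export
runPipeline <- function(structures, config = pipelineConfig(),
                        outDir = NULL, reference = NULL, network = NULL) {
  stopifnot(length(structures) >= 3L)
  t0 <- proc.time()[3]
  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  ref <- reference %||% structures[[1]]
  model <- electroModel(config$mode, config$epsIn, config$epsOut,
                        config$ionicStrength, config$temperature,
                        config$gridSpacing, config$gridPadding)
  grid <- regionGrid(config$regionNx, config$regionNy, config$window,
                     config$excludeRegions)

  oriented <- lapply(structures, function(s)
    canonicalOrient(s, ref, config$fitSelection, config$fitAtomNames)$structure)
  .stageLog("orient", t0)

  surfaces <- lapply(oriented, surfaceImage, model = model,
                     window = config$window, pixelSize = config$pixelSize,
                     probeRadius = config$probeRadius, clamp = config$clamp)
  if (!is.null(outDir)) {
    dir.create(file.path(outDir, "surfaces"), showWarnings = FALSE)
    for (s in surfaces)
      writeSurfacePNG(s, file.path(outDir, "surfaces",
                                   paste0(structureLabel(s), ".png")))
  }
  .stageLog("surfaces", t0)

  features <- featureMatrix(surfaces, grid, config$channels)
  d <- correlationDistance(features)
  bootSeed <- config$seed + .seedOffsets[["bootstrap"]]
  dend <- msBootstrap(features, nBoot = config$nBoot,
                      scales = config$scales, seed = bootSeed)
  .stageLog("cluster", t0, bootSeed)

  out <- list(surfaces = surfaces, features = features, dendrogram = dend)
  if (!is.null(config$threshold))
    out$partition <- cutDendrogram(dend, config$threshold)
  if (!is.null(network)) {
    if (is.null(out$partition))
      stop("network scoring needs a configured threshold")
    out$agreement <- evaluatePartition(out$partition, network)
  }

  if (!is.null(outDir)) {
    writeFeaturesCSV(features, file.path(outDir, "features.csv"))
    writeDistanceCSV(d, file.path(outDir, "distances.csv"))
    toNewick(dend, support = TRUE, path = file.path(outDir, "dendrogram.nwk"))
    writeEdgeReportCSV(dend, file.path(outDir, "edge_report.csv"))
    if (!is.null(out$partition))
      utils::write.csv(data.frame(label = names(out$partition),
                                  cluster = out$partition),
                       file.path(outDir, "partition.csv"), row.names = FALSE)
    if (!is.null(out$agreement))
      writeAgreementJSON(out$agreement, file.path(outDir, "agreement.json"))
    cfgOut <- config
    class(cfgOut) <- NULL
    jsonlite::write_json(cfgOut, file.path(outDir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  .stageLog("done", t0, config$seed)
  out
}

#' Command-style wrappers over the pipeline stages
#'
#' Thin re-runnable entry points mirroring the shell tool in
#' `inst/scripts/pmhc-tools.R`. Each validates its inputs before any
#' computation and never mutates them.
#'
#' @param specFile JSON family spec with fields `members` (named charge
#'   vectors), optional `groups`, `spicyPositions` and base-geometry
#'   overrides.
#' @param outDir output directory.
#' @return `cmdSimulate`: the manifest data.frame (PDBs + manifest.csv
#'   written to `outDir`).
#' @export
cmdSimulate <- function(specFile, outDir) {
  spec <- jsonlite::read_json(specFile, simplifyVector = TRUE)
  if (is.null(spec$members)) stop("family spec needs a 'members' field")
  base <- toyGrooveSpec(
    peptideCharges = spec$base$peptideCharges %||%
      rep(0, length(spec$members[[1]])),
    spicyPosition = spec$base$spicyPosition %||% NA,
    label = "base")
  fam <- makeToyFamily(base, as.list(spec$members),
                       spec$groups %||% seq_along(spec$members),
                       spec$spicyPositions)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (s in fam$structures)
    writePDB(s, file.path(outDir, paste0(structureLabel(s), ".pdb")))
  utils::write.csv(fam$manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  invisible(fam$manifest)
}

#' @rdname cmdSimulate
#' @param pdbPath input PDB (toy grooves store charges in the B-factor
#'   column).
#' @param config a [pipelineConfig()].
#' @param reference optional reference structure or PDB path.
#' @export
cmdSurface <- function(pdbPath, outDir, config = pipelineConfig(),
                       reference = NULL) {
  s <- readPDB(pdbPath, chargesFrom = "bfactor")
  if (is.character(reference))
    reference <- readPDB(reference, chargesFrom = "bfactor")
  if (!is.null(reference))
    s <- canonicalOrient(s, reference, config$fitSelection,
                         config$fitAtomNames)$structure
  model <- electroModel(config$mode, config$epsIn, config$epsOut,
                        config$ionicStrength, config$temperature,
                        config$gridSpacing, config$gridPadding)
  surf <- surfaceImage(s, model, config$window, config$pixelSize,
                       config$probeRadius, config$clamp)
  grid <- regionGrid(config$regionNx, config$regionNy, config$window,
                     config$excludeRegions)
  feats <- extractFeatures(surf, grid, config$channels)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeSurfacePNG(surf, file.path(outDir, paste0(structureLabel(s), ".png")))
  writeFeaturesCSV(matrix(feats, dimnames = list(names(feats),
                                                 structureLabel(s))),
                   file.path(outDir, paste0(structureLabel(s),
                                            "_features.csv")))
  invisible(feats)
}

#' @rdname cmdSimulate
#' @param featuresPath features CSV (see [writeFeaturesCSV()]).
#' @export
cmdCluster <- function(featuresPath, outDir, config = pipelineConfig()) {
  features <- readFeaturesCSV(featuresPath)
  dend <- msBootstrap(features, nBoot = config$nBoot,
                      scales = config$scales,
                      seed = config$seed + .seedOffsets[["bootstrap"]])
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  toNewick(dend, TRUE, file.path(outDir, "dendrogram.nwk"))
  writeEdgeReportCSV(dend, file.path(outDir, "edge_report.csv"))
  invisible(dend)
}

#' @rdname cmdSimulate
#' @param partition named cluster vector, or a partition CSV with columns
#'   `label`, `cluster`.
#' @param peptidesPath,edgesPath network input (see [readNetwork()]).
#' @param jsonPath output JSON report path.
#' @export
cmdNetcheck <- function(partition, peptidesPath, edgesPath, jsonPath) {
  if (is.character(partition) && length(partition) == 1L &&
      file.exists(partition)) {
    df <- utils::read.csv(partition, stringsAsFactors = FALSE)
    partition <- stats::setNames(df$cluster, df$label)
  }
  net <- readNetwork(peptidesPath, edgesPath)
  rep <- evaluatePartition(partition, net)
  writeAgreementJSON(rep, jsonPath)
  invisible(rep)
}
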