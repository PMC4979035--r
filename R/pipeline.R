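# Config-driven runs: JSON run configuration, end-to-end MM/PBSA execution
# with a reproducibility manifest, atomic output writing.

#' Read and validate a JSON run configuration
#'
#' Expected fields: `topology` (path), `trajectories` (named list of PDB
#' paths), `chargeSets` (named list of CSV paths), `receptor`/`ligand`
#' (selection expressions), `conditions` (list of `{charge, trajectory}`),
#' optional `snapshots`, `entropySnapshots`, `entropy` (logical),
#' `window`, `seed`, and parameter blocks `pb`, `nonpolar` overriding
#' defaults. All referenced paths must exist.
#'
#' @param path JSON file
#' @return validated config list
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  for (p in c(cfg$topology, unlist(cfg$trajectories), unlist(cfg$chargeSets)))
    if (!file.exists(p)) stop("config references missing path: ", p)
  for (f in c("topology", "trajectories", "chargeSets", "receptor", "ligand",
              "conditions"))
    if (is.null(cfg[[f]])) stop("config lacks required field '", f, "'")
  cfg
}

.configPipeline <- function(cfg) {
  pb <- do.call(pbParams, as.list(cfg$pb))
  np <- do.call(nonpolarParams, as.list(cfg$nonpolar))
  snaps <- cfg$snapshots %||% 200L
  pipelineConfig(snapshots = snaps,
                 entropySnapshots = cfg$entropySnapshots %||% min(20L, snaps),
                 pb = pb, nonpolar = np, seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured MM/PBSA condition matrix end to end
#'
#' Loads topology, trajectories and charge sets, resolves the receptor and
#' ligand selections, runs every configured charge-by-trajectory condition,
#' and writes a decomposition-table CSV, per-snapshot CSVs and a run
#' manifest (input checksums, parameters, seed, package version) into
#' `outDir`. Outputs are staged and moved into place only on success, so a
#' failed run leaves no partial files.
#'
#' @param config path to a JSON run configuration, or the list from
#'   [readRunConfig()]
#' @param outDir output directory (created if needed)
#' @return the decomposition table, invisibly; files as side effect
#' @export
runPipeline <- function(config, outDir) {
  cfg <- if (is.character(config)) readRunConfig(config) else config
  topo <- readTopology(cfg$topology)
  trajs <- lapply(cfg$trajectories, function(p) {
    tr <- readStructure(p)$trajectory
    Trajectory(topo, tr@coords, tr@frameIndex, tr@time)
  })
  css <- mapply(function(p, lab) readChargeSet(p, lab),
                cfg$chargeSets, names(cfg$chargeSets), SIMPLIFY = FALSE)
  registry <- list(chargeSets = css, trajectories = trajs,
                   receptor = atomSelect(topo, cfg$receptor),
                   ligand = atomSelect(topo, cfg$ligand))
  pc <- .configPipeline(cfg)
  conds <- lapply(cfg$conditions, function(cn) condition(cn$charge, cn$trajectory))
  window <- if (!is.null(cfg$window)) as.integer(unlist(cfg$window))
  tab <- runConditionMatrix(conds, registry, pc, window = window,
                            entropy = cfg$entropy %||% TRUE)

  stage <- tempfile("polarbind-stage-")
  dir.create(stage, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(stage, recursive = TRUE))
  utils::write.csv(tab, file.path(stage, "decomposition_table.csv"),
                   row.names = FALSE)
  for (r in attr(tab, "results")) {
    utils::write.csv(r$perSnapshot,
                     file.path(stage, sprintf("snapshots_%s_%s.csv",
                                              r$condition$charge,
                                              r$condition$trajectory)),
                     row.names = FALSE)
  }
  inputs <- c(cfg$topology, unlist(cfg$trajectories), unlist(cfg$chargeSets))
  manifest <- list(
    package = "polarbind",
    version = as.character(utils::packageVersion("polarbind")),
    seed = pc$seed,
    inputs = data.frame(path = inputs, md5 = unname(tools::md5sum(inputs))),
    parameters = list(snapshots = pc$snapshots,
                      entropySnapshots = pc$entropySnapshots,
                      pb = unclass(pc$pb), nonpolar = unclass(pc$nonpolar),
                      entropy = unclass(pc$entropy),
                      criteria = unclass(pc$criteria)),
    conditions = cfg$conditions)
  jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(stage))
    file.copy(file.path(stage, f), file.path(outDir, f), overwrite = TRUE)
  ok <- TRUE
  unlink(stage, recursive = TRUE)
  invisible(tab)
}

#' Write a complete synthetic fixture bundle to disk
#'
#' PDB structure, JSON topology, base/polarized charge CSVs and a jittered
#' trajectory PDB — everything a config-driven run needs.
#'
#' @param kind fixture kind for [makeFixture()]
#' @param dir output directory
#' @param nFrames trajectory length (default 20)
#' @param sigma jitter, Angstrom
#' @param seed RNG seed
#' @param ... passed to [makeFixture()]
#' @return named list of written paths, invisibly
#' @export
writeFixtureBundle <- function(kind, dir, nFrames = 20L, sigma = 0.1,
                               seed = 1L, ...) {
  fx <- makeFixture(kind, ...)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    structure = file.path(dir, paste0(kind, ".pdb")),
    topology = file.path(dir, paste0(kind, "_topology.json")),
    base = file.path(dir, paste0(kind, "_charges_base.csv")),
    polarized = file.path(dir, paste0(kind, "_charges_polarized.csv")),
    trajectory = file.path(dir, paste0(kind, "_traj.pdb")))
  writeStructure(fx$topology, paths$structure)
  writeTopology(fx$topology, paths$topology)
  writeChargeSet(fx$chargeSets$base, paths$base)
  writeChargeSet(fx$chargeSets$polarized, paths$polarized)
  writeStructure(makeTrajectory(fx, nFrames, sigma = sigma, seed = seed),
                 paths$trajectory)
  invisible(paths)
}
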