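#' Write an agent table
#'
#' CSV with the fixed columns id, species, state, x, y, z, biomass_fg,
#' capsule_fg, radius_um.
#'
#' @param state a \linkS4class{BiofilmState}.
#' @param path output file.
#' @export
writeAgentTable <- function(state, path) {
  utils::write.csv(state@agents[, .AGENT_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Read an agent table written by \code{\link{writeAgentTable}}
#' @param path CSV file.
#' @return data.frame with the agent table columns.
#' @export
readAgentTable <- function(path) {
  ag <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(.AGENT_COLUMNS %in% names(ag)))
  ag
}

#' Write a solute field as a plain dense array file
#'
#' A small header (field name, shape, voxel size, time, diffusivity, bulk)
#' in comment lines, then one concentration per line in column-major
#' order.
#'
#' @param field a \linkS4class{SoluteField}.
#' @param grid the \linkS4class{DomainGrid}.
#' @param time snapshot time (h).
#' @param path output file.
#' @export
writeFieldArray <- function(field, grid, time, path) {
  d <- dim(field@conc)
  hdr <- c(sprintf("# field: %s", field@name),
           sprintf("# shape: %d %d %d", d[1], d[2], d[3]),
           sprintf("# voxel_size: %g", grid@voxelSize),
           sprintf("# time: %g", time),
           sprintf("# diffusivity: %g", field@diffusivity),
           sprintf("# bulk: %g %s", field@bulkConcentration,
                   if (field@bulkMaintained) "maintained" else "accumulating"))
  writeLines(c(hdr, format(as.numeric(field@conc), digits = 17,
                           scientific = TRUE, trim = TRUE)), path)
  invisible(path)
}

#' Read a solute field array file
#' @param path file written by \code{\link{writeFieldArray}}.
#' @return a \code{list(field = SoluteField-like data, name, shape,
#'   voxel_size, time, conc)}.
#' @export
readFieldArray <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) sub(paste0("^# ", key, ": "), "",
                            grep(paste0("^# ", key, ":"), hdr, value = TRUE))
  shape <- as.integer(strsplit(getv("shape"), " ")[[1]])
  conc <- as.numeric(lines[!grepl("^#", lines)])
  list(name = getv("field"), shape = shape,
       voxel_size = as.numeric(getv("voxel_size")),
       time = as.numeric(getv("time")),
       conc = array(conc, dim = shape))
}

#' Serialize a trajectory to a directory
#'
#' One agent CSV and one array file per solute field per snapshot, plus a
#' \code{manifest.csv} listing timepoints and file names and a
#' \code{config.yaml} with the run configuration.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeTrajectory <- function(traj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(traj@times), function(i) {
    st <- traj@states[[i]]
    tlab <- sprintf("%07.3f", traj@times[i])
    af <- sprintf("agents_t%s.csv", tlab)
    writeAgentTable(st, file.path(dir, af))
    ff <- vapply(names(st@fields), function(nm) {
      fn <- sprintf("field_%s_t%s.txt", nm, tlab)
      writeFieldArray(st@fields[[nm]], st@grid, traj@times[i],
                      file.path(dir, fn))
      fn
    }, character(1))
    data.frame(time_h = traj@times[i], agents_file = af,
               field_files = paste(ff, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  manifest$seed <- traj@seed
  manifest$digest <- traj@digest
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  writeRunConfig(traj@config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read back the snapshots of a serialized trajectory
#'
#' Returns the manifest with agent tables attached; full
#' \linkS4class{BiofilmState} reconstruction needs the grid/variant from
#' the stored config, which is also read.
#'
#' @param dir directory written by \code{\link{writeTrajectory}}.
#' @return list with \code{manifest} (data.frame), \code{agents} (list of
#'   data.frames, one per timepoint) and \code{config}
#'   (\linkS4class{RunConfig}).
#' @export
readTrajectory <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  ags <- lapply(manifest$agents_file,
                function(f) readAgentTable(file.path(dir, f)))
  cfg <- readRunConfig(file.path(dir, "config.yaml"))
  list(manifest = manifest, agents = ags, config = cfg)
}

.speciesToList <- function(p) {
  sl <- c("name", "muMax", "KSg", "KSo", "KI", "yieldGlucose", "yieldOxygen",
          "biomassFraction", "capsuleFraction", "productionRateK",
          "yieldInhibitor", "yieldSurfactant", "surfactantTolerance",
          "rhoBiomass", "rhoCapsule")
  out <- lapply(sl, function(s) slot(p, s))
  names(out) <- sl
  out
}

#' Write a run configuration as YAML
#'
#' @param config a \linkS4class{RunConfig}.
#' @param path output file.
#' @export
writeRunConfig <- function(config, path) {
  doc <- list(
    variant = config@variant,
    species = lapply(config@species, .speciesToList),
    seed_counts = as.list(config@seedCounts),
    bulk = as.list(config@bulk),
    duration = config@duration, dt = config@dt,
    output_interval = config@outputInterval,
    seed = config@baseSeed, replicates = config@replicates,
    grid = list(side = c(config@grid@sideX, config@grid@sideY,
                         config@grid@sideZ),
                voxel_size = config@grid@voxelSize,
                boundary_layer = config@grid@boundaryLayer),
    settings = config@settings)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' Accepts documents written by \code{\link{writeRunConfig}}; missing
#' entries fall back to the package defaults, and species entries may give
#' only the fields that differ from \code{speciesParams} defaults.
#'
#' @param path YAML file.
#' @return a \linkS4class{RunConfig}.
#' @export
readRunConfig <- function(path) {
  doc <- yaml::read_yaml(path)
  species <- if (is.null(doc$species)) defaultSpecies() else
    lapply(doc$species, function(sp) {
      sp <- lapply(sp, function(v) if (is.null(v)) NA_real_ else v)
      do.call(speciesParams, sp)
    })
  if (is.null(names(species)) || any(names(species) == ""))
    names(species) <- vapply(species, function(p) p@name, character(1))
  grid <- if (is.null(doc$grid)) domainGrid() else
    domainGrid(side = unlist(doc$grid$side),
               voxelSize = doc$grid$voxel_size %||% 8,
               boundaryLayer = doc$grid$boundary_layer %||% 40)
  runConfig(
    variant = doc$variant %||% "COMPETITION", species = species,
    seedCounts = if (is.null(doc$seed_counts)) NULL else
      unlist(doc$seed_counts),
    bulk = if (is.null(doc$bulk)) NULL else unlist(doc$bulk),
    duration = doc$duration %||% 16, dt = doc$dt %||% 0.05,
    outputInterval = doc$output_interval %||% 1, seed = doc$seed %||% 1,
    grid = grid, replicates = doc$replicates %||% 5,
    settings = doc$settings %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a tidy replicate summary CSV
#'
#' Long-format CSV with columns run_id, time_h, species, state,
#' biovolume_um3, count, thickness_um, suitable for external statistics
#' tools.
#'
#' @param trajs list of \linkS4class{Trajectory}.
#' @param path output CSV.
#' @return the summary data.frame, invisibly.
#' @export
writeSummaryCSV <- function(trajs, path) {
  s <- summarizeReplicates(trajs)
  utils::write.csv(s, path, row.names = FALSE)
  invisible(s)
}
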