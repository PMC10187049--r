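.defaultBulk <- c(glucose = 2, oxygen = 0.0064, substrate1 = 2,
                  substrate2 = 2, inhibitor = 0, surfactant = 0)

.defaultSettings <- function() {
  list(solver = solverSettings(), division = divisionSettings(),
       shove = shoveSettings(), stepLength = 5, planktonicGrowth = FALSE,
       erosionRate = 0, deathRate = 0, diffusivity = list())
}

# Deep-merge user settings over the defaults.
.mergeSettings <- function(user) {
  utils::modifyList(.defaultSettings(), if (is.null(user)) list() else user)
}

#' Build a run configuration
#'
#' Defaults reproduce the standard study conditions: a 136 x 136 x 136 um
#' domain, a dual-species biofilm seeded with 88 S. oralis + 88
#' L. paracasei cells (176 total; single-species runs seed all 176 of one
#' species), 2 g/L glucose and 0.0064 g/L oxygen in the bulk, and 16 h of
#' growth at a 0.05 h global step.
#'
#' @param variant one of \code{modelVariants()} (default COMPETITION).
#' @param species named list of \linkS4class{SpeciesParams}
#'   (default \code{defaultSpecies()}).
#' @param seedCounts named initial cell counts per species; default 88 of
#'   each listed species if two, 176 if one.
#' @param bulk named bulk concentrations (g/L); defaults glucose 2,
#'   oxygen 0.0064, substrate1/2 2, secreted solutes 0.
#' @param duration run length (h), default 16.
#' @param dt global time step (h), default 0.05.
#' @param outputInterval snapshot interval (h), default 1.
#' @param seed base RNG seed; replicate i uses seed + i - 1.
#' @param grid a \linkS4class{DomainGrid}.
#' @param replicates default replicate count for \code{runReplicates}.
#' @param settings overrides merged over the defaults: \code{solver},
#'   \code{division}, \code{shove} setting lists, \code{stepLength} (um,
#'   planktonic random step), \code{planktonicGrowth} (logical, default
#'   FALSE: planktonic cells are metabolically inert), \code{erosionRate}
#'   and \code{deathRate} (1/h, both 0 = off), \code{diffusivity} (named
#'   per-solute overrides, um^2/h).
#' @return a \linkS4class{RunConfig}.
#' @examples
#' cfg <- runConfig("COMPETITION", duration = 1)
#' cfg
#' @export
runConfig <- function(variant = "COMPETITION", species = defaultSpecies(),
                      seedCounts = NULL, bulk = NULL, duration = 16,
                      dt = 0.05, outputInterval = 1, seed = 1,
                      grid = domainGrid(), replicates = 5,
                      settings = list()) {
  variant <- match.arg(variant, .MODEL_VARIANTS)
  if (is.null(seedCounts)) {
    seedCounts <- if (length(species) == 2)
      stats::setNames(c(88, 88), names(species))
    else stats::setNames(176, names(species)[1])
  }
  b <- .defaultBulk
  if (!is.null(bulk)) b[names(bulk)] <- bulk
  new("RunConfig", variant = variant, species = species,
      seedCounts = seedCounts, bulk = b, duration = duration, dt = dt,
      outputInterval = outputInterval, baseSeed = seed, grid = grid,
      replicates = replicates, settings = .mergeSettings(settings))
}

#' Single-species run configuration
#'
#' Convenience wrapper: the default 176-cell inoculum of one species.
#'
#' @param speciesName which species to seed (a name in \code{species}).
#' @param species named list of \linkS4class{SpeciesParams}; the full list
#'   is kept registered so variant wiring is unchanged.
#' @param ... passed to \code{\link{runConfig}}.
#' @return a \linkS4class{RunConfig}.
#' @export
singleSpeciesConfig <- function(speciesName = "S.oralis",
                                species = defaultSpecies(), ...) {
  runConfig(species = species,
            seedCounts = stats::setNames(176, speciesName), ...)
}

# Division-threshold biomass (fg): all-biomass sphere at the division radius.
.divisionBiomass <- function(params, settings) {
  params@rhoBiomass * 4 / 3 * pi * settings$radius^3
}

#' Seed the initial biofilm
#'
#' Places the configured number of cells of each species at uniformly
#' random (x, y) on the substratum, resting on it (z = radius), all
#' BIOFILM, with species interleaved at random and birth biomass drawn
#' uniformly between 50\% and 100\% of the division biomass (capsule mass
#' 0). One shove relaxation resolves initial overlaps; if the requested
#' density cannot be relaxed below tolerance an error is raised. Consumes
#' the R RNG stream; callers wanting reproducibility set the seed first
#' (\code{runSimulation} does).
#'
#' @param config a \linkS4class{RunConfig}.
#' @return a \linkS4class{BiofilmState} at time 0.
#' @examples
#' set.seed(1)
#' st <- seedBiofilm(runConfig())
#' nrow(agents(st))
#' @export
seedBiofilm <- function(config) {
  set <- config@settings
  counts <- config@seedCounts
  n <- sum(counts)
  sp <- if (n > 0) sample(rep(names(counts), counts)) else character()
  div <- vapply(config@species, .divisionBiomass, numeric(1),
                settings = set$division)[sp]
  biomass <- if (n > 0) runif(n, 0.5, 1) * div else numeric()
  rho_b <- vapply(config@species, function(p) p@rhoBiomass, numeric(1))[sp]
  rho_c <- vapply(config@species, function(p) p@rhoCapsule, numeric(1))[sp]
  r <- agentRadius(biomass, 0, rho_b, rho_c)
  ag <- data.frame(
    id = seq_len(n), species = sp, state = rep("BIOFILM", n),
    x = runif(n, 0, config@grid@sideX), y = runif(n, 0, config@grid@sideY),
    z = r, biomass_fg = as.numeric(biomass), capsule_fg = rep(0, n),
    radius_um = r, stringsAsFactors = FALSE)
  if (n > 1) {
    ag <- withCallingHandlers(
      shoveRelax(ag, config@grid, set$shove),
      warning = function(w) {
        stop("seeding density unachievable: ", conditionMessage(w))
      })
  }
  fieldNames <- .variantFieldNames(names(config@species), config@variant)
  fields <- lapply(fieldNames, function(nm) {
    D <- set$diffusivity[[nm]]
    if (is.null(D)) D <- defaultDiffusivity(nm)
    soluteField(nm, config@grid, bulk = unname(config@bulk[nm]),
                diffusivity = D)
  })
  names(fields) <- fieldNames
  new("BiofilmState", time = 0, agents = ag, fields = fields,
      grid = config@grid, variant = config@variant,
      seed = config@baseSeed)
}

# Per-voxel biomass totals (fg) for a subset of agents.
.voxelBiomass <- function(ag, idx, grid, nvox) {
  b <- numeric(nvox)
  if (length(idx)) {
    v <- voxelIndexOf(grid, ag$x[idx], ag$y[idx], ag$z[idx])
    t <- rowsum(ag$biomass_fg[idx], v)
    b[as.integer(rownames(t))] <- t[, 1]
  }
  b
}

# Indices of agents that metabolize (grow/consume/produce).
.metabolicIdx <- function(state, set) {
  if (isTRUE(set$planktonicGrowth)) seq_len(nrow(state@agents))
  else which(state@agents$state == "BIOFILM")
}

# The per-voxel non-carbon Monod factors of one species (oxygen term and,
# if active, the inhibition term), as flat vectors over voxels.
.otherFactor <- function(state, params, fl, exclude = "carbon") {
  d <- gridDims(state@grid)
  out <- rep(1, prod(d))
  if (exclude != "oxygen") {
    So <- as.numeric(state@fields[["oxygen"]]@conc)
    out <- out * So / (params@KSo + So)
  }
  if (fl$inhibition_active && !is.na(params@KI)) {
    I <- as.numeric(state@fields[["inhibitor"]]@conc)
    out <- out * inhibitionFactor(I, params@KI)
  }
  out
}

# Solve the coupled nutrient fields at pseudo-steady state for the current
# biomass distribution, Picard-iterating between fields.
.solveNutrients <- function(state, config) {
  set <- config@settings
  fl <- variantFlags(state@variant)
  grid <- state@grid
  nvox <- prod(gridDims(grid))
  Vvox <- voxelVolume(grid)
  carbon <- .speciesCarbon(names(config@species), state@variant)
  idx <- .metabolicIdx(state, set)
  B <- lapply(names(config@species), function(s)
    .voxelBiomass(state@agents, idx[state@agents$species[idx] == s],
                  grid, nvox))
  names(B) <- names(config@species)
  mask <- .bulkMask(grid, biofilmFront(state))
  for (pass in seq_len(set$solver$outerPasses)) {
    for (cf in unique(carbon)) {
      users <- names(carbon)[carbon == cf]
      groups <- lapply(users, function(s) {
        p <- config@species[[s]]
        list(vmax = p@yieldGlucose * p@muMax *
               .otherFactor(state, p, fl) * B[[s]] / Vvox,
             K = p@KSg)
      })
      state@fields[[cf]] <- solveSteady(state@fields[[cf]], grid, groups,
                                        bulkMask = mask,
                                        settings = set$solver)
    }
    groups <- lapply(names(config@species), function(s) {
      p <- config@species[[s]]
      Sg <- as.numeric(state@fields[[carbon[s]]]@conc)
      fI <- .otherFactor(state, p, fl, exclude = "oxygen")
      list(vmax = p@yieldOxygen * p@muMax * Sg / (p@KSg + Sg) * fI *
             B[[s]] / Vvox,
           K = p@KSo)
    })
    state@fields[["oxygen"]] <- solveSteady(state@fields[["oxygen"]], grid,
                                            groups, bulkMask = mask,
                                            settings = set$solver)
  }
  state
}

# Advance the secreted accumulating solutes by dt with first-order
# production from (biofilm) producer biomass.
.stepSecreted <- function(state, config, dt) {
  fl <- variantFlags(state@variant)
  grid <- state@grid
  nvox <- prod(gridDims(grid))
  Vvox <- voxelVolume(grid)
  idx <- which(state@agents$state == "BIOFILM")
  for (nm in c("inhibitor", "surfactant")) {
    if (is.null(state@fields[[nm]])) next
    src <- numeric(nvox)
    for (s in names(config@species)) {
      p <- config@species[[s]]
      y <- if (nm == "inhibitor") p@yieldInhibitor else p@yieldSurfactant
      if (is.na(y) || is.na(p@productionRateK)) next
      B <- .voxelBiomass(state@agents,
                         idx[state@agents$species[idx] == s], grid, nvox)
      src <- src + y * p@productionRateK * B / Vvox
    }
    state@fields[[nm]] <- stepTransient(state@fields[[nm]], grid,
                                        array(src, gridDims(grid)), dt,
                                        config@settings$solver)
  }
  state
}

# Grow all metabolizing agents over dt with rates frozen at step start.
.growAgents <- function(state, config, dt) {
  fl <- variantFlags(state@variant)
  set <- config@settings
  ag <- state@agents
  idx <- .metabolicIdx(state, set)
  if (!length(idx)) return(state)
  carbon <- .speciesCarbon(names(config@species), state@variant)
  vox <- voxelIndexOf(state@grid, ag$x[idx], ag$y[idx], ag$z[idx])
  So <- as.numeric(state@fields[["oxygen"]]@conc)[vox]
  I <- if (fl$inhibition_active)
    as.numeric(state@fields[["inhibitor"]]@conc)[vox] else NULL
  for (s in unique(ag$species[idx])) {
    p <- config@species[[s]]
    sel <- ag$species[idx] == s
    Sg <- as.numeric(state@fields[[carbon[s]]]@conc)[vox[sel]]
    mu <- monodMu(p, Sg, So[sel])
    if (fl$inhibition_active && !is.na(p@KI))
      mu <- mu * inhibitionFactor(I[sel], p@KI)
    up <- biomassStep(ag$biomass_fg[idx[sel]], ag$capsule_fg[idx[sel]],
                      mu, dt, p, epsActive = fl$eps_active)
    ag$biomass_fg[idx[sel]] <- up$biomass_fg
    ag$capsule_fg[idx[sel]] <- up$capsule_fg
    ag$radius_um[idx[sel]] <- up$radius_um
  }
  state@agents <- ag
  state
}

# Optional first-order processes, both off by default: random cell death
# (agents removed at rate deathRate) and height-weighted surface erosion
# (periphery agents detach at rate erosionRate * height fraction).
.optionalProcesses <- function(state, config, dt) {
  set <- config@settings
  if (set$deathRate > 0) {
    ag <- state@agents
    keep <- runif(nrow(ag)) >= set$deathRate * dt
    state@agents <- ag[keep, ]
  }
  if (set$erosionRate > 0) {
    front <- biofilmFront(state)
    if (front > 0) {
      periph <- peripheryAgents(state)
      ag <- state@agents
      idx <- match(periph, ag$id)
      p <- pmin(1, set$erosionRate * dt * (ag$z[idx] / front))
      going <- idx[runif(length(idx)) < p]
      if (length(going)) {
        band <- .planktonicBand(state@grid, front)
        ag$state[going] <- "PLANKTONIC"
        ag$z[going] <- runif(length(going), band[1], band[2])
        state@agents <- ag
      }
    }
  }
  state
}

#' Advance a state by one global time step
#'
#' Executes the per-step rules in fixed order: (1) pseudo-steady solve of
#' the nutrient fields at the current biomass, (2) transient step of the
#' secreted inhibitor/surfactant with first-order production, (3) growth of
#' every metabolizing agent with rates frozen at the step start, (4) cell
#' divisions, (5) shove relaxation, (6) surfactant detachment of periphery
#' cells (surfactant variants), (7) random planktonic movement, (8) time
#' advance. Deterministic given the state, config and R RNG position.
#'
#' @param state a \linkS4class{BiofilmState}.
#' @param config the \linkS4class{RunConfig}.
#' @return the state at time + dt.
#' @export
simStep <- function(state, config) {
  dt <- config@dt
  fl <- variantFlags(state@variant)
  set <- config@settings
  state <- .solveNutrients(state, config)
  state <- .stepSecreted(state, config, dt)
  state <- .growAgents(state, config, dt)
  state@agents <- .divideAgents(state@agents, config@species, set$division)
  state@agents <- shoveRelax(state@agents, state@grid, set$shove)
  state <- .optionalProcesses(state, config, dt)
  if (fl$surfactant_active)
    state <- surfactantDetach(state, config@species)
  state <- planktonicMove(state, set$stepLength)
  state@time <- state@time + dt
  state
}

.configDigest <- function(config, seed) {
  sprintf("%s|seed=%d|cells=%s|dur=%gh|dt=%g|vox=%g",
          config@variant, as.integer(seed),
          paste(names(config@seedCounts), config@seedCounts,
                sep = ":", collapse = ","),
          config@duration, config@dt, config@grid@voxelSize)
}

#' Run one simulation
#'
#' Seeds the RNG, seeds the biofilm, steps to the configured duration, and
#' snapshots the state at time 0, at every output interval and at the end.
#'
#' @param config a \linkS4class{RunConfig}.
#' @param seed RNG seed for this run (default the config's base seed).
#' @param verbose print progress each snapshot.
#' @return a \linkS4class{Trajectory}.
#' @examples
#' \donttest{
#' cfg <- runConfig(duration = 2)
#' tr <- runSimulation(cfg, seed = 1)
#' biovolume(finalState(tr))
#' }
#' @export
runSimulation <- function(config, seed = config@baseSeed, verbose = FALSE) {
  set.seed(as.integer(seed))
  state <- seedBiofilm(config)
  state@seed <- as.numeric(seed)
  nsteps <- round(config@duration / config@dt)
  every <- max(1L, round(config@outputInterval / config@dt))
  times <- state@time
  states <- list(state)
  for (i in seq_len(nsteps)) {
    state <- simStep(state, config)
    if (i %% every == 0 || i == nsteps) {
      times <- c(times, state@time)
      states <- c(states, list(state))
      if (verbose)
        message(sprintf("t = %5.2f h: %d agents (%d biofilm)", state@time,
                        nrow(state@agents),
                        sum(state@agents$state == "BIOFILM")))
    }
  }
  new("Trajectory", times = times, states = states, seed = as.numeric(seed),
      config = config, digest = .configDigest(config, seed))
}

#' Run a batch of replicate simulations
#'
#' Replicate i runs with seed \code{baseSeed + i - 1}; trajectories are
#' otherwise identical in configuration. Replicate counts follow the study
#' design: 5 for the competition and inhibition models, 50 for the
#' surfactant-containing models (both configurable), chosen to bring the
#' coefficient of variation of the replicate biovolumes under 10\%.
#'
#' @param config a \linkS4class{RunConfig}.
#' @param replicates number of replicates (default from the config).
#' @param baseSeed base seed (default from the config).
#' @param verbose print per-replicate progress.
#' @return list of \linkS4class{Trajectory}.
#' @export
runReplicates <- function(config, replicates = config@replicates,
                          baseSeed = config@baseSeed, verbose = FALSE) {
  stopifnot(replicates >= 1)
  lapply(seq_len(replicates), function(i) {
    if (verbose) message("replicate ", i, "/", replicates)
    runSimulation(config, seed = baseSeed + i - 1)
  })
}

#' Final state of a trajectory
#' @param traj a \linkS4class{Trajectory}.
#' @return the last \linkS4class{BiofilmState}.
#' @export
finalState <- function(traj) traj@states[[length(traj@states)]]

#' Nutrient consumption bookkeeping
#'
#' Two independent views of the instantaneous nutrient consumption implied
#' by a state, for mass-balance checks: \code{fieldSinks} integrates the
#' Monod sink terms over voxels at the solved concentrations (g/h per
#' field), and \code{agentDemand} sums |yield| * mu * X over agents per
#' species and field. At pseudo-steady state the two agree to solver
#' tolerance.
#'
#' @param state a \linkS4class{BiofilmState} whose nutrient fields are
#'   solved (i.e. after \code{simStep}/\code{.solveNutrients}).
#' @param config the \linkS4class{RunConfig}.
#' @return list with data.frames \code{fieldSinks} and \code{agentDemand}.
#' @export
nutrientBalance <- function(state, config) {
  fl <- variantFlags(state@variant)
  grid <- state@grid
  nvox <- prod(gridDims(grid))
  Vvox <- voxelVolume(grid)
  carbon <- .speciesCarbon(names(config@species), state@variant)
  idx <- .metabolicIdx(state, config@settings)
  ag <- state@agents
  sinks <- list(); demand <- list()
  for (s in names(config@species)) {
    p <- config@species[[s]]
    sidx <- idx[ag$species[idx] == s]
    B <- .voxelBiomass(ag, sidx, grid, nvox)
    Sg <- as.numeric(state@fields[[carbon[s]]]@conc)
    fOther <- .otherFactor(state, p, fl)
    # field view: sink integral, fg/h -> g/h
    gl <- sum(abs(p@yieldGlucose) * p@muMax * fOther * B *
                Sg / (p@KSg + Sg)) * 1e-15
    So <- as.numeric(state@fields[["oxygen"]]@conc)
    fI <- .otherFactor(state, p, fl, exclude = "oxygen")
    ox <- sum(abs(p@yieldOxygen) * p@muMax * Sg / (p@KSg + Sg) * fI * B *
                So / (p@KSo + So)) * 1e-15
    sinks[[s]] <- data.frame(species = s, field = c(carbon[s], "oxygen"),
                             g_per_h = c(gl, ox))
    # agent view
    if (length(sidx)) {
      vox <- voxelIndexOf(grid, ag$x[sidx], ag$y[sidx], ag$z[sidx])
      sol <- list(oxygen = So[vox], inhibitor = if (fl$inhibition_active)
        as.numeric(state@fields[["inhibitor"]]@conc)[vox] else NULL)
      sol[[carbon[s]]] <- Sg[vox]
      mu <- effectiveMu(p, sol, state@variant, carbon = carbon[s])
      X <- ag$biomass_fg[sidx]
      demand[[s]] <- data.frame(
        species = s, field = c(carbon[s], "oxygen"),
        g_per_h = c(sum(abs(p@yieldGlucose) * mu * X),
                    sum(abs(p@yieldOxygen) * mu * X)) * 1e-15)
    } else {
      demand[[s]] <- data.frame(species = s, field = c(carbon[s], "oxygen"),
                                g_per_h = 0)
    }
  }
  list(fieldSinks = do.call(rbind, sinks),
       agentDemand = do.call(rbind, demand))
}

#' @describeIn BiofilmState-class display
#' @param object a BiofilmState
#' @export
setMethod("show", "BiofilmState", function(object) {
  ag <- object@agents
  cat(sprintf("BiofilmState (%s) at t = %.2f h\n", object@variant,
              object@time))
  cat(sprintf("  %d agents (%d biofilm, %d planktonic); fields: %s\n",
              nrow(ag), sum(ag$state == "BIOFILM"),
              sum(ag$state == "PLANKTONIC"),
              paste(names(object@fields), collapse = ", ")))
  invisible(NULL)
})

#' @describeIn RunConfig-class display
#' @param object a RunConfig
#' @export
setMethod("show", "RunConfig", function(object) {
  cat(sprintf("RunConfig: %s, %g h at dt = %g h, seed %d\n", object@variant,
              object@duration, object@dt, as.integer(object@baseSeed)))
  cat(sprintf("  seeding: %s\n",
              paste(names(object@seedCounts), object@seedCounts,
                    sep = " x ", collapse = ", ")))
  cat(sprintf("  bulk: glucose %g, oxygen %g g/L; %d replicates\n",
              object@bulk["glucose"], object@bulk["oxygen"],
              as.integer(object@replicates)))
  invisible(NULL)
})

#' @describeIn Trajectory-class display
#' @param object a Trajectory
#' @export
setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %s; %d snapshots over %g h\n", object@digest,
              length(object@times), max(object@times)))
  invisible(NULL)
})

#' @describeIn BiofilmState-class agent table accessor
#' @param x a BiofilmState
#' @export
setMethod("agents", "BiofilmState", function(x) x@agents)

#' @describeIn BiofilmState-class simulation time accessor
#' @export
setMethod("simTime", "BiofilmState", function(x) x@time)

#' @describeIn Trajectory-class snapshot times accessor
#' @param x a Trajectory
#' @export
setMethod("simTime", "Trajectory", function(x) x@times)

#' @describeIn BiofilmState-class solute field list accessor
#' @export
setMethod("soluteFields", "BiofilmState", function(x) x@fields)
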