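# Small programmatic fixtures shared across the suite. Everything is built
# in code; no data files.

tinyGrid <- function(side = 64, voxelSize = 8, boundaryLayer = 24) {
  domainGrid(side = side, voxelSize = voxelSize, boundaryLayer = boundaryLayer)
}

# A scaled-down run configuration for fast engine tests: smaller domain and
# inoculum, short duration; kinetics and step size unchanged.
tinyConfig <- function(variant = "COMPETITION", duration = 1, nPerSpecies = 20,
                       seed = 42, ...) {
  sp <- defaultSpecies()
  runConfig(variant, species = sp,
            seedCounts = setNames(rep(nPerSpecies, 2), names(sp)),
            duration = duration, seed = seed, grid = tinyGrid(), ...)
}

# One agent-table row. Radius is derived from the masses.
agentRow <- function(id, species = "S.oralis", state = "BIOFILM",
                     x = 10, y = 10, z = NULL, biomass = 400, capsule = 0,
                     rhoB = 150, rhoC = 75) {
  r <- agentRadius(biomass, capsule, rhoB, rhoC)
  data.frame(id = as.integer(id), species = species, state = state,
             x = x, y = y, z = if (is.null(z)) r else z,
             biomass_fg = biomass, capsule_fg = capsule, radius_um = r,
             stringsAsFactors = FALSE)
}

# Assemble a BiofilmState around a hand-built agent table.
stateWith <- function(agents, grid = tinyGrid(), variant = "COMPETITION",
                      bulk = c(glucose = 2, oxygen = 0.0064),
                      extraFields = character()) {
  fieldNames <- unique(c("glucose", "oxygen", extraFields))
  fields <- lapply(fieldNames, function(nm)
    soluteField(nm, grid, bulk = if (nm %in% names(bulk)) bulk[[nm]] else 0))
  names(fields) <- fieldNames
  new("BiofilmState", time = 0, agents = agents, fields = fields,
      grid = grid, variant = variant, seed = 0)
}

finalBiovolumes <- function(trajs, species) {
  vapply(trajs, function(tr) biovolume(finalState(tr), species = species),
         numeric(1))
}
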