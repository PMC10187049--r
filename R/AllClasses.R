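#' @useDynLib biofilmIBM, .registration = TRUE
#' @import methods
#' @importFrom Rcpp evalCpp
#' @importFrom stats lm coef runif rnorm rlnorm sd setNames var
#' @importFrom utils read.csv write.csv head
NULL

.AGENT_COLUMNS <- c("id", "species", "state", "x", "y", "z",
                    "biomass_fg", "capsule_fg", "radius_um")

.MODEL_VARIANTS <- c("COMPETITION", "INDEPENDENT_SUBSTRATES", "INHIBITION",
                     "SURFACTANT", "INHIBITION_SURFACTANT")

.SOLUTE_NAMES <- c("glucose", "oxygen", "substrate1", "substrate2",
                   "inhibitor", "surfactant")

#' Rectangular simulation domain
#'
#' Continuous coordinates are in micrometres with the origin at a corner of
#' the substratum (z = 0). The domain is discretized into cubic voxels of
#' side \code{voxelSize}; lateral faces are periodic, the substratum is a
#' zero-flux wall, and the top connects to the well-mixed bulk through a
#' boundary layer of thickness \code{boundaryLayer} above the biofilm front.
#'
#' @slot sideX,sideY,sideZ domain edge lengths (um); default 136 each.
#' @slot voxelSize voxel edge (um); each side must be a multiple of it.
#' @slot boundaryLayer boundary-layer thickness (um).
#' @name DomainGrid-class
#' @rdname DomainGrid-class
#' @exportClass DomainGrid
setClass("DomainGrid",
  representation(sideX = "numeric", sideY = "numeric", sideZ = "numeric",
                 voxelSize = "numeric", boundaryLayer = "numeric"),
  validity = function(object) {
    msg <- character()
    h <- object@voxelSize
    if (!isTRUE(h > 0)) msg <- c(msg, "voxelSize must be > 0")
    for (s in c(object@sideX, object@sideY, object@sideZ)) {
      if (!isTRUE(s > 0)) msg <- c(msg, "domain sides must be > 0")
      else if (abs(s / h - round(s / h)) > 1e-9)
        msg <- c(msg, "each side must be an integer multiple of voxelSize")
    }
    if (!isTRUE(object@boundaryLayer >= 0) ||
        !isTRUE(object@boundaryLayer < object@sideZ))
      msg <- c(msg, "boundaryLayer must lie in [0, sideZ)")
    if (length(msg)) msg else TRUE
  })

#' Per-species growth and production parameters
#'
#' Holds the kinetic constants of one species: maximum specific growth rate,
#' glucose and oxygen half-saturation constants, the optional noncompetitive
#' inhibition constant (S. oralis only), solute yields (negative = consumed
#' per unit new biomass), the biomass:capsule split of produced mass, the
#' first-order production rate and yields for the secreted inhibitor and
#' surfactant (L. paracasei only), the surfactant tolerance threshold, and
#' the mass densities used to convert cell mass to volume.
#'
#' Absent parameters are \code{NA}.
#'
#' @name SpeciesParams-class
#' @rdname SpeciesParams-class
#' @exportClass SpeciesParams
setClass("SpeciesParams",
  representation(name = "character", muMax = "numeric", KSg = "numeric",
                 KSo = "numeric", KI = "numeric",
                 yieldGlucose = "numeric", yieldOxygen = "numeric",
                 biomassFraction = "numeric", capsuleFraction = "numeric",
                 productionRateK = "numeric", yieldInhibitor = "numeric",
                 yieldSurfactant = "numeric", surfactantTolerance = "numeric",
                 rhoBiomass = "numeric", rhoCapsule = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!isTRUE(object@muMax > 0)) msg <- c(msg, "muMax must be > 0")
    if (!isTRUE(object@KSg > 0)) msg <- c(msg, "KSg must be > 0")
    if (!isTRUE(object@KSo > 0)) msg <- c(msg, "KSo must be > 0")
    if (!is.na(object@KI) && !isTRUE(object@KI > 0))
      msg <- c(msg, "KI must be > 0 when present")
    if (abs(object@biomassFraction + object@capsuleFraction - 1) > 1e-9)
      msg <- c(msg, "biomassFraction + capsuleFraction must equal 1")
    for (nm in c("yieldInhibitor", "yieldSurfactant", "surfactantTolerance",
                 "productionRateK")) {
      v <- slot(object, nm)
      if (!is.na(v) && v < 0) msg <- c(msg, paste(nm, "must be >= 0"))
    }
    if (!isTRUE(object@rhoBiomass > 0) || !isTRUE(object@rhoCapsule > 0))
      msg <- c(msg, "densities must be > 0")
    if (length(msg)) msg else TRUE
  })

#' One dissolved chemical on the voxel grid
#'
#' @slot name one of glucose, oxygen, substrate1, substrate2, inhibitor,
#'   surfactant.
#' @slot conc 3D array of concentrations (g/L; numerically equal to
#'   fg/um^3) with dimensions matching the grid voxel counts.
#' @slot diffusivity um^2/h.
#' @slot bulkConcentration g/L, the concentration maintained in the bulk.
#' @slot bulkMaintained TRUE for nutrients solved at pseudo-steady state
#'   against a constant bulk; FALSE for secreted solutes that accumulate.
#' @name SoluteField-class
#' @rdname SoluteField-class
#' @exportClass SoluteField
setClass("SoluteField",
  representation(name = "character", conc = "array", diffusivity = "numeric",
                 bulkConcentration = "numeric", bulkMaintained = "logical"),
  validity = function(object) {
    msg <- character()
    if (!object@name %in% .SOLUTE_NAMES)
      msg <- c(msg, paste("unknown solute name:", object@name))
    if (any(object@conc < 0)) msg <- c(msg, "concentrations must be >= 0")
    if (!isTRUE(object@diffusivity > 0)) msg <- c(msg, "diffusivity must be > 0")
    if (length(dim(object@conc)) != 3) msg <- c(msg, "conc must be a 3D array")
    if (length(msg)) msg else TRUE
  })

#' Full simulation state at one instant
#'
#' Agents are stored as a data.frame with columns id, species, state
#' (BIOFILM or PLANKTONIC), x, y, z (um), biomass_fg, capsule_fg, radius_um;
#' this flat layout is also the serialization format.
#'
#' @name BiofilmState-class
#' @rdname BiofilmState-class
#' @exportClass BiofilmState
setClass("BiofilmState",
  representation(time = "numeric", agents = "data.frame", fields = "list",
                 grid = "DomainGrid", variant = "character", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!isTRUE(object@time >= 0)) msg <- c(msg, "time must be >= 0")
    if (!object@variant %in% .MODEL_VARIANTS)
      msg <- c(msg, "unknown model variant")
    if (!all(.AGENT_COLUMNS %in% names(object@agents)))
      msg <- c(msg, "agents table is missing required columns")
    fl <- variantFlags(object@variant)
    if (fl$inhibition_active && is.null(object@fields[["inhibitor"]]))
      msg <- c(msg, "inhibition variant requires an inhibitor field")
    if (fl$surfactant_active && is.null(object@fields[["surfactant"]]))
      msg <- c(msg, "surfactant variant requires a surfactant field")
    if (length(msg)) msg else TRUE
  })

#' Simulation run configuration
#'
#' @slot variant model variant name.
#' @slot species named list of \linkS4class{SpeciesParams}.
#' @slot seedCounts named integer-ish vector, initial cells per species.
#' @slot bulk named numeric, bulk concentration per solute (g/L).
#' @slot duration,dt,outputInterval hours.
#' @slot baseSeed RNG seed; replicate i uses baseSeed + i - 1.
#' @slot replicates replicate count for batch runs.
#' @slot settings nested list of solver/division/shove/movement settings.
#' @name RunConfig-class
#' @rdname RunConfig-class
#' @exportClass RunConfig
setClass("RunConfig",
  representation(variant = "character", species = "list",
                 seedCounts = "numeric", bulk = "numeric", duration = "numeric",
                 dt = "numeric", outputInterval = "numeric",
                 baseSeed = "numeric", grid = "DomainGrid",
                 replicates = "numeric", settings = "list"),
  validity = function(object) {
    msg <- character()
    if (!object@variant %in% .MODEL_VARIANTS) msg <- c(msg, "unknown variant")
    if (!isTRUE(object@duration > 0)) msg <- c(msg, "duration must be > 0")
    if (!isTRUE(object@dt > 0)) msg <- c(msg, "dt must be > 0")
    if (is.null(names(object@species)) ||
        !all(names(object@seedCounts) %in% names(object@species)))
      msg <- c(msg, "all seeded species must have registered params")
    if (any(object@seedCounts < 0)) msg <- c(msg, "seed counts must be >= 0")
    if (length(object@species) > 2)
      msg <- c(msg, "at most two species are supported")
    if (length(msg)) msg else TRUE
  })

#' An ordered set of state snapshots from one run
#'
#' @slot times snapshot times (h), strictly increasing, first 0, last the
#'   run duration.
#' @slot states list of \linkS4class{BiofilmState}.
#' @slot seed the RNG seed the run used.
#' @slot config the \linkS4class{RunConfig} that produced it.
#' @slot digest short provenance string (variant, seed, key parameters).
#' @name Trajectory-class
#' @rdname Trajectory-class
#' @exportClass Trajectory
setClass("Trajectory",
  representation(times = "numeric", states = "list", seed = "numeric",
                 config = "RunConfig", digest = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@times) != length(object@states))
      msg <- c(msg, "times and states differ in length")
    if (length(object@times) && any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (length(msg)) msg else TRUE
  })
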