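#' Agents accessor
#'
#' Returns the agent table of a state or trajectory snapshot as a
#' data.frame (columns id, species, state, x, y, z, biomass_fg, capsule_fg,
#' radius_um).
#'
#' @param x a \linkS4class{BiofilmState}.
#' @return a data.frame.
#' @export
setGeneric("agents", function(x) standardGeneric("agents"))

#' Simulation time accessor
#' @param x a \linkS4class{BiofilmState} or \linkS4class{Trajectory}.
#' @return numeric time(s) in hours.
#' @export
setGeneric("simTime", function(x) standardGeneric("simTime"))

#' Solute fields accessor
#' @param x a \linkS4class{BiofilmState}.
#' @return named list of \linkS4class{SoluteField}.
#' @export
setGeneric("soluteFields", function(x) standardGeneric("soluteFields"))

#' Total biovolume of selected agents
#'
#' Sum of agent sphere volumes (4/3 pi r^3, um^3), the primary observable.
#' The radius includes the capsule unless \code{includeCapsule = FALSE}, in
#' which case a biomass-only radius is recomputed. Overlaps are not
#' deduplicated; after shoving residual overlaps are below the shove
#' tolerance.
#'
#' @param x a \linkS4class{BiofilmState}.
#' @param species optional character vector of species names to keep.
#' @param states agent states to keep (default biofilm cells only).
#' @param includeCapsule logical; include capsule volume in the radius.
#' @param ... passed to methods.
#' @return numeric, um^3.
#' @export
setGeneric("biovolume",
  function(x, species = NULL, states = "BIOFILM", includeCapsule = TRUE, ...)
    standardGeneric("biovolume"))

#' Mean biofilm thickness
#'
#' Mean over occupied (x, y) grid columns of the per-column maximum of
#' z + radius over biofilm agents (um). Errors when the state holds no
#' biofilm agents, for which thickness is undefined.
#'
#' @param x a \linkS4class{BiofilmState}.
#' @param ... passed to methods.
#' @return numeric, um.
#' @export
setGeneric("biofilmThickness", function(x, ...)
  standardGeneric("biofilmThickness"))
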