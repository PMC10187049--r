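#' Division settings
#'
#' @param radius division radius (um): an agent divides once its total
#'   (biomass + capsule) radius reaches this value. Default 1.0.
#' @param splitMin,splitMax daughter mass split ratio is drawn uniformly in
#'   this interval (default 0.45-0.55); the two daughters receive
#'   complementary fractions, conserving mass exactly.
#' @return a named list.
#' @export
divisionSettings <- function(radius = 1.0, splitMin = 0.45, splitMax = 0.55) {
  stopifnot(radius > 0, splitMin > 0, splitMax < 1, splitMin <= splitMax)
  list(radius = radius, splitMin = splitMin, splitMax = splitMax)
}

#' Shoving settings
#'
#' @param tol residual pairwise overlap tolerated after relaxation (um).
#' @param mult shove multiplier on the half-overlap displacement.
#' @param maxSweeps relaxation sweep cap; reaching it records a warning.
#' @return a named list.
#' @export
shoveSettings <- function(tol = 0.01, mult = 1.0, maxSweeps = 60) {
  stopifnot(tol >= 0, mult > 0, maxSweeps >= 1)
  list(tol = tol, mult = mult, maxSweeps = maxSweeps)
}

# Draw a uniform random unit vector (isotropic).
.randomDirection <- function(n = 1) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(1 - z^2, 0))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Divide an agent if it reached the division radius
#'
#' Splits the agent into two daughters of the same species and state when
#' its radius is at or above the division radius: biomass and capsule are
#' split by a ratio drawn uniformly from the configured interval (mass
#' conserved exactly) and the daughters are displaced symmetrically along a
#' uniformly random direction to a center separation of (r1 + r2)/2; the
#' subsequent shove relaxation resolves any residual overlap. Below the
#' threshold the agent is returned unchanged. Consumes the R RNG stream.
#'
#' @param agent one-row data.frame with the agent table columns.
#' @param params the agent's \linkS4class{SpeciesParams}.
#' @param settings see \code{\link{divisionSettings}}.
#' @param newIds ids for the daughters (length 2); defaults to
#'   \code{agent$id} and \code{agent$id + 1}.
#' @return data.frame with one (no division) or two rows.
#' @export
divideIfReady <- function(agent, params, settings = divisionSettings(),
                          newIds = c(agent$id, agent$id + 1L)) {
  if (agent$radius_um < settings$radius) return(agent)
  f <- runif(1, settings$splitMin, settings$splitMax)
  dir <- .randomDirection(1)
  b <- agent$biomass_fg * c(f, 1 - f)
  cp <- agent$capsule_fg * c(f, 1 - f)
  r <- agentRadius(b, cp, params@rhoBiomass, params@rhoCapsule)
  sep <- (r[1] + r[2]) / 2
  out <- agent[c(1, 1), ]
  out$id <- as.integer(newIds)
  out$biomass_fg <- b
  out$capsule_fg <- cp
  out$radius_um <- r
  out$x <- agent$x + c(0.5, -0.5) * sep * dir[1]
  out$y <- agent$y + c(0.5, -0.5) * sep * dir[2]
  out$z <- pmax(agent$z + c(0.5, -0.5) * sep * dir[3], r)
  rownames(out) <- NULL
  out
}

# Vectorized division pass over the agent table. Biofilm agents only
# (planktonic cells neither grow nor divide). Deterministic given the RNG
# stream: candidates processed in increasing id order.
.divideAgents <- function(ag, speciesList, settings) {
  ready <- which(ag$state == "BIOFILM" & ag$radius_um >= settings$radius)
  if (!length(ready)) return(ag)
  ready <- ready[order(ag$id[ready])]
  nextId <- max(ag$id) + 1L
  pieces <- vector("list", length(ready))
  for (m in seq_along(pieces)) {
    i <- ready[m]
    pieces[[m]] <- divideIfReady(ag[i, ], speciesList[[ag$species[i]]],
                                 settings, newIds = c(ag$id[i], nextId))
    nextId <- nextId + 1L
  }
  rbind(ag[-ready, ], do.call(rbind, pieces))
}

#' Resolve agent overlaps by shoving
#'
#' Iteratively pushes overlapping sphere pairs apart along their center
#' line, half the overlap each, until the maximum overlap is at or below
#' the tolerance or the sweep cap is reached (then a warning is recorded
#' and the relaxed state returned). Only biofilm agents are shoved;
#' positions wrap periodically in x,y and are clamped to z >= radius above
#' the substratum. Deterministic: pairs are visited in ascending agent-id
#' order.
#'
#' @param agentsDf agent table (data.frame).
#' @param grid the \linkS4class{DomainGrid}.
#' @param settings see \code{\link{shoveSettings}}.
#' @return the agent table with updated positions.
#' @export
shoveRelax <- function(agentsDf, grid, settings = shoveSettings()) {
  bf <- which(agentsDf$state == "BIOFILM")
  if (length(bf) < 2) return(agentsDf)
  bf <- bf[order(agentsDf$id[bf])]
  pos <- cbind(agentsDf$x[bf] %% grid@sideX,
               agentsDf$y[bf] %% grid@sideY,
               pmax(agentsDf$z[bf], agentsDf$radius_um[bf]))
  res <- shove_cpp(pos, agentsDf$radius_um[bf],
                   grid@sideX, grid@sideY, grid@sideZ,
                   settings$tol, settings$mult, settings$maxSweeps)
  if (!res$converged && res$max_overlap > 2 * settings$tol)
    warning(sprintf("shove relaxation hit sweep cap (%d) with max overlap %.3g um",
                    settings$maxSweeps, res$max_overlap))
  agentsDf$x[bf] <- res$pos[, 1]
  agentsDf$y[bf] <- res$pos[, 2]
  agentsDf$z[bf] <- res$pos[, 3]
  agentsDf
}

#' Surfactant-driven detachment of periphery cells
#'
#' Every biofilm agent on the biofilm periphery whose local surfactant
#' concentration strictly exceeds its species' tolerance threshold
#' (0.005 g/L for S. oralis, 0.008 g/L for L. paracasei by default) becomes
#' PLANKTONIC and is relocated to a uniformly random (x, y) position at a
#' uniformly random height within the boundary-layer band just below the
#' bulk. Enclosed (non-periphery) agents never detach, and detachment is
#' one-way: planktonic cells never rejoin the biofilm.
#'
#' @param state a \linkS4class{BiofilmState} of a surfactant-active variant.
#' @param speciesList named list of \linkS4class{SpeciesParams}.
#' @return the updated state.
#' @export
surfactantDetach <- function(state, speciesList) {
  stopifnot(variantFlags(state@variant)$surfactant_active)
  surf <- state@fields[["surfactant"]]
  periph <- peripheryAgents(state)
  if (!length(periph)) return(state)
  ag <- state@agents
  idx <- match(periph, ag$id)
  conc <- localConcentration(surf, state@grid,
                             cbind(ag$x[idx], ag$y[idx], ag$z[idx]))
  tolv <- vapply(ag$species[idx], function(s) {
    t <- speciesList[[s]]@surfactantTolerance
    if (is.na(t)) Inf else t
  }, numeric(1))
  going <- idx[conc > tolv]
  if (length(going)) {
    going <- going[order(ag$id[going])]
    band <- .planktonicBand(state@grid, biofilmFront(state))
    n <- length(going)
    ag$state[going] <- "PLANKTONIC"
    ag$x[going] <- runif(n, 0, state@grid@sideX)
    ag$y[going] <- runif(n, 0, state@grid@sideY)
    ag$z[going] <- runif(n, band[1], band[2])
    state@agents <- ag
  }
  state
}

#' Random movement of planktonic cells
#'
#' Each planktonic agent takes one isotropic random step of fixed length,
#' wrapped periodically in x,y and reflected at the top and bottom of the
#' boundary-layer band (it stays below the bulk and above the biofilm
#' front). Biofilm agents are untouched.
#'
#' @param state a \linkS4class{BiofilmState}.
#' @param stepLength step length per call (um), default 5.
#' @return the updated state.
#' @export
planktonicMove <- function(state, stepLength = 5) {
  pk <- which(state@agents$state == "PLANKTONIC")
  if (!length(pk) || stepLength == 0) return(state)
  pk <- pk[order(state@agents$id[pk])]
  ag <- state@agents
  dir <- .randomDirection(length(pk))
  ag$x[pk] <- (ag$x[pk] + stepLength * dir[, 1]) %% state@grid@sideX
  ag$y[pk] <- (ag$y[pk] + stepLength * dir[, 2]) %% state@grid@sideY
  band <- .planktonicBand(state@grid, biofilmFront(state))
  ag$z[pk] <- .reflectInto(ag$z[pk] + stepLength * dir[, 3], band[1], band[2])
  state@agents <- ag
  state
}

# Reflect values into [lo, hi] (fold repeatedly; degenerate band -> lo).
.reflectInto <- function(z, lo, hi) {
  w <- hi - lo
  if (w <= 0) return(rep(lo, length(z)))
  u <- (z - lo) %% (2 * w)
  lo + ifelse(u > w, 2 * w - u, u)
}
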