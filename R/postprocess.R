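#' @describeIn biovolume sum of sphere volumes over the selected agents of
#'   a state
#' @export
setMethod("biovolume", "BiofilmState",
  function(x, species = NULL, states = "BIOFILM", includeCapsule = TRUE, ...) {
    ag <- x@agents
    keep <- ag$state %in% states
    if (!is.null(species)) keep <- keep & ag$species %in% species
    if (!any(keep)) return(0)
    r <- if (includeCapsule) ag$radius_um[keep] else
      agentRadius(ag$biomass_fg[keep], 0)
    sum(4 / 3 * pi * r^3)
  })

#' @describeIn biofilmThickness mean per-column biofilm height of a state
#' @export
setMethod("biofilmThickness", "BiofilmState", function(x, ...) {
  ag <- x@agents
  bf <- ag$state == "BIOFILM"
  if (!any(bf)) stop("thickness undefined: no biofilm agents")
  h <- x@grid@voxelSize
  d <- gridDims(x@grid)
  col <- floor((ag$x[bf] %% x@grid@sideX) / h) +
    d[1] * floor((ag$y[bf] %% x@grid@sideY) / h)
  top <- tapply(ag$z[bf] + ag$radius_um[bf], col, max)
  mean(top)
})

#' Coefficient of variation across replicates
#'
#' 100 * sample SD / mean of an observable measured once per replicate,
#' the replicate-count stopping criterion of the study design (< 10\%).
#'
#' @param values numeric vector, one value per replicate (>= 2).
#' @return percent.
#' @examples
#' replicateCV(c(1, 2, 3))  # 50
#' @export
replicateCV <- function(values) {
  if (length(values) < 2) stop("replicateCV needs >= 2 replicates")
  m <- mean(values)
  if (m == 0) stop("replicateCV undefined: zero mean")
  100 * stats::sd(values) / m
}

#' Tidy per-state summary
#'
#' One row per species x agent state: biovolume (um^3; biofilm cells only
#' by the study's convention -- planktonic rows carry NA), agent count, and
#' biofilm thickness (um, repeated; NA when there is no biofilm).
#'
#' @param state a \linkS4class{BiofilmState}.
#' @param run_id identifier column value.
#' @return data.frame with columns run_id, time_h, species, state,
#'   biovolume_um3, count, thickness_um.
#' @export
summarizeState <- function(state, run_id = NA_integer_) {
  ag <- state@agents
  sp <- sort(unique(ag$species))
  if (!length(sp)) sp <- NA_character_
  th <- if (any(ag$state == "BIOFILM")) biofilmThickness(state) else NA_real_
  out <- expand.grid(species = sp, state = c("BIOFILM", "PLANKTONIC"),
                     stringsAsFactors = FALSE)
  out$biovolume_um3 <- vapply(seq_len(nrow(out)), function(i) {
    if (out$state[i] == "PLANKTONIC") return(NA_real_)
    biovolume(state, species = out$species[i], states = out$state[i])
  }, numeric(1))
  out$count <- vapply(seq_len(nrow(out)), function(i)
    sum(ag$species == out$species[i] & ag$state == out$state[i]),
    numeric(1))
  data.frame(run_id = run_id, time_h = state@time, out,
             thickness_um = th, stringsAsFactors = FALSE)
}

#' Tidy summary of a trajectory
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param run_id identifier (defaults to the run seed).
#' @return data.frame, one block of rows per snapshot
#'   (see \code{\link{summarizeState}}).
#' @export
summarizeTrajectory <- function(traj, run_id = traj@seed) {
  do.call(rbind, lapply(traj@states, summarizeState, run_id = run_id))
}

#' Tidy summary of a replicate batch
#'
#' @param trajs list of \linkS4class{Trajectory} from
#'   \code{\link{runReplicates}}.
#' @return data.frame in long format across runs.
#' @export
summarizeReplicates <- function(trajs) {
  do.call(rbind, lapply(trajs, summarizeTrajectory))
}

#' Ordinary least-squares fit of biovolume on dilution fraction
#'
#' The linear dilution-response summary used for the medium-dilution
#' series: biovolume ~ dilution by OLS, with R^2 the squared Pearson
#' correlation (0 for a flat response).
#'
#' @param table data.frame with columns \code{dilution} and
#'   \code{biovolume} (additional columns ignored); >= 2 distinct dilution
#'   values and >= 2 points required.
#' @return list with \code{slope}, \code{intercept}, \code{r2} and the
#'   underlying \code{lm} fit.
#' @examples
#' d <- data.frame(dilution = c(1, 0.5, 0.1),
#'                 biovolume = 7762 * c(1, 0.5, 0.1) + 357.8)
#' dilutionRegression(d)$slope
#' @export
dilutionRegression <- function(table) {
  if (!all(c("dilution", "biovolume") %in% names(table)))
    stop("table must have columns 'dilution' and 'biovolume'")
  if (nrow(table) < 2 || length(unique(table$dilution)) < 2)
    stop("need >= 2 points at >= 2 distinct dilutions")
  fit <- stats::lm(biovolume ~ dilution, data = table)
  r2 <- if (stats::var(table$biovolume) == 0) 0 else
    suppressWarnings(stats::cor(table$dilution, table$biovolume)^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = r2, fit = fit)
}
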