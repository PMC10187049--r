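#' The glucose dilution sweep
#'
#' The seven medium-dilution fractions of full-strength (2 g/L glucose)
#' biofilm medium used throughout: 1, 0.75, 0.5, 0.25, 0.1, 0.05, 0.01
#' (glucose 2, 1.5, 1, 0.5, 0.2, 0.1, 0.02 g/L). Only glucose is diluted;
#' oxygen is never.
#'
#' @return numeric vector of dilution fractions.
#' @export
dilutionSweep <- function() c(1, 0.75, 0.5, 0.25, 0.1, 0.05, 0.01)

#' Calibration target
#'
#' A target dilution response for \code{\link{bisectionFit}}: either a
#' table of (dilution, biovolume) from which the normalized slope is
#' derived, or the normalized slope directly. The normalized slope is the
#' OLS slope of biovolume on dilution fraction divided by the biovolume at
#' full strength, making the objective insensitive to the absolute
#' biovolume units of the measuring instrument.
#'
#' @param table optional data.frame with columns dilution, biovolume.
#' @param normSlope optional numeric target normalized slope (used when
#'   \code{table} is NULL).
#' @param tolerance absolute tolerance on the objective (default 0.02).
#' @return a list of class \code{calibrationTarget}.
#' @export
calibrationTarget <- function(table = NULL, normSlope = NULL,
                              tolerance = 0.02) {
  stopifnot(tolerance > 0)
  if (is.null(normSlope)) {
    if (is.null(table)) stop("supply a table or a normalized slope")
    if (length(unique(table$dilution)) < 2)
      stop("target table needs >= 2 dilutions")
    normSlope <- .normalizedSlope(table)
  }
  structure(list(normSlope = normSlope, tolerance = tolerance),
            class = "calibrationTarget")
}

# Normalized dilution-response slope of a (dilution, biovolume) table:
# OLS slope divided by the mean biovolume at the largest dilution present.
.normalizedSlope <- function(table) {
  full <- mean(table$biovolume[table$dilution == max(table$dilution)])
  if (full <= 0) stop("non-positive full-strength biovolume")
  dilutionRegression(table)$slope / full
}

#' Simulated biovolume response to medium dilution
#'
#' Runs 16-h (by default) single-species biofilm batches over a set of
#' medium-dilution fractions, scaling only the glucose bulk concentration
#' (dilution x 2 g/L by default; oxygen untouched), and returns the mean
#' final biofilm biovolume per dilution. Replicates use common seeds
#' across dilutions so responses at different parameter values are
#' comparable (common random numbers).
#'
#' @param params \linkS4class{SpeciesParams} of the species to run.
#' @param dilutions dilution fractions in (0, 1] (default the seven-step
#'   sweep).
#' @param config base \linkS4class{RunConfig}; its glucose bulk value is
#'   the full-strength concentration. Defaults to a single-species run of
#'   \code{params} at study conditions.
#' @param replicates runs per dilution (default 1).
#' @param baseSeed seed of the first replicate (shared across dilutions).
#' @return data.frame with columns dilution, biovolume (mean), and n.
#' @export
dilutionResponse <- function(params, dilutions = dilutionSweep(),
                             config = NULL, replicates = 1, baseSeed = 1) {
  stopifnot(all(dilutions > 0), all(dilutions <= 1), replicates >= 1)
  if (is.null(config)) {
    sp <- stats::setNames(list(params), params@name)
    config <- runConfig("COMPETITION", species = sp,
                        seedCounts = stats::setNames(176, params@name))
  } else {
    config@species[[params@name]] <- params
  }
  full <- unname(config@bulk["glucose"])
  rows <- lapply(dilutions, function(f) {
    cfg <- config
    cfg@bulk["glucose"] <- f * full
    trajs <- runReplicates(cfg, replicates = replicates, baseSeed = baseSeed)
    bv <- vapply(trajs, function(tr)
      biovolume(finalState(tr), species = params@name), numeric(1))
    data.frame(dilution = f, biovolume = mean(bv), n = length(bv))
  })
  do.call(rbind, rows)
}

#' Bisection calibration of one growth parameter
#'
#' Adjusts \code{muMax} or \code{KSg} of one species by bisection until the
#' simulated normalized dilution-response slope matches the target. The
#' objective is (simulated normalized slope) - (target normalized slope);
#' every evaluation reuses the same replicate seeds (common random
#' numbers), so the objective is a deterministic function of the parameter
#' and the bracket endpoints must give it opposite signs. Iteration stops
#' when |objective| falls within the target tolerance or the bracket has
#' shrunk to 1e-3 of its initial width.
#'
#' @param paramName "muMax" or "KSg".
#' @param bracket numeric length 2, the search interval (the biologically
#'   relevant range; defaults used by the study-style calibration are
#'   muMax in [0.05, 1] 1/h and KSg in [0.01, 5] g/L).
#' @param target a \code{\link{calibrationTarget}}.
#' @param params starting \linkS4class{SpeciesParams} of the species being
#'   calibrated.
#' @param dilutions,config,replicates,baseSeed forwarded to
#'   \code{\link{dilutionResponse}}.
#' @param checkMonotone evaluate the objective on a coarse grid across the
#'   bracket first and abort with a diagnostic if it is not monotone
#'   (bisection assumes a single sign change). Off by default because each
#'   grid point costs a full dilution sweep.
#' @param monotoneGrid number of coarse grid points for the check.
#' @param verbose print each bisection step.
#' @return list: \code{value} (fitted parameter), \code{objective} at the
#'   fit, \code{iterations}, and \code{history} (data.frame of evaluations).
#' @export
bisectionFit <- function(paramName = c("KSg", "muMax"), bracket, target,
                         params, dilutions = dilutionSweep(), config = NULL,
                         replicates = 1, baseSeed = 1,
                         checkMonotone = FALSE, monotoneGrid = 4,
                         verbose = FALSE) {
  paramName <- match.arg(paramName)
  stopifnot(length(bracket) == 2, bracket[1] <= bracket[2])
  slotName <- if (paramName == "KSg") "KSg" else "muMax"
  evalObjective <- function(theta) {
    p <- params
    slot(p, slotName) <- theta
    resp <- dilutionResponse(p, dilutions, config, replicates, baseSeed)
    .normalizedSlope(resp) - target$normSlope
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (lo == hi)
    return(list(value = lo, objective = NA_real_, iterations = 0,
                history = data.frame()))
  if (checkMonotone) {
    thetas <- seq(lo, hi, length.out = max(3, monotoneGrid))
    objs <- vapply(thetas, evalObjective, numeric(1))
    d <- diff(objs)
    if (!(all(d >= 0) || all(d <= 0)))
      stop("objective is not monotone over the bracket: ",
           paste(sprintf("f(%.4g) = %.4g", thetas, objs), collapse = ", "),
           "; narrow the bracket or change the objective")
  }
  flo <- evalObjective(lo); fhi <- evalObjective(hi)
  hist <- data.frame(theta = c(lo, hi), objective = c(flo, fhi))
  if (sign(flo) == sign(fhi))
    stop("objective has the same sign at both bracket ends; widen or move the bracket")
  minWidth <- 1e-3 * (hi - lo)
  iter <- 0
  mid <- (lo + hi) / 2; fmid <- NA_real_
  while (hi - lo > minWidth) {
    iter <- iter + 1
    mid <- (lo + hi) / 2
    fmid <- evalObjective(mid)
    hist <- rbind(hist, data.frame(theta = mid, objective = fmid))
    if (verbose)
      message(sprintf("  bisection %d: %s = %.5g, objective = %.4g",
                      iter, paramName, mid, fmid))
    if (abs(fmid) <= target$tolerance) break
    if (sign(fmid) == sign(flo)) { lo <- mid; flo <- fmid } else
      { hi <- mid; fhi <- fmid }
  }
  list(value = mid, objective = fmid, iterations = iter, history = hist)
}
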