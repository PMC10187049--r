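#' Solver settings
#'
#' @param tol convergence tolerance on the normalized residual of the
#'   discrete diffusion-reaction equation (default 1e-6).
#' @param maxIter Gauss-Seidel sweep cap (default 10000).
#' @param safety explicit-stability safety factor for transient sub-steps
#'   (default 0.9 of the FTCS bound h^2/(6D)).
#' @param outerPasses coupled-field Picard passes per engine step.
#' @param omega successive over-relaxation factor of the Gauss-Seidel
#'   sweeps (1 = plain Gauss-Seidel; default 1.7, near-optimal for the
#'   default grid).
#' @return a named list.
#' @export
solverSettings <- function(tol = 1e-6, maxIter = 10000, safety = 0.9,
                           outerPasses = 2, omega = 1.7) {
  stopifnot(tol > 0, maxIter >= 1, safety > 0, safety <= 1,
            omega > 0, omega < 2)
  list(tol = tol, maxIter = maxIter, safety = safety,
       outerPasses = outerPasses, omega = omega)
}

#' Pseudo-steady diffusion-reaction solve of a bulk-maintained field
#'
#' Solves D lap(S) + r(S) = 0 on the voxel grid with the bulk region
#' Dirichlet-clamped to the bulk concentration, zero flux at the
#' substratum, and periodic lateral faces. The reaction is a sum of
#' saturable (Monod) sink/source groups, r(S) = sum_g Vmax_g(v) S/(K_g + S)
#' with Vmax_g <= 0 for consumption, re-linearized every Gauss-Seidel sweep
#' (Picard iteration), plus an optional constant-rate map. Concentrations
#' are kept non-negative; for pure constant sinks the solution is floored
#' at 0 where demand exceeds supply.
#'
#' @param field a \linkS4class{SoluteField} with \code{bulkMaintained} TRUE;
#'   its current concentrations warm-start the iteration.
#' @param grid the \linkS4class{DomainGrid}.
#' @param sinkGroups list of \code{list(vmax = <3D array, g/L/h>, K = <g/L>)}
#'   saturable reaction groups (may be empty).
#' @param constRate optional 3D array of constant volumetric rates (g/L/h).
#' @param bulkMask logical 3D array of voxels clamped to the bulk value;
#'   default clamps everything at least \code{boundaryLayer} above z = 0
#'   (callers normally pass a mask above the biofilm front).
#' @param settings see \code{\link{solverSettings}}.
#' @return the field with updated concentrations; attributes
#'   \code{iterations} and \code{residual} record the solve.
#' @export
solveSteady <- function(field, grid, sinkGroups = list(), constRate = NULL,
                        bulkMask = .bulkMask(grid, 0),
                        settings = solverSettings()) {
  stopifnot(field@bulkMaintained)
  d <- gridDims(grid)
  nvox <- prod(d)
  ng <- length(sinkGroups)
  vmax <- matrix(0, nrow = nvox, ncol = max(ng, 1))
  Ks <- rep(1, max(ng, 1))
  if (ng) {
    for (g in seq_len(ng)) {
      vmax[, g] <- as.numeric(sinkGroups[[g]]$vmax)
      Ks[g] <- sinkGroups[[g]]$K
    }
  } else {
    Ks <- numeric(0)
    vmax <- matrix(0, nrow = nvox, ncol = 0)
  }
  cr <- if (is.null(constRate)) numeric(0) else as.numeric(constRate)
  res <- solve_steady_cpp(as.numeric(field@conc), d, vmax, Ks, cr,
                          as.logical(bulkMask), field@bulkConcentration,
                          field@diffusivity, grid@voxelSize,
                          settings$tol, settings$maxIter,
                          settings$omega %||% 1.7)
  if (!res$converged)
    stop(sprintf("steady-state solve for '%s' did not converge: residual %.3g after %d sweeps",
                 field@name, res$residual, res$iterations))
  field@conc <- array(res$conc, dim = d)
  attr(field, "iterations") <- res$iterations
  attr(field, "residual") <- res$residual
  field
}

#' Transient diffusion step of an accumulating field
#'
#' Advances a non-bulk-maintained solute (inhibitor, surfactant) by one
#' time step of explicit diffusion with volumetric sources, sub-stepping
#' internally to respect the FTCS stability bound. All z faces are zero
#' flux and lateral faces periodic, so total solute mass increases by
#' exactly sum(source) * voxelVolume * dt (no washout).
#'
#' @param field a \linkS4class{SoluteField} with \code{bulkMaintained} FALSE.
#' @param grid the \linkS4class{DomainGrid}.
#' @param sourceRate 3D array of volumetric production rates (g/L/h),
#'   non-negative; NULL for pure diffusion.
#' @param dt step length (h), > 0.
#' @param settings see \code{\link{solverSettings}}.
#' @return the field with updated concentrations.
#' @export
stepTransient <- function(field, grid, sourceRate = NULL, dt,
                          settings = solverSettings()) {
  stopifnot(!field@bulkMaintained, dt > 0)
  d <- gridDims(grid)
  src <- if (is.null(sourceRate)) numeric(0) else as.numeric(sourceRate)
  if (length(src) && any(src < 0)) stop("source rates must be >= 0")
  conc <- step_transient_cpp(as.numeric(field@conc), d, src,
                             field@diffusivity, grid@voxelSize, dt,
                             settings$safety)
  field@conc <- array(conc, dim = d)
  field
}
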