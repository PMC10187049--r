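#' Construct a simulation domain grid
#'
#' @param side domain edge lengths in um, length 1 or 3 (default 136 each,
#'   giving an 18,496 um^2 substratum).
#' @param voxelSize voxel edge in um; each side must be a multiple of it.
#' @param boundaryLayer boundary-layer thickness in um (the band between
#'   the biofilm front and the well-mixed bulk).
#' @return a \linkS4class{DomainGrid}.
#' @examples
#' g <- domainGrid()
#' gridDims(g)
#' substratumArea(g)
#' @export
domainGrid <- function(side = 136, voxelSize = 8, boundaryLayer = 40) {
  side <- rep_len(side, 3)
  new("DomainGrid", sideX = side[1], sideY = side[2], sideZ = side[3],
      voxelSize = voxelSize, boundaryLayer = boundaryLayer)
}

#' Voxel counts per axis
#' @param grid a \linkS4class{DomainGrid}.
#' @return integer vector (nx, ny, nz).
#' @export
gridDims <- function(grid) {
  as.integer(round(c(grid@sideX, grid@sideY, grid@sideZ) / grid@voxelSize))
}

#' Voxel volume in um^3
#' @param grid a \linkS4class{DomainGrid}.
#' @export
voxelVolume <- function(grid) grid@voxelSize^3

#' Substratum surface area in um^2
#' @param grid a \linkS4class{DomainGrid}.
#' @export
substratumArea <- function(grid) grid@sideX * grid@sideY

# Flat (column-major) voxel index of continuous positions; voxels are
# half-open [i*h, (i+1)*h). Positions are wrapped periodically in x,y and
# clamped into the top/bottom voxel in z only when within roundoff of the
# faces (callers keep agents inside the domain).
voxelIndexOf <- function(grid, x, y, z) {
  h <- grid@voxelSize
  d <- gridDims(grid)
  i <- floor((x %% grid@sideX) / h)
  j <- floor((y %% grid@sideY) / h)
  k <- pmin(pmax(floor(z / h), 0), d[3] - 1)
  as.integer(i + d[1] * (j + d[2] * k) + 1)
}

#' Concentration at a point
#'
#' Returns the concentration of the voxel containing the position (the
#' coarse-grained individual-based-model convention; no interpolation by
#' default). With \code{interpolate = TRUE} a trilinear interpolation of
#' voxel-center values is used instead.
#'
#' @param field a \linkS4class{SoluteField}.
#' @param grid the \linkS4class{DomainGrid} the field lives on.
#' @param position numeric length 3 (um), or an n x 3 matrix.
#' @param interpolate logical, default FALSE.
#' @return concentration(s), g/L.
#' @examples
#' g <- domainGrid()
#' f <- soluteField("glucose", g, bulk = 2)
#' localConcentration(f, g, c(10, 10, 10))
#' @export
localConcentration <- function(field, grid, position, interpolate = FALSE) {
  pos <- if (is.matrix(position)) position else matrix(position, ncol = 3)
  if (any(pos[, 3] < 0) || any(pos[, 3] > grid@sideZ))
    stop("position outside domain in z")
  if (!interpolate) {
    v <- voxelIndexOf(grid, pos[, 1], pos[, 2], pos[, 3])
    out <- as.numeric(field@conc)[v]
  } else {
    out <- .trilinear(field@conc, grid, pos)
  }
  if (!is.matrix(position)) out[1] else out
}

.trilinear <- function(conc, grid, pos) {
  h <- grid@voxelSize
  d <- dim(conc)
  out <- numeric(nrow(pos))
  for (n in seq_len(nrow(pos))) {
    # fractional voxel-center coordinates; clamp in z, wrap in x,y
    fx <- (pos[n, 1] %% grid@sideX) / h - 0.5
    fy <- (pos[n, 2] %% grid@sideY) / h - 0.5
    fz <- min(max(pos[n, 3] / h - 0.5, 0), d[3] - 1)
    i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
    tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
    acc <- 0
    for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
      w <- (if (di) tx else 1 - tx) * (if (dj) ty else 1 - ty) *
           (if (dk) tz else 1 - tz)
      ii <- ((i0 + di) %% d[1]) + 1
      jj <- ((j0 + dj) %% d[2]) + 1
      kk <- min(max(k0 + dk, 0), d[3] - 1) + 1
      acc <- acc + w * conc[ii, jj, kk]
    }
    out[n] <- acc
  }
  out
}

#' Construct a solute field
#'
#' @param name solute name (glucose, oxygen, substrate1, substrate2,
#'   inhibitor, surfactant).
#' @param grid a \linkS4class{DomainGrid}.
#' @param bulk bulk concentration (g/L).
#' @param diffusivity um^2/h; defaults per solute (glucose-like 2.1e4,
#'   oxygen 7.2e4).
#' @param bulkMaintained TRUE for nutrients (pseudo-steady against constant
#'   bulk), FALSE for secreted accumulating solutes; default by solute name.
#' @param init initial concentration filling the array (default: bulk for
#'   maintained fields, 0 otherwise).
#' @return a \linkS4class{SoluteField}.
#' @export
soluteField <- function(name, grid, bulk = 0,
                        diffusivity = defaultDiffusivity(name),
                        bulkMaintained = !name %in% c("inhibitor", "surfactant"),
                        init = if (bulkMaintained) bulk else 0) {
  d <- gridDims(grid)
  new("SoluteField", name = name,
      conc = array(init, dim = d), diffusivity = diffusivity,
      bulkConcentration = bulk, bulkMaintained = bulkMaintained)
}

#' Default diffusivity of a solute (um^2/h)
#'
#' Glucose 2.1e4; oxygen 7.2e4; the secreted inhibitor and surfactant and
#' the independent carbon substrates default to the glucose value.
#'
#' @param name solute name.
#' @export
defaultDiffusivity <- function(name) {
  switch(name, oxygen = 7.2e4, 2.1e4)
}

# Logical occupancy array: TRUE where a voxel contains >= 1 biofilm agent.
.occupancyArray <- function(state) {
  d <- gridDims(state@grid)
  occ <- array(FALSE, dim = d)
  ag <- state@agents
  bf <- ag$state == "BIOFILM"
  if (any(bf))
    occ[unique(voxelIndexOf(state@grid, ag$x[bf], ag$y[bf], ag$z[bf]))] <- TRUE
  occ
}

#' Biofilm periphery agents
#'
#' Returns the ids of biofilm agents whose containing voxel has at least one
#' biomass-free voxel in its 26-neighborhood or touches the domain top.
#' Below the substratum counts as occupied (a wall), above the top as free.
#' These are the cells exposed to the liquid and eligible for
#' surfactant-driven detachment; planktonic agents are never included.
#'
#' @param state a \linkS4class{BiofilmState}.
#' @return integer vector of agent ids (possibly empty).
#' @export
peripheryAgents <- function(state) {
  ag <- state@agents
  bf <- which(ag$state == "BIOFILM")
  if (!length(bf)) return(integer())
  occ <- .occupancyArray(state)
  d <- dim(occ)
  # pad in z: occupied below the substratum, free above the top
  pad <- array(FALSE, dim = d + c(0, 0, 2))
  pad[, , 2:(d[3] + 1)] <- occ
  pad[, , 1] <- TRUE
  hasEmpty <- array(FALSE, dim = d)
  ix <- seq_len(d[1]); iy <- seq_len(d[2])
  for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    sx <- ((ix - 1 + di) %% d[1]) + 1
    sy <- ((iy - 1 + dj) %% d[2]) + 1
    sz <- seq_len(d[3]) + 1 + dk
    hasEmpty <- hasEmpty | !pad[sx, sy, sz, drop = FALSE]
  }
  vox <- voxelIndexOf(state@grid, ag$x[bf], ag$y[bf], ag$z[bf])
  ag$id[bf][as.vector(hasEmpty)[vox]]
}

#' Height of the biofilm front
#'
#' Maximum of z + radius over biofilm agents (0 for an empty biofilm); the
#' boundary layer extends from here to the bulk.
#'
#' @param state a \linkS4class{BiofilmState}.
#' @return numeric, um.
#' @export
biofilmFront <- function(state) {
  ag <- state@agents
  bf <- ag$state == "BIOFILM"
  if (!any(bf)) return(0)
  max(ag$z[bf] + ag$radius_um[bf])
}

# Bulk mask for pseudo-steady fields: voxels whose centers are at least
# boundaryLayer above the biofilm front are clamped to the bulk value; the
# topmost layer is always clamped so the field stays bulk-connected.
.bulkMask <- function(grid, front) {
  d <- gridDims(grid)
  h <- grid@voxelSize
  zc <- (seq_len(d[3]) - 0.5) * h
  clamped <- zc >= front + grid@boundaryLayer
  clamped[d[3]] <- TRUE
  array(rep(clamped, each = d[1] * d[2]), dim = d)
}

# The boundary-layer band [front, min(front + boundaryLayer, sideZ)] where
# planktonic cells reside.
.planktonicBand <- function(grid, front) {
  top <- min(front + grid@boundaryLayer, grid@sideZ)
  lo <- min(front, top)
  c(lo, top)
}

#' @describeIn DomainGrid-class display
#' @param object a DomainGrid
#' @export
setMethod("show", "DomainGrid", function(object) {
  d <- gridDims(object)
  cat(sprintf("DomainGrid: %g x %g x %g um (%d x %d x %d voxels of %g um), boundary layer %g um\n",
              object@sideX, object@sideY, object@sideZ, d[1], d[2], d[3],
              object@voxelSize, object@boundaryLayer))
  invisible(NULL)
})

#' @describeIn SoluteField-class display
#' @param object a SoluteField
#' @export
setMethod("show", "SoluteField", function(object) {
  cat(sprintf("SoluteField '%s': bulk %g g/L (%s), D %g um^2/h, range [%.4g, %.4g]\n",
              object@name, object@bulkConcentration,
              if (object@bulkMaintained) "maintained" else "accumulating",
              min(object@conc), max(object@conc)))
  invisible(NULL)
})
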