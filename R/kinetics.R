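#' Dual-substrate Monod specific growth rate
#'
#' mu = muMax * Sg/(KSg + Sg) * So/(KSo + So). Each half-saturation constant
#' is the substrate concentration at which growth is half-maximal (holding
#' the other substrate saturating). Vectorized over concentrations.
#'
#' @param params a \linkS4class{SpeciesParams}.
#' @param Sg carbon substrate concentration (g/L), >= 0.
#' @param So oxygen concentration (g/L), >= 0.
#' @return specific growth rate (1/h), in [0, muMax].
#' @examples
#' monodMu(soralisParams(), Sg = 2, So = 0.0064)
#' @export
monodMu <- function(params, Sg, So) {
  if (any(Sg < 0) || any(So < 0)) stop("substrate concentrations must be >= 0")
  params@muMax * Sg / (params@KSg + Sg) * So / (params@KSo + So)
}

#' Noncompetitive inhibition factor
#'
#' KI / (KI + I): 1 with no inhibitor, 1/2 at I = KI, tending to 0 as the
#' inhibitor accumulates; multiplies the Monod rate of the inhibited
#' species independently of substrate levels.
#'
#' @param I inhibitor concentration (g/L), >= 0.
#' @param KI inhibition constant (g/L), > 0.
#' @return dimensionless factor in (0, 1].
#' @examples
#' inhibitionFactor(0.0025, 0.0025)  # 0.5
#' @export
inhibitionFactor <- function(I, KI) {
  if (any(I < 0)) stop("inhibitor concentration must be >= 0")
  if (any(KI <= 0)) stop("KI must be > 0")
  KI / (KI + I)
}

#' Effective specific growth rate under a model variant
#'
#' The Monod dual-substrate rate, multiplied by the noncompetitive
#' inhibition factor when the variant activates inhibition and the species
#' carries an inhibition constant. Under the independent-substrate control
#' each species reads its own carbon field (named in \code{carbon}) with
#' unchanged constants.
#'
#' @param params a \linkS4class{SpeciesParams}.
#' @param solutes named numeric vector/list of local concentrations (g/L);
#'   must contain \code{carbon}, \code{"oxygen"}, and \code{"inhibitor"}
#'   when the inhibition term applies.
#' @param variant model variant name.
#' @param carbon name of the carbon field this species consumes
#'   (default "glucose").
#' @return specific growth rate (1/h).
#' @examples
#' effectiveMu(soralisParams(),
#'             c(glucose = 2, oxygen = 0.0064, inhibitor = 0.0025),
#'             "INHIBITION")
#' @export
effectiveMu <- function(params, solutes, variant, carbon = "glucose") {
  solutes <- as.list(solutes)
  fl <- variantFlags(variant)
  if (!fl$shared_carbon && carbon == "glucose")
    carbon <- grep("^substrate", names(solutes), value = TRUE)[1]
  Sg <- solutes[[carbon]]
  So <- solutes[["oxygen"]]
  if (is.null(Sg) || is.null(So)) stop("missing required solute field")
  mu <- monodMu(params, Sg, So)
  if (fl$inhibition_active && !is.na(params@KI)) {
    I <- solutes[["inhibitor"]]
    if (is.null(I)) stop("inhibition active but no inhibitor concentration supplied")
    mu <- mu * inhibitionFactor(I, params@KI)
  }
  mu
}

#' Advance agent masses over one time step
#'
#' Exponential growth with the specific rate frozen at the step start:
#' produced mass Delta = X (exp(mu dt) - 1) with X the cell biomass. The
#' biomass fraction of Delta goes to cell biomass and the capsule fraction
#' to the EPS capsule; when \code{epsActive} is FALSE (surfactant variants)
#' all produced mass goes to biomass. Vectorized over agents.
#'
#' @param biomass_fg,capsule_fg current masses (fg).
#' @param mu specific growth rate(s) (1/h), >= 0.
#' @param dt time step (h), > 0.
#' @param params a \linkS4class{SpeciesParams} (for the split fractions and
#'   densities).
#' @param epsActive logical; produce capsule mass.
#' @return list with updated \code{biomass_fg}, \code{capsule_fg},
#'   \code{radius_um}.
#' @examples
#' biomassStep(100, 0, mu = 0.32, dt = 1, soralisParams())
#' @export
biomassStep <- function(biomass_fg, capsule_fg, mu, dt, params,
                        epsActive = TRUE) {
  if (!isTRUE(dt > 0)) stop("dt must be > 0")
  if (any(mu < 0)) stop("mu must be >= 0")
  delta <- biomass_fg * (exp(mu * dt) - 1)
  if (epsActive) {
    biomass_fg <- biomass_fg + params@biomassFraction * delta
    capsule_fg <- capsule_fg + params@capsuleFraction * delta
  } else {
    biomass_fg <- biomass_fg + delta
  }
  list(biomass_fg = biomass_fg, capsule_fg = capsule_fg,
       radius_um = agentRadius(biomass_fg, capsule_fg,
                               params@rhoBiomass, params@rhoCapsule))
}

#' Per-agent solute mass rates
#'
#' Consumption is growth-coupled: the glucose (carbon) rate is
#' yieldGlucose * mu * X and the oxygen rate yieldOxygen * mu * X (fg/h,
#' negative = consumed). Production of the inhibitor and surfactant is a
#' separate first-order reaction in producer biomass, yield * k * X,
#' independent of the growth rate, and only when the variant activates the
#' corresponding solute. Rates convert to volumetric g/L/h by dividing by
#' the voxel volume (um^3) of the agent's voxel.
#'
#' @param params a \linkS4class{SpeciesParams}.
#' @param mu specific growth rate(s) (1/h).
#' @param biomass_fg cell biomass(es) (fg).
#' @param variant model variant name.
#' @return list of rates (fg/h): \code{carbon}, \code{oxygen},
#'   \code{inhibitor}, \code{surfactant}.
#' @examples
#' soluteRates(soralisParams(), mu = 0.16, biomass_fg = 100, "COMPETITION")
#' @export
soluteRates <- function(params, mu, biomass_fg, variant) {
  fl <- variantFlags(variant)
  zero <- rep(0, length(biomass_fg))
  inh <- if (fl$inhibition_active && !is.na(params@yieldInhibitor) &&
             !is.na(params@productionRateK))
    params@yieldInhibitor * params@productionRateK * biomass_fg else zero
  srf <- if (fl$surfactant_active && !is.na(params@yieldSurfactant) &&
             !is.na(params@productionRateK))
    params@yieldSurfactant * params@productionRateK * biomass_fg else zero
  list(carbon = params@yieldGlucose * mu * biomass_fg,
       oxygen = params@yieldOxygen * mu * biomass_fg,
       inhibitor = inh, surfactant = srf)
}
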