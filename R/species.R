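#' Construct species parameters
#'
#' Builds a \linkS4class{SpeciesParams}. Yields follow the sign convention
#' of the growth model: negative yields are consumed (g solute per g new
#' biomass), production yields are positive (g product per g producer
#' biomass per unit of the first-order production reaction). Densities
#' convert mass to volume (g/L equals fg/um^3), giving the spherical radius
#' r = (3 (mb/rho_b + mc/rho_c) / (4 pi))^(1/3).
#'
#' @param name species label.
#' @param muMax maximum specific growth rate (1/h).
#' @param KSg glucose (carbon) half-saturation constant (g/L).
#' @param KSo oxygen half-saturation constant (g/L).
#' @param KI noncompetitive inhibition constant (g/L) or NA.
#' @param yieldGlucose,yieldOxygen consumption yields (negative).
#' @param biomassFraction,capsuleFraction split of produced mass between
#'   cell biomass and EPS capsule; must sum to 1.
#' @param productionRateK first-order production rate constant (1/h) or NA.
#' @param yieldInhibitor,yieldSurfactant production yields (g/g) or NA.
#' @param surfactantTolerance detachment threshold (g/L) or NA.
#' @param rhoBiomass,rhoCapsule mass densities (g/L).
#' @return a \linkS4class{SpeciesParams}.
#' @examples
#' p <- speciesParams("demo", muMax = 0.3, KSg = 1, KSo = 2e-4)
#' monodMu(p, Sg = 1, So = 1)
#' @export
speciesParams <- function(name, muMax, KSg, KSo, KI = NA_real_,
                          yieldGlucose = -1, yieldOxygen = -1,
                          biomassFraction = 1, capsuleFraction = 1 - biomassFraction,
                          productionRateK = NA_real_,
                          yieldInhibitor = NA_real_, yieldSurfactant = NA_real_,
                          surfactantTolerance = NA_real_,
                          rhoBiomass = 150, rhoCapsule = 75) {
  new("SpeciesParams", name = name, muMax = muMax, KSg = KSg, KSo = KSo,
      KI = KI, yieldGlucose = yieldGlucose, yieldOxygen = yieldOxygen,
      biomassFraction = biomassFraction, capsuleFraction = capsuleFraction,
      productionRateK = productionRateK, yieldInhibitor = yieldInhibitor,
      yieldSurfactant = yieldSurfactant,
      surfactantTolerance = surfactantTolerance,
      rhoBiomass = rhoBiomass, rhoCapsule = rhoCapsule)
}

#' Streptococcus oralis (So34) default parameters
#'
#' Calibrated growth constants for S. oralis: muMax 0.32/h, KSg 1.756 g/L,
#' KSo 0.192e-3 g/L, inhibition constant KI 0.0025 g/L, glucose yield -3,
#' oxygen yield -2, biomass:capsule 0.8:0.2, surfactant tolerance 0.005 g/L.
#' It secretes nothing.
#'
#' @return a \linkS4class{SpeciesParams}.
#' @examples
#' soralisParams()
#' @export
soralisParams <- function() {
  speciesParams("S.oralis", muMax = 0.32, KSg = 1.756, KSo = 0.192e-3,
                KI = 0.0025, yieldGlucose = -3, yieldOxygen = -2,
                biomassFraction = 0.8, capsuleFraction = 0.2,
                surfactantTolerance = 0.005)
}

#' Lactobacillus paracasei (LB334) default parameters
#'
#' Calibrated growth constants for L. paracasei: muMax 0.153/h, KSg 1.2 g/L,
#' KSo 0.2e-3 g/L, glucose yield -0.17, oxygen yield -1, biomass:capsule
#' 0.9:0.1. It produces both the inhibitor (yield 0.3 g/g) and the
#' surfactant (yield 0.4 g/g) by first-order reactions with k = 0.7/h, and
#' tolerates surfactant up to 0.008 g/L.
#'
#' @return a \linkS4class{SpeciesParams}.
#' @examples
#' lparacaseiParams()
#' @export
lparacaseiParams <- function() {
  speciesParams("L.paracasei", muMax = 0.153, KSg = 1.2, KSo = 0.2e-3,
                yieldGlucose = -0.17, yieldOxygen = -1,
                biomassFraction = 0.9, capsuleFraction = 0.1,
                productionRateK = 0.7, yieldInhibitor = 0.3,
                yieldSurfactant = 0.4, surfactantTolerance = 0.008)
}

#' Default two-species parameter set
#'
#' @return named list with elements \code{S.oralis} and \code{L.paracasei}.
#' @export
defaultSpecies <- function() {
  so <- soralisParams()
  lp <- lparacaseiParams()
  stats::setNames(list(so, lp), c(so@name, lp@name))
}

#' Sphere radius of an agent from its masses
#'
#' @param biomass_fg,capsule_fg masses in fg.
#' @param rhoBiomass,rhoCapsule densities in g/L (= fg/um^3).
#' @return radius in um (vectorized).
#' @export
agentRadius <- function(biomass_fg, capsule_fg, rhoBiomass = 150,
                        rhoCapsule = 75) {
  vol <- biomass_fg / rhoBiomass + capsule_fg / rhoCapsule
  (3 * vol / (4 * pi))^(1 / 3)
}

#' @describeIn SpeciesParams-class compact display
#' @param object a SpeciesParams
#' @export
setMethod("show", "SpeciesParams", function(object) {
  cat("SpeciesParams:", object@name, "\n")
  cat(sprintf("  muMax %.4g /h  KSg %.4g g/L  KSo %.4g g/L  KI %s g/L\n",
              object@muMax, object@KSg, object@KSo,
              ifelse(is.na(object@KI), "-", format(object@KI))))
  cat(sprintf("  yields: glucose %.3g, oxygen %.3g; biomass:capsule %.2g:%.2g\n",
              object@yieldGlucose, object@yieldOxygen,
              object@biomassFraction, object@capsuleFraction))
  if (!is.na(object@productionRateK))
    cat(sprintf("  production k %.3g /h (inhibitor yield %s, surfactant yield %s)\n",
                object@productionRateK,
                ifelse(is.na(object@yieldInhibitor), "-",
                       format(object@yieldInhibitor)),
                ifelse(is.na(object@yieldSurfactant), "-",
                       format(object@yieldSurfactant))))
  if (!is.na(object@surfactantTolerance))
    cat(sprintf("  surfactant tolerance %.3g g/L\n",
                object@surfactantTolerance))
  invisible(NULL)
})
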