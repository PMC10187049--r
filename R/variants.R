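#' Model variants
#'
#' The five model variants: pure competition for glucose, oxygen and space;
#' an independent-carbon-source control (each species consumes its own
#' substrate with identical constants, competing only for space and
#' oxygen); noncompetitive inhibition of S. oralis by a secreted inhibitor;
#' surfactant-driven detachment of periphery cells; and inhibition plus
#' surfactant combined. EPS capsule production is switched off in the
#' surfactant-containing variants.
#'
#' @return character vector of variant names.
#' @examples
#' modelVariants()
#' variantFlags("SURFACTANT")
#' @export
modelVariants <- function() .MODEL_VARIANTS

#' Behavior flags of a model variant
#'
#' Flags are a pure function of the variant name:
#' \code{inhibition_active} (inhibitor field present, S. oralis growth
#' multiplied by KI/(KI+I)), \code{surfactant_active} (surfactant field,
#' periphery detachment, planktonic movement), \code{eps_active} (capsule
#' mass produced; FALSE for the surfactant-containing variants) and
#' \code{shared_carbon} (FALSE only for the independent-substrate control).
#'
#' @param variant variant name, one of \code{modelVariants()}.
#' @return named list of four logicals.
#' @export
variantFlags <- function(variant) {
  variant <- match.arg(variant, .MODEL_VARIANTS)
  list(
    inhibition_active = variant %in% c("INHIBITION", "INHIBITION_SURFACTANT"),
    surfactant_active = variant %in% c("SURFACTANT", "INHIBITION_SURFACTANT"),
    eps_active = !variant %in% c("SURFACTANT", "INHIBITION_SURFACTANT"),
    shared_carbon = variant != "INDEPENDENT_SUBSTRATES"
  )
}

# Which carbon field each species reads: the shared glucose field, or
# substrate1/substrate2 in species order for the independent control.
.speciesCarbon <- function(speciesNames, variant) {
  if (variantFlags(variant)$shared_carbon)
    return(stats::setNames(rep("glucose", length(speciesNames)), speciesNames))
  stats::setNames(paste0("substrate", seq_along(speciesNames)), speciesNames)
}

# Solute field names a variant requires, for a given species set.
.variantFieldNames <- function(speciesNames, variant) {
  fl <- variantFlags(variant)
  nm <- if (fl$shared_carbon) "glucose" else
    paste0("substrate", seq_along(speciesNames))
  nm <- c(nm, "oxygen")
  if (fl$inhibition_active) nm <- c(nm, "inhibitor")
  if (fl$surfactant_active) nm <- c(nm, "surfactant")
  nm
}
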