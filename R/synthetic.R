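.SERIES_CONSTANTS <- data.frame(
  series = c("so34_single", "so34_dual", "lb334_single", "lb334_dual"),
  slope = c(7762, 4665, 4401, -343.8),
  intercept = c(357.8, -795.1, 1034, 2168),
  r2 = c(0.7970, 0.5978, 0.06542, 0.008884),
  stringsAsFactors = FALSE)

#' Linear constants of the in vitro dilution-series responses
#'
#' The four linear regressions of biovolume (um^3) on medium-dilution
#' fraction that summarize the 16-h in vitro dilution series: S. oralis
#' single (y = 7762 x + 357.8) and dual (y = 4665 x - 795.1),
#' L. paracasei single (y = 4401 x + 1034) and dual (y = -343.8 x + 2168),
#' with their reported R^2. The sign of the L. paracasei single R^2 is
#' ambiguous in the source; its magnitude is carried here and is not a
#' generator target.
#'
#' @return data.frame with columns series, slope, intercept, r2.
#' @export
dilutionSeriesConstants <- function() .SERIES_CONSTANTS

#' Noise SD reproducing a given R^2 under the dilution design
#'
#' For additive Gaussian noise on a linear response measured at design
#' points x, the expected coefficient of determination satisfies
#' R^2 = s^2 Var(x) / (s^2 Var(x) + sigma^2) with s the slope, so
#' sigma = |s| sqrt(Var(x) (1 - R^2) / R^2). Population variance of the
#' replicated design is used.
#'
#' @param slope linear slope.
#' @param r2 target coefficient of determination in (0, 1).
#' @param dilutions design points (default the seven-step sweep).
#' @return noise SD in biovolume units.
#' @export
noiseSdForR2 <- function(slope, r2, dilutions = dilutionSweep()) {
  stopifnot(r2 > 0, r2 < 1)
  vx <- mean((dilutions - mean(dilutions))^2)
  abs(slope) * sqrt(vx * (1 - r2) / r2)
}

#' Specification of a synthetic dilution series
#'
#' Emulates the in vitro biovolume-versus-dilution measurements: biovolume
#' = slope x dilution + intercept + Normal(0, sd), floored at 0, at each
#' dilution fraction with n replicates. Named series default to the
#' reported linear constants, with the noise SD solved from the reported
#' R^2 via \code{\link{noiseSdForR2}}.
#'
#' @param series one of "so34_single", "so34_dual", "lb334_single",
#'   "lb334_dual", or NULL to give slope/intercept directly.
#' @param slope,intercept linear response (biovolume units per dilution
#'   fraction / biovolume units).
#' @param sd additive Gaussian noise SD (>= 0).
#' @param dilutions dilution fractions (default the seven-step sweep).
#' @param n replicates per dilution (default 10).
#' @param seed RNG seed used by \code{\link{generateDilutionSeries}}.
#' @return list of class \code{dilutionSeriesSpec}.
#' @examples
#' spec <- dilutionSeriesSpec("so34_single", sd = 0)
#' head(generateDilutionSeries(spec))
#' @export
dilutionSeriesSpec <- function(series = "so34_single", slope = NULL,
                               intercept = NULL, sd = NULL,
                               dilutions = dilutionSweep(), n = 10,
                               seed = 1) {
  if (!is.null(series)) {
    row <- .SERIES_CONSTANTS[.SERIES_CONSTANTS$series == series, ]
    if (!nrow(row)) stop("unknown series: ", series)
    if (is.null(slope)) slope <- row$slope
    if (is.null(intercept)) intercept <- row$intercept
    if (is.null(sd)) sd <- noiseSdForR2(slope, row$r2, dilutions)
  }
  if (is.null(slope) || is.null(intercept) || is.null(sd))
    stop("slope, intercept and sd are required when no named series is used")
  stopifnot(n >= 1, sd >= 0)
  structure(list(series = series, slope = slope, intercept = intercept,
                 sd = sd, dilutions = dilutions, n = n, seed = seed),
            class = "dilutionSeriesSpec")
}

#' Generate a synthetic dilution-series table
#'
#' @param spec a \code{\link{dilutionSeriesSpec}}.
#' @return data.frame with columns dilution, replicate, biovolume
#'   (biovolumes floored at 0); reproducible per spec seed.
#' @export
generateDilutionSeries <- function(spec) {
  stopifnot(inherits(spec, "dilutionSeriesSpec"))
  set.seed(as.integer(spec$seed))
  out <- expand.grid(replicate = seq_len(spec$n), dilution = spec$dilutions)
  out <- out[, c("dilution", "replicate")]
  mu <- spec$slope * out$dilution + spec$intercept
  out$biovolume <- pmax(mu + rnorm(nrow(out), 0, spec$sd), 0)
  rownames(out) <- NULL
  out
}

#' Specification of synthetic biofilm/planktonic well counts
#'
#' Emulates the structure of per-well bacterial enumeration split by
#' species and growth phase (biofilm vs planktonic): counts are drawn
#' lognormally around configured means with a common dispersion.
#'
#' @param means named numeric vector of mean counts; names are
#'   "species.state" pairs, e.g. \code{c("S.oralis.BIOFILM" = 2e6, ...)}.
#' @param dispersion lognormal sdlog (0 = exact means).
#' @param wells number of wells (default 4).
#' @param seed RNG seed.
#' @return list of class \code{wellCountSpec}.
#' @export
wellCountSpec <- function(means, dispersion = 0.5, wells = 4, seed = 1) {
  stopifnot(all(means >= 0), wells >= 1, dispersion >= 0)
  structure(list(means = means, dispersion = dispersion, wells = wells,
                 seed = seed), class = "wellCountSpec")
}

#' Generate a synthetic well-count table
#'
#' Counts are lognormal with median equal to the configured mean stratum
#' count (exact at dispersion 0); zero-mean strata stay exactly zero.
#'
#' @param spec a \code{\link{wellCountSpec}}.
#' @return data.frame with columns well, species, state, count.
#' @export
generateWellCounts <- function(spec) {
  stopifnot(inherits(spec, "wellCountSpec"))
  set.seed(as.integer(spec$seed))
  strata <- strsplit(names(spec$means), ".", fixed = TRUE)
  species <- vapply(strata, function(s) paste(head(s, -1), collapse = "."),
                    character(1))
  state <- vapply(strata, function(s) s[length(s)], character(1))
  out <- do.call(rbind, lapply(seq_len(spec$wells), function(w) {
    cnt <- ifelse(spec$means > 0,
                  spec$means * rlnorm(length(spec$means), 0,
                                      spec$dispersion), 0)
    data.frame(well = w, species = species, state = state, count = cnt,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-well percentage transform of a count table
#'
#' Expresses each species x state count as a percentage of the total
#' bacteria in its well; each well's percentages sum to 100.
#'
#' @param counts data.frame from \code{\link{generateWellCounts}}.
#' @return the table with an added \code{percent} column.
#' @export
wellPercentages <- function(counts) {
  tot <- tapply(counts$count, counts$well, sum)
  counts$percent <- 100 * counts$count / as.numeric(tot[as.character(counts$well)])
  counts
}
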