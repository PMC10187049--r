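---
title: "An individual-based model of S. oralis / L. paracasei biofilm interactions"
author: "biofilmIBM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based model of S. oralis / L. paracasei biofilm interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmIBM)
```

## The biological question

*Streptococcus oralis* is an early oral colonizer and accessory pathogen;
*Lactobacillus paracasei* is a commensal with probiotic, biofilm-antagonistic
properties. When the two grow together in a biofilm, *S. oralis* reaches a
much lower biomass than it does alone — more than plain competition for
nutrients and space can explain. This package implements a family of
three-dimensional individual-based (agent-based) biofilm models that encode
competing mechanistic hypotheses for that antagonism, so their quantitative
consequences can be compared:

* **COMPETITION** — the null model: both species compete only for glucose,
  oxygen, and space.
* **INDEPENDENT_SUBSTRATES** — a control in which each species consumes its
  own private carbon source (`substrate1`, `substrate2`) with identical
  constants, isolating competition for space and oxygen.
* **INHIBITION** — *L. paracasei* secretes a diffusible inhibitor
  (a bacteriocin-like product) that slows *S. oralis* growth by
  noncompetitive kinetics.
* **SURFACTANT** — *L. paracasei* secretes a biosurfactant; periphery cells
  of both species detach and become planktonic where its local concentration
  exceeds a species-specific tolerance.
* **INHIBITION_SURFACTANT** — both mechanisms together.

## Model structure

### Agents

Each cell is a sphere with a biomass mass and an EPS capsule mass
(femtograms). Densities convert mass to volume (150 g/L for biomass,
75 g/L for capsule; 1 g/L = 1 fg/µm³), giving the radius

r = (3 (m_b/ρ_b + m_c/ρ_c) / 4π)^(1/3).

Cells grow, divide when their radius reaches 1 µm, shove each other apart
to resolve overlaps, and (in surfactant variants) detach into a planktonic
state. The growth of a cell with biomass X follows dual-substrate Monod
kinetics on glucose (S_g) and oxygen (S_o):

dX/dt = µ_max · S_g/(K_Sg + S_g) · S_o/(K_So + S_o) · X

with each half-saturation constant K_S defined as the substrate
concentration at which growth is half-maximal. In the inhibition variants,
the *S. oralis* rate carries the extra noncompetitive factor
K_I/(K_I + I), equal to ½ when the inhibitor concentration I equals K_I.

Produced mass splits between biomass and capsule by a fixed per-species
ratio (0.8:0.2 for *S. oralis*, 0.9:0.1 for *L. paracasei*). In the
surfactant-containing variants EPS production is switched off and all
produced mass goes to biomass, matching the software lineage those runs
emulate.

### Species parameters

`soralisParams()` and `lparacaseiParams()` carry the calibrated constants
used throughout:

| parameter | S. oralis | L. paracasei | units |
|---|---|---|---|
| µ_max | 0.32 | 0.153 | 1/h |
| K_Sg | 1.756 | 1.2 | g/L |
| K_So | 0.192e-3 | 0.2e-3 | g/L |
| K_I | 0.0025 | — | g/L |
| yield glucose | −3 | −0.17 | g/g |
| yield oxygen | −2 | −1 | g/g |
| biomass:capsule | 0.8:0.2 | 0.9:0.1 | — |
| production k | — | 0.7 | 1/h |
| inhibitor yield | — | 0.3 | g/g |
| surfactant yield | — | 0.4 | g/g |
| surfactant tolerance | 0.005 | 0.008 | g/L |

Yields are growth-coupled (rate = yield · µ · X; negative = consumed).
Inhibitor and surfactant production are **first-order in producer biomass**
(rate = yield · k · X), independent of the growth rate — the production
reaction is specified only by its rate constant and yield, and first-order
kinetics in biomass is the simplest reading consistent with it. The
inhibitor is neither degraded nor consumed; it accumulates and diffuses.

### Domain and solute fields

The domain is a 136 × 136 × 136 µm box (18,496 µm² of substratum)
discretized into 8 µm voxels: the substratum (z = 0) is a zero-flux wall,
lateral faces are periodic, and the top connects to a well-mixed bulk.
The 8 µm default resolution exceeds the largest cell diameter, keeps the
solver fast, and halving it changes 16-h biovolumes by well under 10%
(checked in the test suite); it is configurable.

Nutrients (glucose, oxygen, the independent substrates) are solved at
**pseudo-steady state** every step — the standard separation of time scales
between reaction–diffusion and growth. The discrete equation
D∇²S + r(S) = 0 is solved by Gauss–Seidel sweeps with successive
over-relaxation (ω = 1.7) and Picard re-linearization of the Monod sinks
(r(S) = Σ V_max S/(K+S), one saturable group per species, so the two
species' different K_Sg values coexist in one solve). Voxels whose centers
lie more than one boundary-layer thickness (default 40 µm) above the
biofilm front are clamped to the bulk concentration; the solve converges
when the normalized residual falls below 1e-6. Sinks re-linearized this way
can never drive concentrations negative.

The secreted inhibitor and surfactant instead **accumulate**: they get an
explicit transient diffusion step with first-order volumetric sources and
zero-flux boundaries top and bottom (sub-stepped internally to satisfy the
FTCS stability bound, so any global step size is safe and total mass is
conserved to machine precision). Treating the top as zero flux — no washout
into the bulk — is an assumption: the monotone rise of both secreted
concentrations past their thresholds over the run is only reproducible
without a sink. A consequence is that threshold crossings here occur
earlier in the run than the mid-run crossings the original figures show;
the comparisons between variants, which is what the package is for, are
unaffected. Diffusivities of the secreted solutes default to the glucose
value (2.1e4 µm²/h; oxygen 7.2e4 µm²/h), textbook orders of magnitude, all
configurable.

### The step loop

Each global step of `dt = 0.05` h executes, in fixed order: nutrient
solves → transient step of secreted solutes → growth (exact exponential
X·e^{µ dt} with µ frozen at the step start, which removes the
linearization error of an Euler update; the frozen-µ error is second order
at these rates) → divisions → shove relaxation → surfactant detachment →
planktonic movement. The step size is small against the fastest doubling
time (ln 2 / 0.32 ≈ 2.2 h).

Division splits a cell's masses by a uniform 0.45–0.55 ratio (mass
conserved exactly) and places the daughters a half-sum of radii apart in a
uniformly random direction. Shoving pushes overlapping pairs apart along
their center line, half the overlap each, sweeping in ascending agent-id
order until the largest overlap is below 0.01 µm — deterministic given the
RNG stream, like every other rule. Coincident centers (a degenerate case)
split vertically.

### Detachment and planktonic cells

A biofilm cell is on the **periphery** if its voxel has at least one
biomass-free voxel in its 26-neighborhood or touches the domain top
(below the substratum counts as occupied). Each step, every periphery cell
whose local surfactant concentration **strictly exceeds** its species'
tolerance (detachment happens when the concentration becomes higher than
the threshold, so exact equality does not trigger) becomes planktonic and
is relocated to a uniform random position in the boundary-layer band just
below the bulk. Planktonic cells take isotropic 5 µm random steps,
reflected at the band's top and bottom, and never rejoin the biofilm.

Planktonic cells are **metabolically inert** by default: they do not grow,
consume, or produce. The study design tracks them only as counts, and
keeping them inert avoids inventing planktonic kinetics — but it biases
planktonic cell sizes and any planktonic biovolume low, so planktonic
output should be read as counts, not mass. A `planktonicGrowth` setting
turns growth back on for sensitivity checks. Similarly, generic
erosion/shear detachment exists behind an `erosionRate` setting but is off
in all five variants: the models attribute all detachment to the
surfactant. Cell death is likewise a stub that is off by default — the
rule set names it, but no death parameters exist to parameterize it.

### Seeding and replicates

Runs start from 176 cells (88 of each species in dual runs) at uniform
random positions on the substratum, with birth biomass uniform between 50%
and 100% of the division mass. The seeding statements in the source
conflict slightly (an areal density of 0.01 cells/µm² of each species
versus 176 cells total); the explicit counts are treated as authoritative.
Replicate i of a batch runs with seed base + i − 1; five replicates for
the competition and inhibition models and fifty for surfactant models
bring the coefficient of variation (100·SD/mean) of final per-species
biovolumes under 10% — in practice the competition-model CV here is 1–2%.

## Calibration

`dilutionResponse()` reruns the glucose dilution sweep of the original
calibration: 16-h single-species runs at glucose 2, 1.5, 1, 0.5, 0.2, 0.1
and 0.02 g/L (dilution fractions of the 2 g/L full-strength medium; oxygen
is never diluted). `bisectionFit()` adjusts µ_max or K_Sg — one at a time,
within biologically relevant brackets (µ_max ∈ [0.05, 1] 1/h,
K_Sg ∈ [0.01, 5] g/L) — until the **normalized slope** (OLS slope of
biovolume on dilution fraction, divided by the full-strength biovolume)
matches a target. Normalizing makes the objective insensitive to the
absolute biovolume units of the measuring instrument, which differ between
confocal image segmentation and simulation. Every objective evaluation
reuses the same replicate seeds (common random numbers), so bisection sees
a deterministic function.

Two practical caveats, both discovered by running the machinery. First,
the normalized slope is only monotone in K_Sg when the dilution design
spans the response: with very sparse designs (e.g. three points including
a near-zero dilution) the inoculum-biovolume floor compresses the low end
and the objective can peak inside the bracket. The full seven-point sweep
is monotone across the default bracket; `checkMonotone = TRUE` probes a
coarse grid first and aborts with a diagnostic if bisection's premise
fails. Second, the bracket endpoints must straddle the target
(opposite-signed objective), which the fitter verifies before iterating.
Self-consistency is tested at full scale: forward data generated at
K_Sg = 1.2 are recovered by bisection to within 2%.

## The synthetic-experiment generator

No laboratory data ship with the package, so `generateDilutionSeries()`
emulates the structure of the in vitro dilution-series measurements: a
linear biovolume response on dilution fraction with additive Gaussian
noise, floored at zero, at the seven sweep fractions with n = 10
replicates each. The four named series carry the reported linear constants
(e.g. *S. oralis* single: y = 7762·x + 357.8). The default noise SD is
solved from the reported R² through
σ = |slope|·sqrt(Var(x)·(1−R²)/R²), so refitting generated tables
reproduces the reported R² on average (verified over 200 seeds in the
suite). Two caveats: the reported R² of the *L. paracasei* single series
has an ambiguous sign in the source, so its magnitude is used and never
targeted; and the zero-floor slightly truncates the noise at the lowest
dilutions, which biases the mean refit slope a few percent below the
configured slope at the default noise level. The generator emulates the
linear response and replicate scatter only — not image-segmentation
artifacts, well-to-well covariance, or qPCR chemistry — so passing tests
validate the calibration and postprocessing machinery, not any claim
about real biofilms. `generateWellCounts()` similarly emulates per-well
biofilm/planktonic count tables (lognormal around configured means, with
a percentage-of-well transform).

## Observables

`biovolume()` sums agent sphere volumes (capsule included by default;
excludable) without overlap deduplication — after shoving, residual
overlaps are below the 0.01 µm tolerance, and voxelized alternatives
differ by a few percent. Planktonic cells are excluded from biovolume and
thickness but included in counts, mirroring the biofilm/planktonic split
of the well-count data. `biofilmThickness()` is the mean over occupied
(x, y) columns of the per-column maximum of z + r. `replicateCV()` and
`dilutionRegression()` provide the replicate statistics; group-comparison
statistics (e.g. Games–Howell) are deliberately out of scope — summaries
export as tidy CSV for any statistics tool.

## Problem sizes in the tests

The unit suite runs scaled-down conditions (64 µm domain, 20–40 cells,
0.25–4 h) chosen to exercise every rule in seconds; the acceptance suite
runs the full study conditions — 136 µm domain, 176 cells, 16 h — with 5
replicates for competition-class comparisons and 10 for the
surfactant-class ones, a deliberate scale-down from the 50 used for the
original surfactant statistics that keeps the coefficient of variation
criterion testable in minutes.

## Known limitations

* Cells are spheres; rod or filament morphologies are not represented.
* No pH dynamics (the acidification the species cause in culture is not a
  modeled mechanism), no advection, no EPS particles distinct from the
  per-cell capsule.
* Planktonic inertness (above) biases planktonic biomass low.
* The zero-washout assumption for secreted solutes makes their absolute
  concentrations and threshold-crossing times upper bounds / early bounds
  respectively; cross-variant comparisons are the supported use.
* Biovolume units are simulation µm³; comparisons with imaged biovolumes
  should use normalized quantities, as the calibration objective does.
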