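Package: biofilmIBM
Title: Individual-Based Modeling of Dual-Species Oral Biofilms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Three-dimensional individual-based (agent-based) simulation of
    single- and dual-species biofilms of Streptococcus oralis and
    Lactobacillus paracasei. Cells grow by dual-substrate Monod kinetics on
    glucose and oxygen solved at pseudo-steady state on a voxel grid, divide,
    shove, and excrete an extracellular capsule. Model variants add an
    independent-carbon-source control, noncompetitive growth inhibition of
    S. oralis by a secreted inhibitor, and biosurfactant-driven detachment of
    periphery cells into a planktonic state. Includes replicate batches with
    coefficient-of-variation summaries, biovolume/count/thickness
    postprocessing, bisection calibration of growth parameters against a
    medium-dilution response, and a synthetic-experiment generator for
    dilution-series biovolumes and well count tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
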