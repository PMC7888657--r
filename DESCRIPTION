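Package: fixcascade
Title: Dual-Sensor Oxygen Regulation Cascade Modelling for Rhizobia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary differential equation modelling of the hFixL-FxkR-FixK /
    FnrN oxygen-sensing cascade that controls microaerobic and symbiotic gene
    expression in Rhizobium leguminosarum bv. viciae 3841. Provides the
    five-species cascade model with Hill-type oxygen sensing and competitive
    anaerobox occupancy, steady-state and bifurcation analysis over dissolved
    oxygen sweeps, detection of bistable windows, knockout scenario simulation
    and mutant/wild-type expression ratios, calibration of kinetic parameters
    to reporter-fusion ratio data, Langevin ensemble simulation of stochastic
    commitment to the high-expression state, a synthetic plate-reader /
    bacteroid reporter data generator, and a promoter motif scanner for
    anaerobox and K-box operators with TSS-relative coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    deSolve,
    lhs,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    jsonlite
Config/testthat/edition: 3
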