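Package: nematox
Title: Metal Mixture Toxicity and Population Dynamics in Caenorhabditis
    elegans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing single-metal and mixture toxicity
    experiments with the nematode Caenorhabditis elegans. Fits and inverts
    two-parameter log-logistic dose-response curves (ECx/LCx estimation),
    predicts mixture effects under Concentration Addition and Independent
    Action and classifies observed mixture effects as additive,
    antagonistic or synergistic by exact signed-rank comparison against
    both model predictions. Reconstructs whole-population abundances from
    serially diluted well counts, computes trapezoid-rule area-under-curve,
    maximum and end population endpoints with the associated parametric and
    rank-based group comparisons, and ships a stage-structured stochastic
    simulator of C. elegans populations under metal exposure, including a
    phenomenological concentration-dependent protective interaction of Zn
    on Cd toxicity, for generating synthetic experiments and validating the
    analysis chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    multcomp,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
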