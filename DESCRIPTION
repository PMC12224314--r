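Package: pellicca
Title: Substrate Discrimination and Protein-Microbe Association for
    Salivary Pellicle Multi-Omics
Version: 0.1.0
Authors@R:
    person("Pellicca", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical pipeline for relating salivary-pellicle protein
    intensities to oral microbial adhesion across dental substrates
    (dentine, enamel, titanium). Implements detection-limit imputation by
    Pearson-skewness minimization, an offset-log transform for
    zero-inflated abundances, per-feature Kruskal-Wallis screening with
    shrinkage-regularized linear discriminant analysis, substrate-matched
    Cartesian pairing of unpaired experiments, Pearson and
    mutual-information association, regularized canonical correlation
    analysis with interset/intraset structure correlations, and supporting
    diversity statistics (Shannon, Bray-Curtis, PCoA, log2 median
    proportion ratios). Ships a synthetic-data generator with planted
    substrate effects and signed protein-to-microbe couplings for
    parameter-recovery testing, plus a command-line pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
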