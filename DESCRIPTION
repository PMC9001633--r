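Package: divscape
Title: Tip Speciation Rates, Gridded Phylogenetic Endemism, and
    Climate-Niche Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A comparative-phylogenetics toolkit linking lineage
    diversification, geography, and climate-niche evolution. Computes
    equal-splits tip speciation rates (the DR statistic) and species ages;
    builds presence-absence matrices on regular longitude-latitude grids
    and maps species richness, Faith's phylogenetic diversity, and
    DR-quartile richness residuals; classifies centres of neo- and
    paleo-endemism (CANAPE) with curveball randomization nulls;
    summarises species climate niches by correlation-matrix PCA with
    broken-stick axis retention and relative climate-stability surfaces;
    fits single- and multi-rate Brownian-motion models of niche evolution
    over stochastic character maps with AICc model averaging; computes
    disparity-through-time curves with resampled null envelopes and
    traitgrams; and tests trait-speciation-rate associations with the
    simulation-based ES-sim procedure. A seeded synthetic-data generator
    (birth-death trees, Mk discrete traits, gradient-plus-noise climate
    landscapes, niche-driven occurrences) makes every stage testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    phytools,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
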