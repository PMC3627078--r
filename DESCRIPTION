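Package: pgpr
Title: Phylogenetic Gaussian Process Regression for Function-Valued Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and inference for function-valued traits (curves)
    evolving on a phylogeny. Curves are modelled as linear mixtures of a small
    set of basis functions whose mixing coefficients evolve independently as
    stationary Ornstein-Uhlenbeck Gaussian processes indexed by the tree, with
    additional non-phylogenetic (within-species) variation at extant taxa.
    Provides a generative simulator on random or user-supplied phylogenies;
    source separation of tip curves by principal component analysis followed by
    an independent component rotation (cumulant-based or fixed-point); maximum
    likelihood estimation of the per-component hyperparameters (phylogenetic
    standard deviation, characteristic length-scale, non-phylogenetic standard
    deviation) with bootstrap aggregation over random subtrees; and Gaussian
    posterior reconstruction of ancestral curves with pointwise uncertainty
    bands, together with a phylogenetically aware estimate of the trait
    autocovariance function.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    lhs,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
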