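Package: symbionet
Title: Phylogeny-Informed Analysis of Coral-Symbiodiniaceae Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds frequency-weighted bipartite networks from coral-symbiont
    association records and analyses them with phylogenetic comparative methods.
    Provides Barber bipartite modularity with a stochastic stitch optimizer and
    marginal-preserving null models, Olesen c/z node-role classification,
    per-coral assemblage statistics (rarefied richness, Bluethgen d', Bray-Curtis
    and unweighted UniFrac beta diversity, thermotolerance summaries), Pagel's
    lambda, phylogenetic generalized least squares, simulation-based phylogenetic
    ANOVA, Firth-type phylogenetic logistic regression, permutation t tests on
    phylogenetic distances, metahaplotype sensitivity analysis, and a synthetic
    data generator with planted module structure and known trait signal for
    ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    igraph,
    vegan,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phytools,
    picante,
    nlme,
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
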