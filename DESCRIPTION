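Package: cladeshift
Title: Tree Imbalance and Diversification-Rate Shift Detection on
    Composite Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for topology-based diversification analysis of
    species-level phylogenies. Builds complete composite trees by
    grafting species without molecular data onto the most recent common
    ancestor of their closest sampled relatives, treats polytomies as
    soft via random equal-rates Markov (ERM) resolutions, tests
    whole-tree imbalance with four symmetry indices (Colless IC, mean
    and standard deviation of nodal ERM log-probabilities, B1) against
    Monte-Carlo ERM null distributions, scans every internal branch for
    diversification-rate shifts with a likelihood-ratio delta statistic
    on local three-clade triplets, and summarizes absolute shift
    statistics by geological epoch on a dated tree with one-way ANOVA
    and Tukey HSD comparisons. Includes generators for ERM/Yule trees,
    dated trees with planted rate shifts, and nested taxonomies with
    partial species sampling, so every stage of the pipeline can be
    exercised with simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
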