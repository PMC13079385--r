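Package: rnapal
Title: RNA Palindromes and Homotypic Clustering Propensity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying RNA self-recognition through self-complementary
    (palindromic) regions. Implements a nearest-neighbor thermodynamic model
    with single-strand and multi-strand partition functions, equilibrium base-pair
    probabilities, stochastic structure sampling and region accessibility;
    enumeration and free-energy scoring of palindromes and complementary region
    pairs; homomultimer free energies with single-species mass-action cluster-size
    distributions; a nonequilibrium, accessibility-weighted binding score for
    initial contacts between folded RNAs; and seeded in-silico experiment
    pipelines comparing homodimer versus heterodimer formation, multimerization
    propensity, and palindrome weights across random or user-supplied sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
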