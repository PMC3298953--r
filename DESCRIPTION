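Package: rescueval
Title: Evaluation of Genetic Management in Supplemented Wildlife Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate genetic-rescue supplementation experiments in
    reintroduced wildlife populations, developed around the bighorn sheep
    (Ovis canadensis) study design of two resident herds supplemented with
    ewes from a genetically diverse source herd. Provides a Bayesian
    six-category classifier of descent (pure resident, pure supplemented,
    F1, F2 and the two backcrosses) for multilocus codominant genotypes with
    a mitochondrial-haplotype override, power assessment of the classifier
    on simulated hybrids, stochastic age-structured demographic simulation
    to bound hybrid lamb survival as a screen for outbreeding depression,
    microsatellite and mitochondrial diversity statistics (observed and Nei
    unbiased expected heterozygosity, rarefacted allelic richness, exact
    Hardy-Weinberg tests, pairwise relatedness with bootstrap confidence
    intervals, haplotype diversity and mean pairwise nucleotide
    differences), and a synthetic-data generator that produces study-shaped
    inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
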