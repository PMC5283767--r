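Package: resistmix
Title: Two-Locus Population Genetics of Insecticide Resistance Under
    Mixture and Sequential Deployment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic two-locus, two-sex population-genetic model of the
    evolution of insecticide resistance in mosquito populations. Mosquitoes
    encounter one of nine exposure 'niches' defined by the absence, low or
    high concentration of each of two insecticides; genotype fitnesses are
    built from per-insecticide effectiveness, dominance, resistance
    restoration and fitness-cost parameters, and genotype frequencies are
    iterated through selection, Mendelian gamete production with
    recombination (tracking coupling and repulsion double heterozygotes) and
    random union of gametes. On top of the recursion the package implements
    the operational comparison of insecticide deployment strategies
    (sequential use, mixtures, and adaptive mixtures with threshold-based
    switching) and a global sensitivity analysis: Monte Carlo parameter
    sampling, partial rank correlation coefficients, classification trees,
    and linear decision boundaries separating parameter regions that favour
    mixtures from those that favour sequential use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    rpart,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
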