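Package: mfselector
Title: Monotonic Feature Selection for Staged Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ranks genes by how monotonically their expression rises or
    falls across an ordered series of stages (time points, differentiation
    states, disease grades). The core statistic is the total discriminating
    error (DE_total): at each level k a horizontal discriminating line is
    placed at one sample's expression value to separate stages 1..k from
    the rest, and DE_total sums the misclassified samples over all N-1
    levels, charging each sample at most once so that outliers do not
    dominate. Permutation p- and q-values, a noise-perturbation stability
    index (SVDE) for breaking ties among equally monotone genes, a Cuzick
    rank trend test as comparator, a nine-archetype synthetic benchmark
    generator, and a command-line interface are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
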