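Package: keysteps
Title: Evolutionary Rate of Diagnostic Characters and Their Utility in
    Interactive Identification Keys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links the evolutionary rate of discrete taxonomic characters,
    measured as parsimony steps on a phylogeny, to their diagnostic utility
    in an interactive identification key ranked by a "Best"-style evenness
    score. Provides Fitch/Hartigan-type parsimony step counting on rooted
    trees with polytomies, polymorphic and missing states, consistency and
    retention indices, an interactive-key elimination engine with greedy
    identification paths, Mk-model character and alignment simulators on
    ultrametric Yule trees, and an end-to-end study pipeline correlating
    steps with key rank (Spearman, exact or permutation p-values), overall
    and stratified by state count.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
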