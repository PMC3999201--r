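Package: lineaburst
Title: Species Delimitation and Diversification-Rate-Shift Analysis on
    Time-Calibrated Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delimiting putative species from single-locus
    alignments and chronograms, and for detecting shifts in diversification
    rate on the resulting species trees.  Implements Kimura 2-parameter
    distances with pairwise deletion, a wildcard-aware deduplication filter,
    similarity-threshold clustering, single- and multiple-threshold GMYC
    (general mixed Yule coalescent) fitting, piecewise-constant pure-birth
    and constant birth-death model selection with a simulated critical
    delta-AIC, posterior-ensemble shift summaries, lineage-through-time
    curves, and Magallon-Sanderson net diversification estimators.  A
    seeded synthetic-data generator (Yule, rate-shifted Yule, birth-death
    and multispecies-coalescent trees; GTR+Gamma sequences) provides
    ground-truthed inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    phangorn,
    seqinr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
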