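Package: metcensus
Title: Census of Methionine-Rich Prion-Like Domains in Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterises methionine-rich prion-like domains
    (MR-PrLDs) across a proteome. Implements a transect-based spatial
    statistic for methionine clustering with per-protein empirical null
    distributions, a four-criterion MR-PrLD caller combining a
    compositional-bias scan with a two-state hidden Markov model
    prion-likeness posterior and exact binomial scoring, a terminal
    alpha-carbon compactness index with matched resampling nulls, and a
    GO-similarity network analysis based on Newman's nominal assortativity
    with relabeling and resampling permutation controls. Ships synthetic
    generators for proteomes, alpha-carbon traces and GO annotations so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
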