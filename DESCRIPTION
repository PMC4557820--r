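Package: structsignal
Title: Structure-Partitioned Phylogenetic Signal Assessment for Ribosomal DNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for assessing phylogenetic signal in ribosomal DNA
    alignments annotated with secondary structure. Reads dot-bracket
    structure masks, partitions alignments into stem, loop and
    ambiguously aligned (RAA) classes, and provides per-partition
    diagnostics: nucleotide composition with tetrahedral simplex
    coordinates, chi-squared stationarity tests, Spearman GC-length
    correlation, and an entropy-based index of substitution saturation
    with simulation-derived critical values. Ambiguously aligned regions
    are rescued by per-block progressive affine-gap alignment under
    posterior guide trees followed by Monte-Carlo random-similarity
    masking. Tree-side signal assessment includes likelihood mapping of
    quartets under GTR+Gamma, consensus-network split systems,
    internode-certainty indices (IC, ICA, TC, TCA), a Bayesian
    relative-rates test on posterior tree samples, and
    marginal-likelihood-proxy model comparison (harmonic mean, AICM)
    from MCMC traces. A seeded synthetic-data generator produces
    structured alignments, tree sets and traces with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
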