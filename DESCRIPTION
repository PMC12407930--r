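Package: dndsim
Title: Codon-Level Mutagenesis Simulation and dN/dS Estimation Under
    Nucleotide Substitution Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates codon-level mutagenesis and computes dN/dS (omega)
    under pluggable nucleotide substitution models (JC69, K2P, K3P, F81,
    HKY85). Two simulation algorithms are provided: an exhaustive,
    model-weighted scan of every single-base change in a protein-coding
    sequence, and a context mode that builds codons around VCF variant
    positions from reference flanking bases and draws mutations from the
    model to form null dN/dS distributions. Includes synonymous and
    nonsynonymous site counting with stop-change exclusion, empirical
    percentile comparison of an observed omega against a simulated null,
    cross-model distribution comparison, synthetic fixture generators,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    vcfR,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
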