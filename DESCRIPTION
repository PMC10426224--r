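Package: safescreen
Title: Tiered Allergenicity and Toxicity Sequence Screening for Transgenic Products
Version: 0.1.0
Authors@R:
    person("safescreen", "developers", email = "safescreen@example.org",
           role = c("aut", "cre"))
Description: A tiered bioinformatic screen of transgene-expressed products
    against allergen, toxin and microRNA reference sets, as used in
    environmental risk assessment of genetically modified organisms.
    Implements exact Smith-Waterman/Gotoh local alignment with affine gaps
    and BLOSUM scoring, the Codex Alimentarius 35%-identity-over-80-residue
    cross-reactivity rule, sliding 80-mer window searches, exact 8-mer
    linear-epitope scanning, Karlin-Altschul E-value gating, and a
    guide-RNA versus microRNA nucleotide screen. A seeded decoy-database
    generator with planted homologous segments, planted epitopes and
    dinucleotide-shuffled RNA decoys makes every screening stage testable
    without external database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    optparse,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
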