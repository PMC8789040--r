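Package: pdselex
Title: Simulation and Analysis of Library-vs-Library RNA-Protein Selections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for library-vs-library in vitro selection experiments in
    which an RNA pool and a phage-displayed protein pool are co-enriched as
    complexes (PD-SELEX). Provides degenerate-codon (NNK) library statistics
    and IUPAC motif matching; a seeded stochastic simulator of two-step
    affinity-purification selection rounds emitting per-round pools and
    FASTQ reads; round-to-round enrichment-factor analysis with monotonic
    filtering, diversity binning, consensus-motif fractions and positional
    residue preferences; re-selection deconvolution that assigns RNA motif
    subsets to cognate proteins; and 1:1 Langmuir surface plasmon resonance
    kinetics with double referencing, global fitting, replicate aggregation
    and binding-selectivity matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    withr
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
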