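Package: mitocomp
Title: Comparative Analysis of Annotated Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative mitogenomics of small circular genomes
    such as arthropod mitochondria: GenBank flat-file input and output with
    strand-aware gene extraction on circular coordinates, base composition
    and AT/GC skew by region, codon-usage bias under the invertebrate
    mitochondrial code (RSCU, effective number of codons, ENC-GC3 and
    neutrality plots), sliding-window nucleotide diversity, pairwise
    distances under nested substitution models, Nei-Gojobori Ka/Ks,
    gene-order rearrangement analysis under the tandem
    duplication-random loss model, tandem-repeat detection in control
    regions, and a synthetic annotated-mitogenome generator with a
    codon-level divergence simulator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
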