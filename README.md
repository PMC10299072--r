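# mitocomp

Comparative analysis of small circular mitochondrial genomes in R, built
around the analyses typically run on newly sequenced arthropod (e.g.
jumping spider) mitogenomes: a 13 protein-coding gene (PCG) + 22 tRNA +
2 rRNA + control-region (CR) architecture on two strands, extreme AT
richness, strand-asymmetric composition, strong codon-usage bias, tRNA
gene rearrangements, and tandem repeats in the control region.

The package provides, as plain R functions over plain-text formats:

* **GenBank I/O** — parse and write annotated mitogenomes with circular
  0-based coordinates, a gene-name synonym map (COI/COX1/CO1 → `cox1`),
  strand-aware gene extraction, and start/stop codon validation
  (canonical ATN/TTN starts, truncated `T`/`TA` stops completed by
  polyadenylation).
* **Composition** — base counts, AT/GC content and the strand skews
  AT-skew = (A−T)/(A+T), GC-skew = (G−C)/(G+C), per region (whole
  genome, PCGs by codon position, tRNAs, rRNAs, CR).
* **Codon usage** — codon counting under the invertebrate mitochondrial
  code (translation table 5; 62 sense codons), RSCU, Wright's effective
  number of codons generalized to the table-5 family structure
  (12 twofold, 6 fourfold, 1 sixfold, 1 eightfold family; ENC ∈ [20, 62]),
  the no-selection expectation curve ENC = 2 + s + 29/(s² + (1−s)²) for
  an ENC–GC3 plot, and the neutrality regression of GC12 on GC3 whose
  slope partitions codon-composition evolution into mutational (slope)
  and selective (1 − slope) shares.
* **Divergence** — sliding-window nucleotide diversity (Pi; 100-bp
  window, 25-bp step by default, DnaSP-style complete deletion),
  pairwise distances under p/JC69/K2P/TN93 and a pooled-frequency
  composite TN93 (`MCL-composite`), Nei–Gojobori (1986) Ka/Ks with
  pathway averaging and Jukes–Cantor correction, and neighbor-joining
  trees.
* **Gene order** — signed circular gene orders, rearrangement calls
  against a reference order (tRNA shuffle vs translocation, PCG move,
  inversion), and a minimal-event bound under the tandem
  duplication–random loss (TDRL) model:
  `ceil(log2(descent runs))`, minimized over rotations.
* **Tandem repeats** — a self-contained detector for control regions
  (period, fractional copy number, consensus, partial copies) with
  TRF-style +2/−7 scoring, plus a brute-force oracle.
* **Synthetic data** — a generator of fully annotated, parameter-known
  mitogenomes (composition, GC3/GC12, ENC concentration, TDRL events,
  CR repeats) and a codon-level divergence simulator with tunable
  ω = Ka/Ks and transition bias κ, so every analysis can be validated by
  parameter recovery without downloading anything.
* **Pipeline** — `run_pipeline()` turns a directory of GenBank files
  (plus optional codon-aware alignments) into the full TSV/Newick/BED
  table bundle with a JSON manifest;
  `inst/scripts/mitocomp-pipeline.R` is a thin CLI wrapper.

## Worked example

```r
library(mitocomp)

# a jumping-spider-like synthetic genome: 74% AT, AT skew -0.12,
# GC skew +0.36, GC3 = 0.12, a 24-nt CR repeat
g <- generate_mitogenome(synthetic_spec(seed = 42))
base_composition(g$sequence, "full")[, c("at_content", "at_skew", "gc_skew")]
#>   at_content at_skew gc_skew
#> 1     0.7402 -0.1192  0.3578

codon_bias_summary(g)
#>      genome n_codons     enc       gc1       gc2       gc3      gc12
#> 1 SYN000001     3586 31.8429 0.2805354 0.3173452 0.1221417 0.2989403

find_tandem_repeats(extract_gene_sequence(g, "CR"))[, 1:6]
#>   start end period copy_number                consensus identity
#> 1   324 475     24    6.291667 TATTAGGTATAATTACAATTATTA        1
```

The composition realizes its targets to ~0.003; the ENC of 31.8 matches
the value implied by the generating codon distribution (31.83); the
inserted 24-nt tandem repeat is recovered with its exact period. The
neutrality arithmetic used throughout the field is a one-liner: a GC12~GC3
slope of 0.249 means a 24.9% mutational and 75.1% selective share.

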