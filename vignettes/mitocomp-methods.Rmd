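---
title: "Methods and design notes for mitocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

mitocomp implements the comparative analyses that are routinely applied
to newly assembled animal mitochondrial genomes — composition and
strand-skew profiling, codon-usage bias, nucleotide diversity and
divergence, gene-order rearrangement analysis, and control-region
tandem-repeat detection — together with a synthetic-genome generator
that makes every one of those analyses testable by parameter recovery.
This vignette records the models, the conventions, and the design
decisions that were genuinely open.

## Coordinates, strands and gene names

Mitogenomes are circular; internally every feature is stored 0-based,
half-open, on the linearized majority (J) strand, and a feature whose
`end <= start` wraps the origin and is interpreted modulo the genome
length. GenBank's 1-based inclusive coordinates (and
`complement(join(...))` locations) exist only at the I/O boundary, so
interval arithmetic never carries an off-by-one. The linearization
anchor is configurable and defaults to `cox1`; every reported statistic
is rotation-invariant, so the anchor is cosmetic.

Deposited records are inconsistent in gene naming (COX1/COI/CO1,
ND4L/nad4L, 12S/s-rRNA, tRNA-Leu(UUR)/trnL2 ...), so normalization is
data, not code: a packaged synonym table
(`inst/extdata/gene_synonyms.tsv`) maps labels, case- and
punctuation-insensitively, to the canonical symbols `cox1..cox3`,
`nad1..nad6`, `nad4L`, `atp6`, `atp8`, `cytb`, `trnX` (with
`trnL1/trnL2`, `trnS1/trnS2`), `rrnS`, `rrnL`, `CR`. When a record has
no control-region feature but `trnQ` and `trnM` are annotated, the gap
between them is labeled CR, which is where the control region sits in
these genomes; control regions shorter than a configurable minimum
(default 200 nt) are flagged rather than second-guessed, because some
deposited records are genuinely incomplete there. Ambiguity codes other
than N are rejected outright: all codon-level statistics assume
A/C/G/T, and N-containing codons are excluded from every count.

## Composition and skews

AT-skew = (A − T)/(A + T) and GC-skew = (G − C)/(G + C). Full-genome
composition is computed on the J strand (the convention under which
these taxa show negative AT and positive GC skew); per-gene composition
uses each gene's own reading orientation. Positional (codon) statistics
drop incomplete terminal codons — a 1–2 nt truncated stop has no full
codon positions. A skew whose pair-sum is zero is reported `NA`
(undefined), never 0. TSV output prints percentages at one decimal to
match the field's reporting convention; full precision is kept
internally.

## Codon usage

All codon statistics use the invertebrate mitochondrial code
(translation table 5, taken from Biostrings): AGA/AGG = Ser, ATA = Met,
TGA = Trp, stops TAA/TAG, hence 62 sense codons. The synonymous-family
partition is derived programmatically from the code table — table 5 has
12 twofold, 6 fourfold, 1 sixfold (Leu) and 1 eightfold (Ser) family
and no threefold family, so nothing is hard-coded to the standard-code
layout.

RSCU is the observed codon count scaled by family size over family
total; unused families are flagged `NA` rather than zero, since real
records can use only 60–61 codons.

ENC uses Wright's estimator generalized to an arbitrary family
partition: per family with n ≥ 2 observations,
F = (n·Σp² − 1)/(n − 1); F is averaged within each family-size class
and ENC = Σₖ nₖ/F̄ₖ, giving the exact bounds 20 (one codon per family)
and 62 (uniform usage). Families observed once contribute no F (the
estimator is undefined at n = 1, and treating them as F = 1 would bias
ENC down); a size class with no defined mean imputes it from the
defined classes scaled by 1/k. The expectation curve for the ENC–GC3
plot is the closed form 2 + s + 29/(s² + (1 − s)²).

GC3 is computed over all third positions of sense codons, not
synonymous-only third positions, matching how the quantity is usually
reported for mitogenomes; positional GC is pooled over all PCGs. The
neutrality plot regresses GC12 on GC3 by ordinary least squares across
genomes; the slope is read as the mutational share of
codon-composition evolution and 1 − slope as the selective share, with
Pearson's r and its two-sided t-based p-value attached.

## Diversity, distances, Ka/Ks

Nucleotide diversity (Pi) is the mean over unordered sequence pairs of
the per-site difference fraction. The default gap policy is complete
deletion (a column with any gap/N is dropped alignment-wide), matching
the DnaSP-style convention for sliding-window profiles; pairwise
deletion is available by flag, and under it Pi equals the mean of the
p-distance matrix exactly (tested as an oracle identity). Windows
default to 100 nt with a 25-nt step; when the last full window does not
land on a step multiple, one extra window ending at the final site is
appended and flagged.

Distance models are nested closed forms: p, JC69, K2P, TN93. The
`MCL-composite` model is the TN93 functional form with base frequencies
estimated once from all sequences pooled and applied to every pair — a
composite-estimation reading of "maximum composite likelihood" that, on
gap-free data, agrees to machine precision with ape's TN93 (which pools
frequencies the same way); the per-pair-frequency TN93 differs from it
only in the frequency source. Pairs whose corrections leave the
logarithm domain are flagged saturated and reported `NA`, never
silently clamped, and distance summaries are emitted both with and
without such pairs.

Ka/Ks uses the Nei–Gojobori (1986) counting method: per-codon
synonymous site fractions with mutations to stop codons removed from
the denominators (so S + N = 3 per codon holds exactly), multi-hit
codon differences averaged over all orderings of the differing
positions with stop-crossing pathways skipped (all orderings weighted
equally), and the Jukes–Cantor correction applied to pS and pN. The
ratio is undefined (flagged) at Ks = 0. Per-gene tables are summarized
two ways — mean over species pairs per gene and mean over genes per
species — the two usual comparison axes.

Neighbor-joining trees are delegated to ape (tree inference beyond NJ
is out of scope); negative branch lengths are clamped to zero with a
warning and tie-breaking is fixed by taxon-label order.

## Gene order and the TDRL bound

A gene order is the signed circular sequence of the 37 genes + CR,
extracted by start position after rotation to the anchor. Rearrangement
calls are computed against a reference order by removing the longest
common circular subsequence: each contiguous moved block is classified
as a tRNA shuffle (only tRNAs, no PCG/rRNA crossed between source and
destination), tRNA translocation (a PCG/rRNA is crossed), PCG move, or
inversion (any strand flip, including in place). The packaged reference
(`inst/extdata/salticid_gene_order.tsv`) is a constructed table
representing the conserved salticid-type arrangement — CR between trnQ
and trnM, rrnL between trnL1 and trnV, rrnS between trnV and trnQ,
trnN preceding trnL2, trnE adjacent to trnF, 9 J-strand and 4 N-strand
PCGs — and is user-replaceable; the package makes no ancestral-state
claim.

A tandem duplication–random loss (TDRL) event duplicates a contiguous
block and loses one copy of each gene; it can move genes but never flip
them. A single event therefore produces exactly the permutations that
consist of at most two maximal increasing runs (one descent), and k
events compose to at most 2^k runs, so the minimal event count is
ceil(log2(descents + 1)), which this package minimizes over circular
rotations. The run-based count matters: the superficially similar
bound via the longest decreasing subsequence (Dilworth cover by
increasing *subsequences* rather than runs) is wrong — the permutation
2143 is covered by two increasing subsequences yet is not a single-TDRL
product under any rotation, which the packaged exhaustive single-TDRL
enumeration oracle confirms. The bound is exact at 0 and 1 (a
characterization, tested by equivalence against that oracle for n ≤ 8)
and a lower bound beyond. Orders that differ by a strand flip are
typed "not TDRL-explainable" rather than bounded. The CR is excluded
from the permutation mapping: control-region movement involves other
mechanisms and would distort the gene-level bound.

## Tandem repeats

The detector targets control regions (hundreds of nt, periods from 5 to
a few hundred). For each candidate period p the sequence is compared
with itself at lag p; maximal positive-scoring runs under match +2 /
mismatch −7 (the classic tandem-repeat-finder weights) seed candidate
arrays, each array is re-scored against its column-majority consensus,
and hits below 1.9 copies, 80% identity, or a consensus score of 50 are
suppressed — the score floor is what keeps trivially short perfect
2-copy arrays in random AT-rich sequence out of the reports. Overlaps
are resolved by score then smaller period, and every accepted hit is
re-examined at divisor periods: a mutated array can score *higher* at
2p because the mutations are baked into the doubled consensus, so the
smallest divisor period whose consensus still explains the span is the
one reported. Copy number is fractional (span/period). For a uniformly
periodic array every phase decomposition into leading partial + full
copies + trailing partial is equally valid, so the detector anchors the
phase maximizing the number of full consensus copies and reports the
remainder as partials; their sum always equals the span modulo the
period. A brute-force (start, period, whole-copy-window) scan with the
same qualifying rule ships as an independent oracle and the test suite
requires agreement on all short strings it is given.

## The synthetic-data generator

The generator exists so that every statistic in the package can be
checked against a known truth. Its defaults emulate the genome class
the package targets: ~15 kb, 13 PCGs (realistic lengths, 10.8 kb
total), 22 tRNAs of 66 nt, two rRNAs (1260/720 nt), an 800-nt control
region between trnQ and trnM carrying a 24-nt tandem repeat with
partial copies (22 and 9 nt), 9 J-strand and 4 N-strand PCGs, AT
content 0.74, AT skew −0.12, GC skew +0.36, GC3 0.12 and GC12 0.30
(inside the ranges reported for jumping spiders), and a handful of
truncated stop codons.

Coding sequence is sampled codon-wise from a two-level distribution:
the amino-acid distribution is an exponential tilt of AT-rich
mitochondrial-proteome base weights solved by `uniroot` so the expected
GC12 hits its target; within each family the third-position class mass
carries the GC3 target exactly, codons are down-weighted by
exp(−penalty · #C) (mirroring the strong C avoidance of these
AT-skewed genomes — the preferred Leu codon comes out as UUA, as
observed in real data), and a concentration knob boosts one preferred
codon per family, which lowers the implied ENC; the implied
ENC/GC3/GC12 of the final distribution are computed exactly and
attached to the genome as ground truth. The non-coding/RNA base
distribution is then solved in closed form so that the expected
full-genome J-strand composition equals the targets given the coding
expectation — infeasible targets (e.g. high GC3 with very high AT and
strong GC skew) raise an error instead of drifting. Sampling is by
quota (largest-remainder counts, randomized order), so realized
composition matches its target to well under the ±0.01 recovery
tolerance and only the arrangement is random; a fixed seed gives
byte-identical GenBank output. RNA genes are composition-matched random
sequence with no secondary-structure realism — synthetic data validates
the statistics, not annotation tools, and passing recovery tests says
nothing about, e.g., tRNA folding in real records.

Divergence is simulated at codon level on a star tree by
acceptance/rejection: proposed single-base changes (transitions
weighted κ) are accepted at relative rate 1 if synonymous and ω if
nonsynonymous, stop codons always rejected, with a Poisson number of
accepted substitutions per branch at the requested expected
substitutions/site. This is deliberately not a full substitution-matrix
exponential: it is simple, auditable, and sufficient for recovery
testing. Recovery of ω by NG86 is asserted at κ = 1, the mutation model
NG86's site counting assumes; at κ > 1 NG86 is known to underestimate
Ka/Ks (transitions are disproportionately synonymous, inflating the
apparent synonymous rate relative to its unweighted site count), and
the suite asserts that downward bias as a property rather than
pretending the estimator recovers ω there. The neutrality-recovery
panel draws per-genome GC3 targets on a grid with GC12 coupled
linearly; the OLS slope of measured GC12 on measured GC3 recovers the
coupling within ±0.1 at 10 genomes × 3000 codons.

## Problem sizes and numerical conventions

The test suite and acceptance script run at sizes chosen to make the
statistical tolerances comfortable on a single CPU: full ~15 kb genomes
for composition (quota sampling makes ±0.01 essentially deterministic),
~10,700 codons for Ka/Ks recovery at ±0.05, 10 × 3000 codons for the
neutrality panel at ±0.1, n ≤ 8 for the exhaustive TDRL oracle, and
≤ 200 nt strings for the brute-force repeat oracle (it is quadratic).
Ties in majority consensus are broken by base order; LCS traceback and
NJ tie-breaks are fixed by input order; all randomness flows from
integer seeds through R's default generator, so every pipeline output
is a pure function of (inputs, config, seed).

## Known limitations

De novo annotation, tRNA secondary structure, alignment construction,
and likelihood/Bayesian tree inference are out of scope; alignments are
inputs. The composite-TN93 reading of "maximum composite likelihood" is
one well-defined member of that family, and printed distances from
other implementations may differ at the third decimal. The TDRL count
is a lower bound above 1 event, and rearrangement classification
depends on the supplied reference order. The repeat detector is built
for control-region-scale inputs, not genome-wide repeat masking.
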