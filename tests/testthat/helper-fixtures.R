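# In-code fixtures shared across test files; nothing is read from disk.

# A small hand-made genome: two PCGs (one N-strand, one truncated stop),
# one tRNA, one origin-spanning tRNA, and a CR gap between trnQ and trnM.
toy_features <- function() {
  data.frame(
    name  = c("cox1", "nad1", "trnQ", "trnM", "trnA"),
    type  = c("PCG", "PCG", "tRNA", "tRNA", "tRNA"),
    start = c(0L, 12L, 24L, 36L, 54L),
    end   = c(12L, 22L, 30L, 42L, 4L),   # trnA spans the origin
    strand = c("J", "N", "N", "J", "J"),
    codon_offset = c(0L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
}

toy_genome <- function() {
  # cox1 [0,12): ATGAAATTTTAA (complete stop); nad1 [12,22) on N strand:
  # J-strand ACCCGGGCAT -> reading = revcomp = ATGCCCGGGT (10 nt, so
  # stop class truncated-T); trnA wraps the origin: [54,58)+[0,4)
  seq <- paste0("ATGAAATTTTAA", "ACCCGGGCAT", "GC", "AATTGG", "CCGGTT",
                "TTAATT", "ACGTACGTACGT", "GCAT")
  # layout: 0..11 cox1, 12..21 nad1, 22..23 spacer, 24..29 trnQ,
  # 30..35 unannotated CR gap, 36..41 trnM, 42..53 filler, 54.. trnA
  mitogenome("TOY1", seq, toy_features(), taxon = "Toyus exampli")
}

# random gap-free alignment over n taxa and L sites
random_alignment <- function(n, L, gene = "toy", p_gap = 0, p_n = 0) {
  pool <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n), function(i) {
    ch <- sample(pool, L, replace = TRUE)
    if (p_n > 0) ch[stats::runif(L) < p_n] <- "N"
    if (p_gap > 0) ch[stats::runif(L) < p_gap] <- "-"
    paste(ch, collapse = "")
  }, "")
  alignment_set(stats::setNames(seqs, sprintf("t%02d", seq_len(n))),
                gene = gene)
}

# alignment of n related rows: a shared random base sequence, each row
# mutated at ~frac of its sites (keeps pairwise divergence well below
# saturation, unlike iid rows)
related_alignment <- function(n, L, frac = 0.05, gene = "toy") {
  base <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                       prob = c(0.35, 0.1, 0.15, 0.4)), collapse = "")
  seqs <- vapply(seq_len(n), function(i) {
    mutate_sites(base, max(1L, round(frac * L)))
  }, "")
  alignment_set(stats::setNames(seqs, sprintf("t%02d", seq_len(n))),
                gene = gene)
}

# mutate k distinct sites of a sequence (to a different base)
mutate_sites <- function(seq, k) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- sample(seq_along(ch), k)
  for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# mutate ~k sites of an in-frame sequence without creating stop codons
mutate_codons_keep_sense <- function(seq, k) {
  gc <- Biostrings::getGeneticCode("5")
  done <- 0
  while (done < k) {
    cand <- mutate_sites(seq, 1)
    cods <- substring(cand, seq(1, nchar(cand) - 2, 3),
                      seq(3, nchar(cand), 3))
    if (any(gc[cods] == "*")) next
    seq <- cand
    done <- done + 1
  }
  seq
}

# independent NG86 single-codon oracle built directly on the Biostrings
# code table (used against ng86_sites / ng86_diffs)
oracle_syn_sites <- function(codon) {
  gc <- Biostrings::getGeneticCode("5")
  s <- 0
  for (pos in 1:3) {
    orig <- substring(codon, pos, pos)
    alts <- setdiff(c("A", "C", "G", "T"), orig)
    muts <- vapply(alts, function(b) {
      m <- codon; substring(m, pos, pos) <- b; m
    }, "")
    muts <- muts[gc[muts] != "*"]
    if (length(muts) == 0) next
    s <- s + mean(gc[muts] == gc[[codon]])
  }
  s
}

# all permutations of 1..n (small n)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in combinat_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(sub, as.integer(n), after = pos)
    }
  }
  out
}

all_sense_codons <- function() {
  gc <- Biostrings::getGeneticCode("5")
  names(gc)[gc != "*"]
}
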