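test_that("fixed seed gives byte-identical GenBank output", {
  sp <- synthetic_spec(seed = 77)
  g1 <- generate_mitogenome(sp)
  g2 <- generate_mitogenome(synthetic_spec(seed = 77))
  expect_identical(g1$sequence, g2$sequence)
  f1 <- withr::local_tempfile(fileext = ".gb")
  f2 <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g1, f1); write_genbank(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed, different bytes
  g3 <- generate_mitogenome(synthetic_spec(seed = 78))
  expect_false(identical(g1$sequence, g3$sequence))
})

test_that("generated genomes carry the full expected gene complement", {
  g <- generate_mitogenome(synthetic_spec(seed = 29))
  tab <- table(g$features$type)
  expect_equal(unname(tab[c("PCG", "tRNA", "rRNA", "CR")]),
               c(13L, 22L, 2L, 1L), ignore_attr = TRUE)
  # 9 J / 4 N protein-coding genes, CR between trnQ and trnM
  pcg <- g$features[g$features$type == "PCG", ]
  expect_equal(sum(pcg$strand == "J"), 9)
  expect_equal(sum(pcg$strand == "N"), 4)
  o <- extract_gene_order(g)$gene
  expect_equal(o[which(o == "trnQ") + 1], "CR")
  expect_equal(o[which(o == "CR") + 1], "trnM")
  # every PCG has a valid canonical-class start and a parseable stop
  v <- validate_pcg_codons(g)
  expect_true(all(v$start_class != "unconventional"))
  expect_equal(sort(v$gene[v$stop_class == "truncated-T"]),
               sort(c("atp6", "cox3", "nad4", "nad5")))
})

test_that("realized composition and codon statistics hit their targets", {
  sp <- synthetic_spec(seed = 37, at_content = 0.72, at_skew = -0.15,
                       gc_skew = 0.30, gc3 = 0.18, gc12 = 0.31,
                       concentration = 0.3)
  g <- generate_mitogenome(sp)
  r <- base_composition(g$sequence, "full")
  expect_lt(abs(r$at_content - 0.72), 0.01)
  expect_lt(abs(r$at_skew - -0.15), 0.01)
  expect_lt(abs(r$gc_skew - 0.30), 0.01)
  bias <- codon_bias_summary(g)
  truth <- attr(g, "truth")
  expect_lt(abs(bias$gc3 - truth$implied_gc3), 0.02)
  expect_lt(abs(bias$gc12 - truth$implied_gc12), 0.02)
  expect_lt(abs(bias$enc - truth$implied_enc), 1)
})

test_that("infeasible composition targets raise a validation error", {
  sp <- synthetic_spec(seed = 1, at_content = 0.95, gc_skew = 0.9)
  expect_error(generate_mitogenome(sp), "infeasible composition")
})

test_that("requested TDRL events reshape the realized gene order", {
  sp <- synthetic_spec(seed = 41, tdrl_events = list(
    list(block = c("trnN", "trnL2"), keep_first = "trnL2")))
  g <- generate_mitogenome(sp)
  o <- extract_gene_order(g)
  calls <- compare_orders(o, reference_gene_order())
  expect_equal(nrow(calls), 1)
  expect_equal(calls$kind, "tRNA-shuffle")
  expect_equal(calls$tdrl_events, 1L)
})

test_that("zero branch lengths leave the set identical with Pi = 0", {
  g <- generate_mitogenome(synthetic_spec(seed = 47))
  ev <- evolve_set(g, n_taxa = 3, branch_length = 0, omega = 0.5,
                   seed = 4, genes = c("cox1", "atp8"))
  for (a in ev$alignments) {
    expect_equal(length(unique(a$seqs)), 1)
    expect_equal(nucleotide_diversity(a), 0)
  }
})

test_that("realized pairwise divergence matches the branch lengths", {
  g <- generate_mitogenome(synthetic_spec(seed = 53))
  # 2 taxa, 0.01 expected substitutions/site each: pairwise ~0.02 over
  # the ~10.7 kb coding complement
  ev <- evolve_set(g, n_taxa = 2, branch_length = 0.01, omega = 0.5,
                   seed = 6)
  cat1 <- paste(vapply(ev$alignments, function(a) a$seqs[1], ""),
                collapse = "")
  cat2 <- paste(vapply(ev$alignments, function(a) a$seqs[2], ""),
                collapse = "")
  aln <- alignment_set(c(a = cat1, b = cat2))
  p <- pairwise_distance(aln, "p")[1, 2]
  expect_lt(abs(p - 0.02), 0.005)
})

test_that("NG86 under-reports omega when transitions are favored", {
  g <- generate_mitogenome(synthetic_spec(seed = 59))
  ev <- evolve_set(g, n_taxa = 2, branch_length = 0.02, omega = 0.2,
                   kappa = 4, seed = 9)
  cat1 <- paste(vapply(ev$alignments, function(a) a$seqs[1], ""),
                collapse = "")
  cat2 <- paste(vapply(ev$alignments, function(a) a$seqs[2], ""),
                collapse = "")
  r <- ng86_kaks(cat1, cat2)
  expect_lt(r$ratio, 0.2)
})

test_that("the neutrality panel recovers its coupling coefficient", {
  pan <- neutrality_panel(n_genomes = 8, coupling = 0.25,
                          n_codons = 2000, seed = 13)
  fit <- neutrality_fit(pan$gc3, pan$gc12)
  expect_lt(abs(fit$slope - 0.25), 0.1)
  expect_gt(fit$r, 0.8)
})
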