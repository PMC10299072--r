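test_that("the invertebrate mitochondrial family partition is derived", {
  fams <- codon_families(5)
  expect_equal(nrow(fams), 62)
  sizes <- table(vapply(split(fams$family_size, fams$aa),
                        function(x) x[1], 0L))
  expect_equal(as.integer(sizes[c("2", "4", "6", "8")]), c(12L, 6L, 1L, 1L))
  # table-5 oddities: AGA = Ser (8-fold), ATA = Met, TGA = Trp
  expect_equal(fams$aa[fams$codon == "AGA"], "S")
  expect_equal(fams$family_size[fams$codon == "AGA"], 8L)
  expect_equal(fams$aa[fams$codon == "ATA"], "M")
  expect_equal(fams$aa[fams$codon == "TGA"], "W")
})

test_that("codon counting separates sense, stop and ambiguous codons", {
  tab <- count_codons("TTATTG")
  expect_equal(tab$count[tab$codon == "TTA"], 1L)
  expect_equal(tab$count[tab$codon == "TTG"], 1L)
  expect_equal(sum(tab$count), 2L)
  tab2 <- count_codons("ATGTAA")
  expect_equal(sum(tab2$count), 1L)
  expect_equal(attr(tab2, "n_stop"), 1L)
  tab3 <- count_codons(c("ATGNNN", "AGA"))
  expect_equal(attr(tab3, "n_ambiguous"), 1L)
  expect_equal(tab3$count[tab3$codon == "AGA"], 1L)
  # incomplete trailing codon dropped
  expect_equal(sum(count_codons("ATGAA")$count), 1L)
  expect_error(count_codons("ATG", code = 999), "unsupported")
})

test_that("RSCU values and family-sum normalization are exact", {
  # Phe TTT=3, TTC=1 -> RSCU 1.5 / 0.5
  tab <- rscu(count_codons(c("TTTTTTTTTTTC")))
  expect_equal(tab$rscu[tab$codon == "TTT"], 1.5)
  expect_equal(tab$rscu[tab$codon == "TTC"], 0.5)
  # uniform usage within every family -> all RSCU 1, sums = family size
  uni <- count_codons(paste(all_sense_codons(), collapse = ""))
  u <- rscu(uni)
  expect_true(all(abs(u$rscu - 1) < 1e-12))
  # property: family sums equal family sizes on random tables
  set.seed(7)
  for (i in 1:10) {
    codons <- sample(all_sense_codons(), 500, replace = TRUE,
                     prob = stats::runif(62))
    t <- rscu(count_codons(paste(codons, collapse = "")))
    sums <- tapply(t$rscu, t$aa, sum)
    sizes <- vapply(split(t$family_size, t$aa), function(x) x[1], 0L)
    used <- tapply(t$count, t$aa, sum) > 0
    expect_equal(as.numeric(sums[used]), as.numeric(sizes[used]))
  }
})

test_that("ENC hits its closed-form extremes and bounds", {
  fams <- codon_families(5)
  one_per_family <- tapply(seq_len(nrow(fams)), fams$aa, function(i) i[1])
  counts <- integer(nrow(fams))
  counts[one_per_family] <- 1000L
  tab <- count_codons("ATG")  # scaffold, replace counts
  tab$count <- counts
  expect_equal(enc(tab), 20)
  tab$count <- rep(1000L, nrow(fams))
  expect_gt(enc(tab), 61.9)
  expect_lte(enc(tab), 62)
  # bounds on random tables with all families used
  set.seed(11)
  for (i in 1:10) {
    tab$count <- as.integer(sample(1:50, nrow(fams), replace = TRUE))
    e <- enc(tab)
    expect_gte(e, 20); expect_lte(e, 62)
  }
})

test_that("concentrating usage within a family never increases ENC", {
  fams <- codon_families(5)
  tab <- count_codons("ATG")
  set.seed(13)
  for (i in 1:20) {
    tab$count <- as.integer(sample(5:50, nrow(fams), replace = TRUE))
    e0 <- enc(tab)
    # move one count from a minority codon to the majority codon of a
    # random multi-codon family (totals fixed)
    aa <- sample(unique(fams$aa[fams$family_size > 1]), 1)
    idx <- which(tab$aa == aa)
    hi <- idx[which.max(tab$count[idx])]
    lo <- idx[which.min(tab$count[idx])]
    if (hi == lo || tab$count[lo] == 0) next
    tab$count[hi] <- tab$count[hi] + 1L
    tab$count[lo] <- tab$count[lo] - 1L
    expect_lte(enc(tab), e0 + 1e-9)
  }
})

test_that("the no-selection ENC-GC3 curve matches its closed form", {
  expect_equal(enc_expected(0), 31.0)
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(1), 32.0)
  # symmetry up to the linear term
  s <- seq(0, 1, by = 0.05)
  expect_equal(enc_expected(s) - s, enc_expected(1 - s) - (1 - s))
  expect_error(enc_expected(1.2))
})

test_that("positional GC pools sense codons correctly", {
  r <- positional_gc("GGGGGG")
  expect_equal(c(r$gc1, r$gc2, r$gc3, r$gc12), c(1, 1, 1, 1))
  r2 <- positional_gc("GATGAT")
  expect_equal(c(r2$gc1, r2$gc2, r2$gc3, r2$gc12), c(1, 0, 0, 0.5))
  expect_equal(positional_gc("ATTATAAAA")$gc3, 0)
  # stop codons excluded from the pool
  r3 <- positional_gc("GGGTAA")
  expect_equal(r3$n_codons, 1L)
  expect_equal(r3$gc1, 1)
})

test_that("neutrality regression slope, r and shares are consistent", {
  gc3 <- c(0.05, 0.10, 0.15, 0.20, 0.25)
  fit <- neutrality_fit(gc3, 0.3 + 0.5 * gc3)
  expect_equal(fit$slope, 0.5, tolerance = 1e-10)
  expect_equal(fit$r, 1, tolerance = 1e-10)
  # the published slope maps to the published shares
  expect_equal(100 * 0.249, 24.9)
  fit2 <- neutrality_fit(gc3, 0.3 + 0.249 * gc3)
  expect_equal(round(fit2$mutation_share_pct, 1), 24.9)
  expect_equal(round(fit2$selection_share_pct, 1), 75.1)
  expect_error(neutrality_fit(c(0.1, 0.2), c(0.1, 0.2)), "3 points")
  expect_error(neutrality_fit(rep(0.1, 5), gc3), "degenerate")
})

test_that("measured ENC tracks the distribution implied by the generator", {
  d0 <- codon_distribution(0.12, 0.30, concentration = 0)
  d9 <- codon_distribution(0.12, 0.30, concentration = 0.9)
  expect_gt(attr(d0, "implied_enc"), attr(d9, "implied_enc"))
  set.seed(19)
  for (conc in c(0.2, 0.7)) {
    d <- codon_distribution(0.12, 0.30, concentration = conc)
    codons <- sample(d$codon, 6000, replace = TRUE, prob = d$prob)
    e <- enc(count_codons(paste(codons, collapse = "")))
    expect_lt(abs(e - attr(d, "implied_enc")), 1)
  }
})
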