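test_that("nucleotide diversity matches hand-enumerated pair averages", {
  a <- alignment_set(c(x = "ACGT", y = "ACGT", z = "ACGT"))
  expect_equal(nucleotide_diversity(a), 0)
  base <- paste(rep("ACGT", 25), collapse = "")
  b <- alignment_set(c(x = base, y = mutate_sites(base, 1)))
  expect_equal(nucleotide_diversity(b), 0.01)
  # 3 sequences with pairwise differences 1, 2, 3 over 100 sites
  s1 <- base                                   # ...ACGT ending CGT
  s2 <- paste0("T", substring(base, 2))        # 1 diff vs s1 (site 1)
  s3 <- paste0(substring(base, 1, 97), "TTT")  # diffs vs s1 at 98, 99
  c3 <- alignment_set(c(a = s1, b = s2, c = s3))
  # pairs: (s1,s2)=1, (s1,s3)=2, (s2,s3)=3 -> mean 6/300
  expect_equal(nucleotide_diversity(c3), 0.02)
})

test_that("Pi equals the mean pairwise p-distance (oracle equivalence)", {
  set.seed(41)
  for (i in 1:8) {
    n <- sample(3:20, 1); L <- sample(60:300, 1)
    aln <- random_alignment(n, L, p_gap = 0.02, p_n = 0.02)
    d <- suppressWarnings(pairwise_distance(aln, "p"))
    expect_equal(nucleotide_diversity(aln, deletion = "pairwise"),
                 mean(d[upper.tri(d)]))
  }
})

test_that("sliding windows tile the alignment as specified", {
  aln <- random_alignment(4, 200)
  wd <- sliding_window_pi(aln, w = 100, step = 25)
  expect_equal(wd$windows$start, c(0, 25, 50, 75, 100))
  expect_false(any(wd$windows$flagged_tail))
  # non-multiple tail gets a flagged final window
  aln2 <- random_alignment(4, 210)
  wd2 <- sliding_window_pi(aln2, w = 100, step = 25)
  expect_equal(wd2$windows$start, c(0, 25, 50, 75, 100, 110))
  expect_true(wd2$windows$flagged_tail[6])
  # identical rows give all-zero windows
  s <- paste(rep("ACGT", 50), collapse = "")
  aln3 <- alignment_set(c(a = s, b = s))
  expect_true(all(sliding_window_pi(aln3)$windows$pi == 0))
  expect_error(sliding_window_pi(aln, w = 1), "window")
})

test_that("distance models match closed forms and ape as oracle", {
  # JC69 closed form at p = 0.3
  expect_equal(round(-0.75 * log(1 - 4 * 0.3 / 3), 4), 0.3831)
  set.seed(43)
  for (i in 1:5) {
    aln <- related_alignment(5, 300, frac = 0.08)
    bin <- ape::as.DNAbin(ape::as.alignment(
      stats::setNames(lapply(tolower(aln$seqs),
                             function(s) strsplit(s, "")[[1]]), aln$taxa)))
    for (mod in c("p", "JC69", "K2P")) {
      ape_mod <- c(p = "raw", JC69 = "JC69", K2P = "K80")[mod]
      mine <- pairwise_distance(aln, mod)
      ref <- as.matrix(ape::dist.dna(bin, model = ape_mod))
      expect_equal(unname(mine), unname(ref[aln$taxa, aln$taxa]),
                   tolerance = 1e-8, info = mod)
    }
    # ape pools base frequencies over the whole alignment, which is this
    # package's MCL-composite variant: exact agreement expected there,
    # near agreement for the per-pair-frequency TN93
    ref_tn <- as.matrix(ape::dist.dna(bin, model = "TN93"))
    mine_mcl <- pairwise_distance(aln, "MCL-composite")
    expect_equal(unname(mine_mcl), unname(ref_tn[aln$taxa, aln$taxa]),
                 tolerance = 1e-10)
    mine_tn <- pairwise_distance(aln, "TN93")
    expect_equal(unname(mine_tn), unname(ref_tn[aln$taxa, aln$taxa]),
                 tolerance = 0.01)
  }
  # identical pair is 0 under every model
  same <- alignment_set(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))
  for (mod in c("p", "JC69", "K2P", "TN93", "MCL-composite")) {
    expect_equal(pairwise_distance(same, mod)[1, 2], 0, info = mod)
  }
})

test_that("all corrected distances agree with p to first order", {
  # one difference in 100 sites: p = 0.01
  base <- paste(rep("ACGT", 25), collapse = "")
  aln <- alignment_set(c(a = base, b = mutate_sites(base, 1)))
  p <- pairwise_distance(aln, "p")[1, 2]
  for (mod in c("JC69", "K2P", "TN93", "MCL-composite")) {
    d <- pairwise_distance(aln, mod)[1, 2]
    expect_gte(d, p)
    expect_lt(abs(d - p) / p, 0.01)
  }
})

test_that("saturated pairs are flagged, not clamped", {
  a <- paste(rep("A", 50), collapse = "")
  g <- paste(rep("G", 50), collapse = "")
  aln <- alignment_set(c(x = a, y = g))
  expect_warning(d <- pairwise_distance(aln, "JC69"), "W_SATURATED")
  expect_true(is.na(d[1, 2]))
})

test_that("NJ recovers an additive 4-taxon topology deterministically", {
  # tree ((A:1,B:2):1,(C:3,D:4):1); path-length (additive) matrix
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 6
  d["A", "D"] <- d["D", "A"] <- 7
  d["B", "C"] <- d["C", "B"] <- 7
  d["B", "D"] <- d["D", "B"] <- 8
  d["C", "D"] <- d["D", "C"] <- 7
  nwk <- nj_tree(d)
  tr <- ape::unroot(attr(nwk, "phylo"))
  want <- ape::unroot(ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);"))
  expect_equal(ape::dist.topo(tr, want)[1], 0)
  # 2 taxa: a single edge of total length d
  nwk2 <- nj_tree(matrix(c(0, 0.4, 0.4, 0), 2, 2,
                         dimnames = list(c("x", "y"), c("x", "y"))))
  expect_match(nwk2, "x:0.2")
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2,
                              dimnames = list(c("x", "y"), c("x", "y")))),
               "symmetric")
})
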