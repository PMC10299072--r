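ref_order <- reference_gene_order()

# observed order built by editing the reference gene vector
edited_order <- function(genes, strands = NULL) {
  s <- stats::setNames(ref_order$strand, ref_order$gene)
  if (!is.null(strands)) s[names(strands)] <- strands
  gene_order(genes, unname(s[genes]), genome_id = "edited")
}

test_that("the packaged reference order has the expected structure", {
  expect_equal(nrow(ref_order), 38)
  expect_equal(sum(vapply(ref_order$gene, function(g)
    identical(mitocomp:::canonical_type(g), "PCG"), TRUE)), 13)
  g <- ref_order$gene
  expect_lt(which(g == "trnQ"), which(g == "CR"))
  expect_lt(which(g == "CR"), which(g == "trnM"))
  expect_equal(which(g == "trnL2") - which(g == "trnN"), 1)
})

test_that("gene orders extract rotation-invariantly from genomes", {
  g <- generate_mitogenome(synthetic_spec(seed = 2))
  o <- extract_gene_order(g, anchor = "cox1")
  expect_equal(o$gene[1], "cox1")
  expect_true(orders_equal(o, ref_order))
  o2 <- extract_gene_order(g, anchor = "nad2")
  expect_true(orders_equal(o2, o))
  expect_error(extract_gene_order(g, anchor = "nope"), "anchor")
})

test_that("identical and rotated orders produce no rearrangement calls", {
  expect_equal(nrow(compare_orders(ref_order, ref_order)), 0)
  rot <- gene_order(mitocomp:::rotate_vec(ref_order$gene, 10),
                    mitocomp:::rotate_vec(ref_order$strand, 10))
  expect_equal(nrow(compare_orders(rot, ref_order)), 0)
  expect_equal(tdrl_event_bound(rot, ref_order), 0)
})

test_that("an adjacent tRNA swap is called as a single-TDRL shuffle", {
  g <- ref_order$gene
  i <- which(g == "trnN")
  g[c(i, i + 1)] <- g[c(i + 1, i)]   # trnN <-> trnL2
  obs <- edited_order(g)
  calls <- compare_orders(obs, ref_order)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$kind, "tRNA-shuffle")
  expect_true(calls$genes %in% c("trnN", "trnL2"))
  expect_equal(calls$tdrl_events, 1L)
})

test_that("a PCG relocated between tRNAs is called as a PCG move", {
  g <- setdiff(ref_order$gene, "nad1")
  i <- which(g == "trnE")
  g <- append(g, "nad1", after = i)   # nad1 now between trnE and trnF
  obs <- edited_order(g)
  calls <- compare_orders(obs, ref_order)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$kind, "PCG-move")
  expect_equal(calls$genes, "nad1")
})

test_that("a tRNA crossing a PCG is a translocation, a flip an inversion", {
  g <- setdiff(ref_order$gene, "trnK")
  i <- which(g == "trnG")
  g <- append(g, "trnK", after = i)   # trnK jumped across several PCGs
  obs <- edited_order(g)
  calls <- compare_orders(obs, ref_order)
  expect_equal(calls$kind, "tRNA-translocation")

  flip <- edited_order(ref_order$gene, strands = c(trnK = "N"))
  calls2 <- compare_orders(flip, ref_order)
  expect_true("inversion" %in% calls2$kind)
  b <- tdrl_event_bound(flip, ref_order)
  expect_true(is.na(b))
  expect_equal(attr(b, "reason"), "not TDRL-explainable")
})

test_that("gene-set mismatches raise a validation error", {
  short <- gene_order(ref_order$gene[-5], ref_order$strand[-5])
  expect_error(compare_orders(short, ref_order), "gene sets differ")
})

test_that("TDRL bound is 1 exactly on the single-TDRL enumeration", {
  for (n in 4:8) {
    products <- enumerate_single_tdrl(n)
    for (perm in products) {
      expect_equal(tdrl_event_bound(perm, circular = FALSE), 1L,
                   info = paste(perm, collapse = ","))
    }
  }
  # and on nothing else: every other non-identity permutation needs >= 2
  for (n in 4:6) {
    keys <- vapply(enumerate_single_tdrl(n), paste, "", collapse = ",")
    all_perms <- combinat_perms(n)
    for (perm in all_perms) {
      key <- paste(perm, collapse = ",")
      b <- tdrl_event_bound(perm, circular = FALSE)
      if (identical(perm, seq_len(n))) {
        expect_equal(b, 0L)
      } else if (key %in% keys) {
        expect_equal(b, 1L, info = key)
      } else {
        expect_gte(b, 2L)
      }
    }
  }
})

test_that("TDRL bound worked examples and rotation invariance hold", {
  expect_equal(tdrl_event_bound(1:6, circular = FALSE), 0L)
  expect_equal(tdrl_event_bound(c(2L, 1L, 3L, 4L), circular = FALSE), 1L)
  # full reversal of 4 elements needs 2 events
  expect_equal(tdrl_event_bound(c(4L, 3L, 2L, 1L), circular = FALSE), 2L)
  # circular: rotating both inputs never changes the bound
  g <- ref_order$gene
  i <- which(g == "trnN")
  g[c(i, i + 1)] <- g[c(i + 1, i)]
  obs <- edited_order(g)
  b0 <- tdrl_event_bound(obs, ref_order)
  for (r in c(5, 17, 30)) {
    rot_obs <- gene_order(mitocomp:::rotate_vec(obs$gene, r),
                          mitocomp:::rotate_vec(obs$strand, r))
    rot_ref <- gene_order(mitocomp:::rotate_vec(ref_order$gene, r),
                          mitocomp:::rotate_vec(ref_order$strand, r))
    expect_equal(tdrl_event_bound(rot_obs, ref_order), b0)
    expect_equal(tdrl_event_bound(obs, rot_ref), b0)
  }
})
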