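test_that("gene-name synonyms normalize heterogeneous labels", {
  expect_equal(canonical_gene_name("COI"), "cox1")
  expect_equal(canonical_gene_name("ND4"), "nad4")
  expect_equal(canonical_gene_name("ND4L"), "nad4L")
  expect_equal(canonical_gene_name("12S ribosomal RNA"), "rrnS")
  expect_equal(canonical_gene_name("tRNA-Leu(UUR)"), "trnL2")
  expect_equal(canonical_gene_name("tRNA-Ser(AGN)"), "trnS1")
  expect_equal(canonical_gene_name("D-loop"), "CR")
  expect_equal(canonical_gene_name(NA, "cytochrome b"), "cytb")
  expect_true(is.na(canonical_gene_name("nonsense")))
})

test_that("extraction honours strand, origin wrap and codon offset", {
  g <- toy_genome()
  expect_equal(extract_gene_sequence(g, "cox1"), "ATGAAATTTTAA")
  # N-strand PCG is reverse-complemented into its reading orientation
  expect_equal(extract_gene_sequence(g, "nad1"), "ATGCCCGGGT")
  # origin-spanning feature concatenates across the junction
  expect_equal(extract_gene_sequence(g, "trnA"), "GCATATGA")
  expect_error(extract_gene_sequence(g, "nad2"), "no feature")

  # hand wrap example on a 6-mer circle
  g2 <- mitogenome("W1", "AAAAAG", data.frame(
    name = "trnA", type = "tRNA", start = 5L, end = 2L, strand = "J",
    codon_offset = 0L))
  expect_equal(extract_gene_sequence(g2, "trnA"), "GAA")

  # codon_offset shifts the PCG reading frame start
  g3 <- mitogenome("O1", "GATGAAATAA", data.frame(
    name = "cox1", type = "PCG", start = 0L, end = 10L, strand = "J",
    codon_offset = 1L))
  expect_equal(extract_gene_sequence(g3, "cox1"), "ATGAAATAA")
})

test_that("feature lengths match modular interval arithmetic", {
  g <- toy_genome()
  ft <- feature_table(g)
  len <- genome_length(g)
  for (i in seq_len(nrow(ft))) {
    s <- extract_gene_sequence(g, ft$gene[i], apply_offset = FALSE)
    expect_equal(nchar(s), (ft$end[i] - ft$start[i]) %% len,
                 info = ft$gene[i])
  }
})

test_that("start/stop codon validation classifies canonical and truncated", {
  g <- toy_genome()
  v <- validate_pcg_codons(g)
  cox1 <- v[v$gene == "cox1", ]
  expect_equal(cox1$start_codon, "ATG")
  expect_equal(cox1$stop_codon, "TAA")
  expect_equal(cox1$start_class, "canonical-ATN")
  expect_equal(cox1$stop_class, "complete")
  nad1 <- v[v$gene == "nad1", ]
  expect_equal(nad1$stop_class, "truncated-T")
  expect_equal(nad1$stop_codon, "T")

  # unconventional start and truncated-TA stop
  g4 <- mitogenome("U1", "CGAAAATTTTA", data.frame(
    name = "cox1", type = "PCG", start = 0L, end = 11L, strand = "J",
    codon_offset = 0L))
  v4 <- validate_pcg_codons(g4)
  expect_equal(v4$start_class, "unconventional")
  expect_equal(v4$stop_class, "truncated-TA")
  expect_equal(v4$stop_codon, "TA")
})

test_that("GenBank round trip preserves names, coordinates and strands", {
  g <- toy_genome()
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, path)
  g2 <- parse_genbank(path, infer_cr = FALSE, min_cr_length = 1L)
  expect_equal(g2$id, g$id)
  expect_equal(g2$sequence, g$sequence)
  expect_equal(g2$features, g$features)
  expect_true(g2$circular)
  # second round trip is byte-stable
  path2 <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("an unannotated trnQ..trnM gap is labeled as the control region", {
  g <- toy_genome()
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, path)
  g2 <- parse_genbank(path, infer_cr = TRUE, min_cr_length = 1L)
  expect_true("CR" %in% g2$features$name)
  cr <- g2$features[g2$features$name == "CR", ]
  expect_equal(cr$start, 30L)
  expect_equal(cr$end, 36L)
  # a short CR is flagged, not rejected
  g3 <- parse_genbank(path, infer_cr = TRUE, min_cr_length = 200L)
  expect_equal(attr(g3, "cr_short"), 6L)
})

test_that("malformed inputs raise typed errors", {
  f <- toy_features()
  f$name[2] <- "cox1"
  expect_error(mitogenome("D1", "ACGTACGTAC", f), "duplicate")
  f <- toy_features()
  f$end[1] <- 999L
  expect_error(mitogenome("D2", "ACGTACGTAC", f), "outside")
  expect_error(mitogenome("D3", "ACGRTT", toy_features()), "unsupported")
  tmp <- withr::local_tempfile(lines = ">not genbank\nACGT")
  expect_error(parse_genbank(tmp), "not a GenBank")
})

test_that("synthetic GenBank files parse back to equal genomes", {
  g <- generate_mitogenome(synthetic_spec(seed = 17))
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, path)
  g2 <- parse_genbank(path)
  expect_equal(g2$sequence, g$sequence)
  expect_equal(g2$features, g$features)
  expect_equal(table(g2$features$type)[c("PCG", "tRNA", "rRNA", "CR")],
               table(g$features$type)[c("PCG", "tRNA", "rRNA", "CR")])
})
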