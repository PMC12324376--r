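tx_fixture <- function() {
  build_transcript_models(tibble::tibble(
    transcript_id = rep(c("t_plus", "t_minus", "t_out"), each = 2),
    gene_id = rep(c("g1", "g2", "g3"), each = 2),
    chrom = "chr1",
    start = c(5000, 7000, 3000, 4800, 30000, 32000),
    end = c(5200, 7400, 3400, 5200, 30200, 32400),
    strand = rep(c("+", "-", "+"), each = 2),
    transcript_type = "protein_coding",
    peptide = "MAAA"))
}

test_that("TE-derived transcript calls test the single strand-aware TSS base", {
  tx <- tx_fixture()
  tes <- tibble::tibble(chrom = "chr1", start = c(4800, 5201), end = c(5200, 5400),
                        strand = "+", subfamily = c("sfA", "sfB"), family = "f",
                        te_class = "LTR", clade = "Other",
                        uid = c("te_000001", "te_000002"))
  calls <- find_te_derived_transcripts(tx, tes)
  # plus strand: tss 5000 inside [4800,5200)
  expect_true("t_plus" %in% calls$transcript_id)
  # minus strand: tss is 5199 (end of last exon - 1), not 3000
  expect_true("t_minus" %in% calls$transcript_id)
  expect_equal(calls$te_uid[calls$transcript_id == "t_minus"], "te_000001")
  expect_false("t_out" %in% calls$transcript_id)

  # 1 bp left of the TE start is outside
  tes2 <- dplyr::mutate(tes[1, ], start = 5001, end = 5400)
  t_plus_only <- tx[tx$transcript_id == "t_plus", ]
  expect_equal(nrow(find_te_derived_transcripts(t_plus_only, tes2)), 0)
})

test_that("TSS-in-TE calls match the brute-force oracle on random instances", {
  set.seed(52)
  tes <- random_te_annotation(300)
  pos <- sample.int(100000, 400)
  tx <- build_transcript_models(tibble::tibble(
    transcript_id = sprintf("t%03d", seq_along(pos)),
    gene_id = sprintf("g%03d", seq_along(pos)),
    chrom = sample(c("chr1", "chr2"), length(pos), replace = TRUE),
    start = pos, end = pos + 500, strand = "+",
    transcript_type = "other"))
  calls <- find_te_derived_transcripts(tx, tes)
  expected <- oracle_assign_points(tx$chrom, tx$tss, tes)
  got <- setNames(rep(NA_character_, nrow(tx)), tx$transcript_id)
  got[calls$transcript_id] <- calls$te_uid
  expect_equal(unname(got[tx$transcript_id]), expected)
})

test_that("the expression quorum needs CPM above threshold in a strict majority", {
  calls <- tibble::tibble(transcript_id = c("t1", "t2", "t3"),
                          gene_id = "g", transcript_type = "other",
                          gene_biotype = "noncoding", te_uid = "te_000001",
                          te_class = "LTR", subfamily = "sfA", expressed = NA)
  cpm_tbl <- tibble::tibble(
    feature_id = c("t1", "t2", "t3"),
    s1 = c(5, 5, 0), s2 = c(5, 0, 0), s3 = c(5, 0, 0),
    s4 = c(5, 5, 0), s5 = c(0, 1, 0), s6 = c(5, 0, 0))
  design <- tiny_design(3)
  out <- expressed_filter(calls, cpm_tbl, design)
  expect_true(out$expressed[1])    # > 1 in a strict majority of each group
  expect_false(out$expressed[2])   # one hit per group; CPM exactly 1 is not > 1
  expect_false(out$expressed[3])   # all zero
  expect_error(
    expressed_filter(dplyr::mutate(calls, transcript_id = "missing"),
                     cpm_tbl, design),
    "missing")
})

test_that("type composition reports fractions for calls and the background", {
  tx <- tx_fixture()
  calls <- tibble::tibble(transcript_id = c("t_plus", "t_minus"),
                          transcript_type = c("protein_coding",
                                              "retained_intron"))
  out <- transcript_type_composition(calls, tx)
  te <- out[out$group == "te_derived", ]
  expect_equal(sort(te$fraction), c(0.5, 0.5))
  expect_equal(sum(te$fraction), 1)
  non <- out[out$group == "non_te_derived", ]
  expect_equal(sum(non$n), 1)
  empty <- transcript_type_composition(calls[0, ], tx)
  expect_equal(sum(empty$group == "te_derived"), 0)
})

test_that("per-type subfamily enrichment matches the plain enrichment per stratum", {
  set.seed(53)
  sim <- shared_sim()
  background <- subfamily_summaries(sim$tes)
  calls <- tibble::tibble(
    transcript_id = sprintf("t%02d", 1:20),
    te_uid = sim$tes$uid[1:20],
    subfamily = sim$tes$subfamily[1:20],
    transcript_type = rep(c("protein_coding", "retained_intron"), 10))
  out <- subfamily_enrichment_by_type(calls, background)
  one <- subfamily_enrichment(
    dplyr::filter(calls, transcript_type == "protein_coding") |>
      dplyr::transmute(uid = te_uid, subfamily),
    background)
  sub <- dplyr::filter(out, transcript_type == "protein_coding") |>
    dplyr::select(-"transcript_type")
  expect_equal(dplyr::arrange(sub, name), dplyr::arrange(one, name))
})

test_that("protein products compare by exact peptide identity within the gene", {
  tx <- build_transcript_models(tibble::tibble(
    transcript_id = c("c1", "c1b", "c2", "c3", "n1"),
    gene_id = c("gA", "gA", "gA", "gB", "gC"),
    chrom = "chr1", start = c(0, 0, 0, 1000, 2000) * 10 + 1000,
    end = c(0, 0, 0, 1000, 2000) * 10 + 1400,
    strand = "+",
    transcript_type = c("protein_coding", "protein_coding", "protein_coding",
                        "protein_coding", "lincRNA"),
    peptide = c("MSEQ", "MSEQ", "MSEQX", "MONLY", NA)))
  calls <- tibble::tibble(
    transcript_id = c("c1b", "c2", "c3", "n1"),
    gene_id = c("gA", "gA", "gB", "gC"),
    transcript_type = c("protein_coding", "protein_coding", "protein_coding",
                        "lincRNA"))
  out <- compare_protein_products(calls, tx)
  lut <- setNames(out$protein_comparison, out$transcript_id)
  expect_equal(unname(lut["c1b"]), "same")       # matches canonical c1
  expect_equal(unname(lut["c2"]), "different")   # N-terminal variant
  expect_equal(unname(lut["c3"]), "no_canonical")
  expect_equal(unname(lut["n1"]), "noncoding")
  # partition over coding calls is exhaustive and exclusive
  coding <- out[out$protein_comparison != "noncoding", ]
  expect_true(all(coding$protein_comparison %in%
                    c("same", "different", "no_canonical")))
})
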