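chim_tes <- function() {
  tibble::tibble(chrom = "chr1",
                 start = c(1000, 20000), end = c(1500, 20600), strand = "+",
                 subfamily = c("sfA", "sfB"), family = "f", te_class = "LTR",
                 clade = "Other", uid = c("te_000001", "te_000002"))
}

chim_genes <- function() {
  build_transcript_models(tibble::tibble(
    transcript_id = rep(c("known_cod", "known_nc"), each = 2),
    gene_id = rep(c("gc", "gn"), each = 2),
    chrom = "chr1",
    start = c(5000, 8000, 40000, 43000),
    end = c(5400, 8400, 40400, 43400),
    strand = "+",
    transcript_type = rep(c("protein_coding", "lincRNA"), each = 2)))
}

as_model <- function(id, starts, ends, strand = "+") {
  build_transcript_models(tibble::tibble(
    transcript_id = id, gene_id = id, chrom = "chr1",
    start = starts, end = ends, strand = strand,
    transcript_type = "other"))
}

test_that("candidates require the strand-aware TSS base inside a TE", {
  tes <- chim_tes()
  asm <- dplyr::bind_rows(
    as_model("in_te", c(1100, 5000), c(1300, 5400)),
    as_model("upstream", c(997, 5000), c(1200, 5400)),  # tss 3 bp before TE
    as_model("single_in_te", 1050, 1450))
  cand <- detect_te_first_exon(asm, tes)
  expect_setequal(cand$transcript_id, c("in_te", "single_in_te"))
  expect_equal(cand$category, rep("unclassified", 2))
})

test_that("the novel-first-exon filter is a >= 1 bp strand-agnostic overlap", {
  tes <- chim_tes()
  gm <- chim_genes()
  asm <- dplyr::bind_rows(
    as_model("clean", c(1100, 8000), c(1300, 8400)),
    # first exon runs from the TE to exactly 1 bp into the known exon
    as_model("one_bp", c(1100, 30000), c(5001, 30200)))
  cand <- detect_te_first_exon(asm, tes)
  out <- filter_novel_first_exon(cand, gm)
  lut <- setNames(out$filter_novel_first_exon, out$transcript_id)
  expect_equal(unname(lut["clean"]), "pass")
  expect_equal(unname(lut["one_bp"]), "fail")
  # a minus-strand candidate whose first exon overlaps a plus-strand known
  # exon fails the default strand-agnostic test but passes strand-aware mode
  tes3 <- dplyr::bind_rows(tes, dplyr::mutate(tes[1, ], start = 5350,
                                              end = 5700, uid = "te_000003"))
  opp <- as_model("opp_strand", c(2000, 5380), c(2200, 5600), strand = "-")
  cand2 <- detect_te_first_exon(opp, tes3)
  expect_equal(nrow(cand2), 1)
  agn <- filter_novel_first_exon(cand2, gm)
  expect_equal(agn$filter_novel_first_exon, "fail")
  aware <- filter_novel_first_exon(cand2, gm, strand_aware = TRUE)
  expect_equal(aware$filter_novel_first_exon, "pass")
})

test_that("junction support needs min_reads in at least one sample", {
  tes <- chim_tes()
  asm <- dplyr::bind_rows(
    as_model("ok", c(1100, 8000), c(1300, 8400)),
    as_model("weak", c(1100, 8000), c(1310, 8400)),
    as_model("single", 1050, 1450))
  cand <- detect_te_first_exon(asm, tes)
  junctions <- tibble::tibble(
    chrom = "chr1", intron_start = c(1300, 1310), intron_end = 8000,
    strand = "+", s1 = c(0, 1), s2 = c(1, 1), s3 = c(3, 1))
  out <- filter_junction_support(cand, junctions)
  lut <- setNames(out$filter_junction, out$transcript_id)
  expect_equal(unname(lut["ok"]), "pass")      # reads 0,1,3
  expect_equal(unname(lut["weak"]), "fail")    # reads 1,1,1
  expect_equal(unname(lut["single"]), "not_applicable")
  # a junction absent from the table counts as zero support
  out2 <- filter_junction_support(cand, junctions[0, ])
  expect_equal(out2$filter_junction[out2$transcript_id == "ok"], "fail")
  # stricter rule: every sample of one condition
  design <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                           condition = c("control", "exposed", "exposed"))
  j2 <- tibble::tibble(chrom = "chr1", intron_start = 1300, intron_end = 8000,
                       strand = "+", s1 = 0, s2 = 2, s3 = 3)
  out3 <- filter_junction_support(cand, j2, rule = "all_of_condition",
                                  design = design)
  expect_equal(out3$filter_junction[out3$transcript_id == "ok"], "pass")
  expect_error(filter_junction_support(cand, j2, rule = "all_of_condition"),
               "design")
})

test_that("the chimeric expression quorum is inclusive and strict-majority", {
  tes <- chim_tes()
  cand <- detect_te_first_exon(
    as_model("x", c(1100, 8000), c(1300, 8400)), tes)
  design3 <- tibble::tibble(sample_id = paste0("s", 1:3),
                            condition = c("control", "control", "exposed"))
  cpm_tbl <- tibble::tibble(feature_id = "x", s1 = 1, s2 = 1, s3 = 0)
  # CPM >= 1 in 2 of 3 control samples: 2 > 1.5 -> pass
  out <- filter_expression(cand, cpm_tbl, design3)
  expect_equal(out$filter_expression, "pass")
  design8 <- tiny_design(4)
  cpm8 <- tibble::tibble(feature_id = "x", s1 = 1, s2 = 1, s3 = 0, s4 = 0,
                         s5 = 1, s6 = 1, s7 = 0.5, s8 = 0)
  # exactly half of every group -> fail (strict majority required)
  out2 <- filter_expression(cand, cpm8, design8)
  expect_equal(out2$filter_expression, "fail")
})

test_that("classification follows coding > noncoding > TE_transcript > TE_no_gene", {
  tes <- chim_tes()
  gm <- chim_genes()
  pass_all <- function(cand) {
    cand$filter_novel_first_exon <- "pass"
    cand$filter_junction <- "pass"
    cand$filter_expression <- "pass"
    cand
  }
  asm <- dplyr::bind_rows(
    as_model("to_coding", c(1100, 5000), c(1300, 5400)),
    as_model("to_noncoding", c(1100, 40000), c(1300, 40400)),
    as_model("whole_te", 20050, 20550),
    as_model("to_nothing", c(1100, 30000), c(1300, 30200)))
  cand <- pass_all(detect_te_first_exon(asm, tes))
  cand$filter_junction[cand$transcript_id == "whole_te"] <- "not_applicable"
  out <- classify_chimeric(cand, gm, tes)
  lut <- setNames(out$category, out$transcript_id)
  expect_equal(unname(lut["to_coding"]), "TE_coding_gene")
  expect_equal(unname(lut["to_noncoding"]), "TE_noncoding_gene")
  expect_equal(unname(lut["whole_te"]), "TE_transcript")
  expect_equal(out$covering_tes[out$transcript_id == "whole_te"], "te_000002")
  expect_equal(unname(lut["to_nothing"]), "TE_no_gene")

  # antisense within a coding exon region: no same-strand overlap -> no_gene
  anti <- pass_all(detect_te_first_exon(
    as_model("anti", c(5000, 20100), c(5400, 20300), strand = "-"), tes))
  out2 <- classify_chimeric(anti, gm, tes)
  expect_equal(out2$category, "TE_no_gene")

  # a failed ledger leaves the candidate unclassified
  failed <- cand
  failed$filter_expression <- "fail"
  out3 <- classify_chimeric(failed, gm, tes)
  expect_equal(unique(out3$category), "unclassified")
  expect_false(any(out3$passes_filters))
})

test_that("find_orf returns the longest ATG..stop frame above the minimum", {
  # two ORFs: 30 nt and a longer 45 nt one; the longer wins
  s <- paste0("CC", "ATG", strrep("GAA", 8), "TAA",
              "GG", "ATG", strrep("GCT", 13), "TGA", "AA")
  out <- find_orf(s, min_length = 30)
  expect_equal(out$length_nt, 45)
  expect_equal(out$peptide, paste0("M", strrep("A", 13)))
  expect_null(find_orf("CCCGGGTTTAAACCC", min_length = 6))  # no ATG
  expect_error(find_orf("ATGXXX"), "ACGTN")
  # below the minimum length -> nothing
  expect_null(find_orf(paste0("ATG", strrep("GAA", 5), "TAA"),
                       min_length = 300))
})

test_that("an N-terminal extension lengthens the peptide by length/3 residues", {
  core <- paste0("ATG", strrep("GAC", 40), "TAA")      # 126 nt, 41 aa
  extended <- paste0("ATG", strrep("GAG", 64), core)   # +195 nt of coding
  p1 <- find_orf(core, min_length = 60)$peptide
  p2 <- find_orf(extended, min_length = 60)$peptide
  expect_equal(nchar(p2) - nchar(p1), 65)
})

test_that("find_orf agrees with position-by-position enumeration", {
  set.seed(61)
  for (i in 1:25) {
    s <- random_dna_string(sample(200:1200, 1))
    got <- find_orf(s, min_length = 60)
    want <- oracle_orf(s, min_length = 60)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$start, want$start)
      expect_equal(got$length_nt, want$length_nt)
    }
  }
})

test_that("spliced sequences concatenate exons and reverse-complement on minus", {
  genome <- c(chr1 = "AAACCCGGGTTTAAACCCGGGTTT")
  plus <- as_model("p", c(0, 12), c(3, 15))
  expect_equal(unname(extract_spliced_sequence(plus, genome)), "AAAAAA")
  minus <- as_model("m", c(0, 12), c(3, 15), strand = "-")
  expect_equal(unname(extract_spliced_sequence(minus, genome)), "TTTTTT")
})
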