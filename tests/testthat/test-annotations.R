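rmsk_file <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  header <- paste(c("genoName", "genoStart", "genoEnd", "strand", "repName",
                    "repClass", "repFamily"), collapse = "\t")
  writeLines(c(header, rows), path)
  path
}

test_that("rmsk reading drops simple repeats/satellites and keeps the four TE classes", {
  path <- rmsk_file(c(
    "chr1\t999\t1200\t+\tMTC\tLTR\tERVL-MaLR",
    "chr1\t2000\t2100\t+\t(AT)n\tSimple_repeat\tSimple_repeat",
    "chr1\t3000\t3500\t-\tGSAT_MM\tSatellite\tSatellite",
    "chr1\t4000\t4100\t+\tpoly_A\tLow_complexity\tLow_complexity",
    "chr2\t10\t600\tC\tL1Md_A\tLINE\tL1"
  ))
  tes <- read_te_annotation(path, dialect = "rmsk")
  expect_equal(nrow(tes), 2)
  expect_equal(tes$start[1], 999)
  expect_equal(tes$end[1], 1200)
  expect_equal(tes$subfamily, c("MTC", "L1Md_A"))
  # rmsk "C" strand is the reverse strand
  expect_equal(tes$strand[2], "-")
  # uids follow file order even after filtering
  expect_equal(tes$uid, c("te_000001", "te_000005"))
})

test_that("unknown repeat classes are skipped with a warning, empty files are fine", {
  path <- rmsk_file("chr1\t5\t50\t+\tweird\tUnknownClass\tx")
  expect_warning(tes <- read_te_annotation(path), "UnknownClass")
  expect_equal(nrow(tes), 0)

  empty <- rmsk_file(character())
  expect_silent(tes2 <- read_te_annotation(empty))
  expect_equal(nrow(tes2), 0)
})

test_that("malformed coordinates raise a parse error naming the line", {
  path <- rmsk_file("chr1\tnot_a_number\t50\t+\tMTC\tLTR\tfam")
  expect_error(read_te_annotation(path), "line 2")
})

test_that("TE BED round-trip preserves interval, strand and subfamily", {
  tes <- random_te_annotation(50)
  path <- withr::local_tempfile(fileext = ".bed")
  write_te_bed(tes, path)
  back <- read_te_annotation(path, dialect = "bed")
  expect_equal(back$chrom, tes$chrom)
  expect_equal(back$start, tes$start)
  expect_equal(back$end, tes$end)
  expect_equal(back$strand, tes$strand)
  expect_equal(back$subfamily, tes$subfamily)
  expect_equal(back$te_class, tes$te_class)
})

test_that("clade assignment follows the taxon mapping and is order-invariant", {
  taxa <- tibble::tibble(
    subfamily = c("a", "b", "c", "d", "e", "f", "g"),
    taxon = c("Mus_musculus", "Mus_genus", "Murinae", "Muridae",
              "Glires", "Rodentia", "Theria"))
  tes <- random_te_annotation(40)
  tes$subfamily <- rep_len(c(taxa$subfamily, "unmapped"), nrow(tes))
  out <- suppressMessages(assign_clades(tes, taxa))
  lut <- setNames(out$clade, out$subfamily)
  expect_equal(unname(lut[c("a", "b")]), rep("Mus_musculus", 2))
  expect_equal(unname(lut[c("c", "d")]), rep("Muridae", 2))
  expect_equal(unname(lut[c("e", "f")]), rep("Rodentia", 2))
  expect_equal(unname(lut["g"]), "Other")
  expect_equal(unname(lut["unmapped"]), "Other")

  shuffled <- tes[sample.int(nrow(tes)), ]
  out2 <- suppressMessages(assign_clades(shuffled, taxa))
  joined <- dplyr::left_join(out["uid"], out2[, c("uid", "clade")], by = "uid")
  expect_equal(joined$clade, out$clade)
})

test_that("GTF gene models convert coordinates and derive strand-aware TSS", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\texon\t101\t200\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1"; transcript_type "protein_coding";'),
    paste0("chr1\tsrc\texon\t301\t400\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1"; transcript_type "protein_coding";'),
    paste0("chr1\tsrc\texon\t101\t200\t.\t-\t.\t",
           'gene_id "g2"; transcript_id "t2"; transcript_type "lincRNA";'),
    paste0("chr1\tsrc\texon\t301\t400\t.\t-\t.\t",
           'gene_id "g2"; transcript_id "t2"; transcript_type "lincRNA";')
  ), gtf)
  tx <- read_gene_models(gtf)
  t1 <- tx[tx$transcript_id == "t1", ]
  expect_equal(t1$exons[[1]]$start, c(100, 300))  # 1-based -> 0-based
  expect_equal(t1$exons[[1]]$end, c(200, 400))
  expect_equal(t1$tss, 100)
  t2 <- tx[tx$transcript_id == "t2", ]
  expect_equal(t2$tss, 399)  # minus strand: end of last exon - 1
  expect_equal(t2$tts, 100)
  expect_equal(t2$gene_biotype, "noncoding")
  expect_equal(t1$gene_biotype, "coding")
})

test_that("transcripts without exon rows are rejected by name", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\ttranscript\t101\t400\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t_orphan"; transcript_type "protein_coding";')
  ), gtf)
  expect_error(read_gene_models(gtf), "t_orphan")
})

test_that("subfamily summaries compute fractions that sum to 1 and honour the bp rule", {
  tes <- tibble::tibble(
    chrom = "chr1",
    start = c(0, 200, 400, 600, 800, 1000, 1200, 1400, 1600, 1800),
    end = c(0, 200, 400, 600, 800, 1000, 1200, 1400, 1600, 1800) + 100,
    strand = "+", family = "f", te_class = "LTR", clade = "Other",
    subfamily = rep(c("A", "B"), c(3, 7)),
    uid = sprintf("te_%06d", 1:10))
  s <- subfamily_summaries(tes)
  expect_equal(s$copy_fraction[s$subfamily == "A"], 0.3)
  expect_equal(s$copy_fraction[s$subfamily == "B"], 0.7)
  expect_equal(sum(s$copy_fraction), 1)
  expect_equal(sum(s$bp_fraction), 1)

  one <- subfamily_summaries(tes[tes$subfamily == "A", ])
  expect_equal(one$copy_fraction, 1)

  # overlapping copies: linear sum by default, interval union as option
  ov <- tibble::tibble(chrom = "chr1", start = c(100, 150), end = c(200, 250),
                       strand = "+", subfamily = "A", family = "f",
                       te_class = "LTR", clade = "Other",
                       uid = c("te_000001", "te_000002"))
  expect_equal(subfamily_summaries(ov)$bp_total, 200)
  expect_equal(subfamily_summaries(ov, merge_overlaps = TRUE)$bp_total, 150)

  expect_error(subfamily_summaries(tes[0, ]), "empty")
})

test_that("subfamily summaries are invariant under record shuffling", {
  tes <- random_te_annotation(200)
  s1 <- subfamily_summaries(tes) |> dplyr::arrange(subfamily)
  s2 <- subfamily_summaries(tes[sample.int(nrow(tes)), ]) |>
    dplyr::arrange(subfamily)
  expect_equal(s1, s2)
})
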