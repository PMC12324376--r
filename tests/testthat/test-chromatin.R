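simple_tes <- function(...) {
  rows <- list(...)
  purrr::map_dfr(seq_along(rows), function(i) {
    r <- rows[[i]]
    tibble::tibble(chrom = r[[1]], start = r[[2]], end = r[[3]], strand = "+",
                   subfamily = if (length(r) >= 4) r[[4]] else "sfA",
                   family = "f", te_class = "LTR", clade = "Other",
                   uid = sprintf("te_%06d", i))
  })
}

test_that("summit assignment is half-open and prefers the innermost element", {
  tes <- simple_tes(list("chr1", 1000, 2000, "sfA"),
                    list("chr1", 0, 5000, "sfB"),
                    list("chr1", 1400, 1600, "sfC"))
  peaks <- tibble::tibble(
    peak_id = c("p1", "p2", "p3"),
    chrom = "chr1", start = c(1400, 1900, 6000),
    end = c(1700, 2100, 6400), summit = c(1500, 2000, 6200))
  out <- assign_summits_to_tes(peaks, tes)
  # nested tie-break: shortest element wins
  expect_equal(out$te_uid[1], "te_000003")
  # summit exactly at a TE end is outside (half-open); falls to the outer copy
  expect_equal(out$te_uid[2], "te_000002")
  expect_false(out$is_te_derived[3])
  expect_true(is.na(out$te_uid[3]))

  bad <- dplyr::mutate(peaks, summit = end + 5)
  expect_error(assign_summits_to_tes(bad, tes), "summit outside")
})

test_that("DA-TE calls inherit DAR direction and keep the smallest-FDR record", {
  tes <- simple_tes(list("chr1", 1000, 2000, "sfA"))
  dars <- tibble::tibble(
    peak_id = c("d1", "d2", "d3"),
    chrom = "chr1", start = c(1000, 1500, 4000), end = c(1400, 1900, 4400),
    summit = c(1200, 1700, 4200),
    status = c("up", "up", "down"),
    fdr = c(1e-3, 1e-5, 1e-4), log2fc = c(1, 2, -1))
  out <- call_da_tes(dars, tes)
  expect_equal(nrow(out), 1)  # d3's summit is not in a TE
  expect_equal(out$peak_id, "d2")
  expect_equal(out$status, "up")
  expect_equal(out$fdr, 1e-5)
  # ns records never produce DA-TEs
  none <- call_da_tes(dplyr::mutate(dars, status = "ns"), tes)
  expect_equal(nrow(none), 0)
})

test_that("genomic feature labels follow the declared precedence", {
  gm <- build_transcript_models(tibble::tibble(
    transcript_id = "t1", gene_id = "g1", chrom = "chr1",
    start = c(10000, 14000, 18000), end = c(10400, 14400, 18400),
    strand = "+", transcript_type = "protein_coding"))
  tes <- simple_tes(
    list("chr1", 10100, 10300),   # exon AND TSS window -> TSS
    list("chr1", 14100, 14300),   # exon only (3 kb from TSS/TTS) -> exon
    list("chr1", 12500, 12800),   # intron only
    list("chr1", 17600, 17800),   # TTS window (tts = 18399)
    list("chr1", 40000, 40300))   # intergenic
  out <- genomic_feature_assignment(tes, gm)
  expect_equal(out$genomic_feature,
               c("TSS", "exon", "intron", "TTS", "intergenic"))
  # labels partition the input
  expect_equal(nrow(out), nrow(tes))
})

test_that("cCRE labels use the largest overlap with the declared tie-break", {
  tes <- simple_tes(list("chr1", 1000, 1100), list("chr1", 2000, 2100),
                    list("chr1", 3000, 3100))
  ccres <- tibble::tibble(
    chrom = "chr1",
    start = c(1040, 990, 2020),
    end = c(1080, 1050, 2080),
    ccre_type = c("dELS", "pELS", "dELS"))
  out <- annotate_ccre(tes, ccres)
  # te1: pELS overlap 50 bp < dELS 40 bp? no: pELS covers [1000,1050) = 50,
  # dELS [1040,1080) = 40 -> pELS wins on overlap alone
  expect_equal(out$ccre, c("pELS", "dELS", "None"))
  # equal overlaps resolve by PLS > pELS > dELS > DNase-H3K4me3 > CTCF-only
  tie <- tibble::tibble(chrom = "chr1", start = c(1000, 1000),
                        end = c(1060, 1060),
                        ccre_type = c("dELS", "pELS"))
  expect_equal(annotate_ccre(tes[1, ], tie)$ccre, "pELS")
  expect_error(annotate_ccre(tes, dplyr::mutate(ccres, ccre_type = "bogus")),
               "unknown cCRE")
})

test_that("subfamily enrichment reproduces hand-computed ratios and enumerated p", {
  background <- tibble::tibble(
    subfamily = c("sfA", "sfB"), te_class = "LTR", clade = "Other",
    copy_count = c(10L, 990L), bp_total = c(1000L, 99000L),
    copy_fraction = c(0.01, 0.99), bp_fraction = c(0.01, 0.99))
  da <- tibble::tibble(uid = sprintf("te_%06d", 1:50),
                       subfamily = rep(c("sfA", "sfB"), c(10, 40)),
                       start = 0L, end = 100L)
  out <- subfamily_enrichment(da, background)
  a <- out[out$name == "sfA", ]
  expect_equal(a$ratio, (10 / 50) / 0.01)  # 20
  expect_equal(a$log2_ratio, log2(20))
  # all 10 genome copies drawn: matches exhaustive enumeration
  expect_equal(a$pvalue, oracle_hyper_upper(10, 10, 1000, 50),
               tolerance = 1e-12)
  b <- out[out$name == "sfB", ]
  expect_equal(b$pvalue, oracle_hyper_upper(40, 990, 1000, 50),
               tolerance = 1e-12)
  # fraction equal to background -> ratio 1
  bg2 <- dplyr::mutate(background, copy_fraction = c(0.2, 0.8))
  expect_equal(subfamily_enrichment(da, bg2)$ratio[
    subfamily_enrichment(da, bg2)$name == "sfA"], 1)
  expect_error(
    subfamily_enrichment(dplyr::mutate(da, subfamily = "sfX"), background),
    "absent from background")
  expect_error(subfamily_enrichment(da[0, ], background), "empty")
})

test_that("class enrichment over shared DA-subfamilies matches arithmetic", {
  all_sf <- tibble::tibble(
    subfamily = sprintf("sf%03d", 1:100),
    te_class = rep(c("LINE", "SINE", "LTR", "DNA"), c(20, 30, 30, 20)))
  shared <- c(sprintf("sf%03d", 1:7), sprintf("sf%03d", 21:23))  # 7 LINE, 3 SINE
  out <- class_enrichment_shared(shared, all_sf)
  expect_equal(out$ratio[out$name == "LINE"], (7 / 10) / 0.2)  # 3.5
  expect_equal(out$ratio[out$name == "LTR"], 0)
  # shared set = everything -> all ratios 1
  out_all <- class_enrichment_shared(all_sf$subfamily, all_sf)
  expect_equal(out_all$ratio, rep(1, 4))
  expect_error(class_enrichment_shared(character(), all_sf), "empty")
})

test_that("exposure specificity counts per-TE multiplicity", {
  out <- exposure_specificity(list(A = c("1", "2"), B = c("2", "3")))
  expect_equal(out$unique_fraction, 2 / 3)
  expect_equal(exposure_specificity(list(A = "1", B = "2"))$unique_fraction, 1)
  expect_equal(exposure_specificity(list(A = c("1", "2"),
                                         B = c("1", "2")))$unique_fraction, 0)
  expect_error(exposure_specificity(list(A = "1")), "at least 2")
})

test_that("enrichment ratios are invariant under background record order", {
  sim <- shared_sim()
  bg1 <- subfamily_summaries(sim$tes)
  bg2 <- subfamily_summaries(sim$tes[sample.int(nrow(sim$tes)), ])
  da <- dplyr::slice_sample(sim$tes, n = 80)
  e1 <- subfamily_enrichment(da, bg1) |> dplyr::arrange(name)
  e2 <- subfamily_enrichment(da, bg2) |> dplyr::arrange(name)
  expect_equal(e1, e2)
})
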