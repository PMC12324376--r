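test_that("annotation bookkeeping: 20 subfamilies x 50 copies on 2 x 1 Mb gives 1000 TEs", {
  cfg <- small_config()
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann$tes), 1000)
  expect_equal(length(unique(ann$tes$subfamily)), 20)
  expect_setequal(unique(ann$tes$te_class), c("DNA", "LINE", "SINE", "LTR"))
  expect_true(all(ann$tes$clade %in%
                    c("Mus_musculus", "Muridae", "Rodentia", "Other")))
  expect_equal(anyDuplicated(ann$tes$uid), 0)
  # every counted cross-reference resolves
  expect_true(all(ann$plant$uid %in% ann$tes$uid))
  # capacity guard
  expect_error(
    simulate_annotation(simulation_config(copies_per_subfamily = 5000)),
    "capacity")
})

test_that("identical config and seed reproduce the dataset byte for byte", {
  cfg <- small_config(seed = 9)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_equal(s1$tes, s2$tes)
  expect_equal(s1$peaks, s2$peaks)
  expect_equal(s1$counts, s2$counts)
  expect_equal(s1$junctions, s2$junctions)
  expect_equal(s1$methylation, s2$methylation)
  expect_equal(as.character(s1$genome), as.character(s2$genome))

  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  write_dataset(s1, d1); write_dataset(s2, d2)
  f <- list.files(d1)
  expect_setequal(f, list.files(d2))
  expect_equal(unname(tools::md5sum(file.path(d1, f))),
               unname(tools::md5sum(file.path(d2, f))))
})

test_that("the realized TE-summit fraction stays within binomial tolerance", {
  sim <- shared_sim()
  frac <- mean(sim$truth$peaks$in_te)
  p <- sim$config$te_summit_fraction
  tol <- 3.5 * sqrt(p * (1 - p) / sim$config$n_peaks)
  expect_lt(abs(frac - p), tol)
  # planted in-TE summits really fall inside the recorded TE copy
  t_in <- dplyr::filter(sim$truth$peaks, in_te) |>
    dplyr::left_join(sim$peaks[, c("peak_id", "summit")], by = "peak_id") |>
    dplyr::left_join(sim$tes[, c("uid", "start", "end")],
                     by = c(te_uid = "uid"))
  expect_true(all(t_in$summit >= t_in$start & t_in$summit < t_in$end))
})

test_that("simulated counts approach Poisson in the vanishing-dispersion limit", {
  cfg <- simulation_config(seed = 3, nb_dispersion = 1e-8, library_sdlog = 0)
  out <- simulate_counts(cfg, sprintf("f%04d", 1:2000), design_sheet(cfg),
                         base_meanlog = log(200), base_sdlog = 0.3)
  m <- as.matrix(out$counts[, -1])
  ratio <- apply(m, 1, var) / rowMeans(m)
  expect_equal(mean(ratio), 1, tolerance = 0.02)
})

test_that("planted effects shift group means by the configured log2 fold change", {
  cfg <- simulation_config(seed = 4, library_sdlog = 0)
  design <- design_sheet(cfg)
  planted <- tibble::tibble(feature_id = sprintf("f%03d", 1:50),
                            sex = "F", exposure = "expoA", true_log2fc = 2)
  out <- simulate_counts(cfg, sprintf("f%03d", 1:200), design, planted,
                         base_meanlog = log(400), base_sdlog = 0.3)
  m <- as.matrix(out$counts[, -1])
  rownames(m) <- out$counts$feature_id
  exp_cols <- design$sample_id[design$sex == "F" & design$exposure == "expoA"]
  ctl_cols <- design$sample_id[design$sex == "F" & design$condition == "control"]
  lfc <- log2(rowMeans(m[, exp_cols]) / rowMeans(m[, ctl_cols]))
  expect_equal(mean(lfc[1:50]), 2, tolerance = 0.15)
  # null features: group means equal in expectation
  expect_equal(mean(lfc[51:200]), 0, tolerance = 0.1)
  # truth table covers every feature once per contrast
  expect_equal(nrow(out$truth), 200 * 4)
  expect_equal(sum(out$truth$is_differential), 50)
})

test_that("TE copies diverge from consensus at the configured rate", {
  cfg <- small_config(seed = 6)
  seqs <- simulate_te_sequences(cfg)
  # a non-motif subfamily: mean identity ~ 1 - divergence * 3/4... no:
  # substitutions always change the base, so identity ~ 1 - 0.05
  sf <- setdiff(unique(seqs$copies$subfamily), seqs$motif_subfamily)[1]
  cons <- strsplit(seqs$consensus[[sf]], "")[[1]]
  copies <- dplyr::filter(seqs$copies, subfamily == sf)
  ident <- vapply(copies$sequence, function(s) {
    mean(strsplit(s, "")[[1]] == cons)
  }, numeric(1))
  expect_equal(mean(ident), 1 - cfg$copy_divergence, tolerance = 0.01)

  # zero divergence: copies identical to consensus, motifs intact
  cfg0 <- small_config(seed = 6)
  cfg0$copy_divergence <- 0
  cfg0$frac_motif_ablated <- 0
  seqs0 <- simulate_te_sequences(cfg0)
  expect_true(all(vapply(seq_len(nrow(seqs0$copies)), function(i) {
    seqs0$copies$sequence[i] == seqs0$consensus[[seqs0$copies$subfamily[i]]]
  }, logical(1))))

  # ablated copies carry no intact motif instance at the planted offsets
  motif_copies <- dplyr::filter(seqs$copies,
                                subfamily == seqs$motif_subfamily,
                                motif_ablated)
  expect_gt(nrow(motif_copies), 0)
  motifs <- rep_len(cfg$motif_strings, length(cfg$motif_offsets))
  for (i in seq_len(nrow(motif_copies))) {
    for (k in seq_along(cfg$motif_offsets)) {
      instance <- substr(motif_copies$sequence[i],
                         cfg$motif_offsets[k] + 1,
                         cfg$motif_offsets[k] + nchar(motifs[[k]]))
      expect_false(instance == motifs[[k]])
    }
  }
})

test_that("the methylation generator recovers the planted shift and keeps low-coverage sites", {
  sim <- shared_sim()
  raw <- sim$methylation
  expect_gt(sum(raw$coverage < 20), 0)  # the 20X filter has work to do
  cpgs <- filter_cpgs(raw)
  contrast <- suppressMessages(methylation_contrast(
    cpgs, sim$tes, sim$methylation_design,
    subfamilies = sim$truth$methylation$subfamily))
  expect_equal(mean(contrast$per_subfamily$difference),
               sim$config$meth_shift, tolerance = 0.03)
})

test_that("the no-shift methylation null yields uniform paired-test p-values", {
  tes <- random_te_annotation(90)
  tes$subfamily <- rep(sprintf("sf%02d", 1:30), 3)
  pv <- vapply(1:40, function(i) {
    cfg <- simulation_config(seed = 1000 + i, n_planted_hypo_subfams = 0,
                             n_cpgs_outside = 10)
    meth <- simulate_methylation(cfg, tes, design_sheet(cfg))
    suppressMessages(
      methylation_contrast(filter_cpgs(meth$cpgs), tes, meth$design)
    )$test$pvalue
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})
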