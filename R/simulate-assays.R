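# Assay-level generators: NB count matrices with planted effects, chimeric
# transcript models with junction support, CpG methylation.

# Choose planted differential features for every (sex, exposure) contrast.
# paired_sexes = TRUE mirrors the subfamily analysis: males get the same
# features as females for each exposure, with 3/4 of the signs flipped so the
# sexes respond discordantly.
plant_effects <- function(config, eligible, n_diff, paired_sexes = FALSE,
                          must_include = character()) {
  out <- list()
  for (ex in config$exposures) {
    if (paired_sexes) {
      feats <- sample(eligible, n_diff)
      signs_f <- rep_len(c(1, -1), n_diff)
      flip <- rep_len(c(-1, -1, -1, 1), n_diff)
      for (sx in config$sexes) {
        signs <- if (sx == config$sexes[1]) signs_f else signs_f * flip
        out[[paste(sx, ex)]] <- tibble(
          feature_id = feats, sex = sx, exposure = ex,
          true_log2fc = signs * config$effect_log2fc)
      }
    } else {
      for (sx in config$sexes) {
        n_extra <- max(0, n_diff - length(must_include))
        feats <- c(must_include,
                   sample(setdiff(eligible, must_include), n_extra))
        out[[paste(sx, ex)]] <- tibble(
          feature_id = feats, sex = sx, exposure = ex,
          true_log2fc = rep_len(c(1, -1), length(feats)) * config$effect_log2fc)
      }
    }
  }
  bind_rows(out)
}

#' Simulate a negative-binomial count matrix with planted effects
#'
#' Counts are NB with per-feature log-normal base means, log-normal
#' library-size factors, the configured dispersion, and mean multiplied by
#' `2^true_log2fc` in the samples of the contrasts where the feature carries
#' a planted effect.
#'
#' @param config A [simulation_config()].
#' @param feature_ids Feature identifiers (matrix rows).
#' @param design Sample sheet from [design_sheet()].
#' @param planted Tibble `feature_id`, `sex`, `exposure`, `true_log2fc` (from
#'   `plant_effects()`); NULL for an all-null matrix.
#' @param base_meanlog,base_sdlog Log-normal base-mean parameters.
#' @param low_features Features forced to near-zero means (exercise CPM
#'   prefilters).
#' @param salt Integer distinguishing repeated draws (one per tier).
#' @return A list: `counts` tibble and a full `truth` tibble (every feature
#'   by contrast, `true_log2fc`, `is_differential`).
#' @export
simulate_counts <- function(config, feature_ids, design, planted = NULL,
                            base_meanlog = log(300), base_sdlog = 0.7,
                            low_features = character(), salt = 0L) {
  if (nrow(design) == 0 || min(table(design$condition)) < 2) {
    abort("design needs at least 2 samples per condition")
  }
  n_f <- length(feature_ids)
  with_stream(config$seed, "counts", salt = salt, {
    base <- rlnorm(n_f, base_meanlog, base_sdlog)
    names(base) <- feature_ids
    base[low_features] <- 0.05
    libf <- rlnorm(nrow(design), 0, config$library_sdlog)

    beta <- matrix(0, nrow = n_f, ncol = nrow(design),
                   dimnames = list(feature_ids, design$sample_id))
    if (!is.null(planted) && nrow(planted) > 0) {
      for (k in seq_len(nrow(planted))) {
        cols <- design$sample_id[design$condition == "exposed" &
                                   design$sex == planted$sex[k] &
                                   design$exposure == planted$exposure[k]]
        beta[planted$feature_id[k], cols] <- planted$true_log2fc[k]
      }
    }
    mu <- outer(base, libf) * 2^beta
    counts <- matrix(
      rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
      nrow = n_f, dimnames = dimnames(beta))

    truth <- tidyr::crossing(
      feature_id = feature_ids, sex = config$sexes,
      exposure = config$exposures)
    if (!is.null(planted) && nrow(planted) > 0) {
      truth <- truth |>
        left_join(planted, by = c("feature_id", "sex", "exposure"))
    } else {
      truth$true_log2fc <- NA_real_
    }
    truth <- truth |>
      mutate(true_log2fc = dplyr::coalesce(.data$true_log2fc, 0),
             is_differential = .data$true_log2fc != 0,
             is_low_expressed = .data$feature_id %in% low_features)
    list(counts = matrix_to_tibble(counts), truth = truth)
  })
}

# 366-nt ORF cassette with a unique ATG: prefix without ATG, ATG + 120 GAA
# codons + TAA, stop-dense suffix. Spliced length 600 = 200 (exon1) + 400
# (exon2); the ORF starts at spliced offset 30.
planted_orf_cassette <- function() {
  orf <- paste0("ATG", strrep("GAA", 120), "TAA")
  spliced <- paste0(strrep("TTA", 10), orf, strrep("TAA", 68))
  stopifnot(nchar(spliced) == 600)
  list(spliced = spliced, start = 30L, length_nt = 366L,
       peptide = paste0("M", strrep("E", 120)))
}

#' Simulate assembled chimeric transcripts, decoys, and junction support
#'
#' Builds assembled transcript models around the anchor TEs planted by
#' [simulate_annotation()]: survivors of all four categories (coding-gene and
#' noncoding-gene chimeras splicing from a TE first exon into a known exon,
#' wholly-TE single-exon transcripts, no-gene transcripts including an
#' antisense-in-intron case), one decoy per filter (first exon overlapping a
#' known exon; junction support below 2 reads in every sample; CPM quorum
#' failure), and two non-TE transcripts that must not be detected. One
#' coding survivor carries a designed 366-nt ORF written into the genome.
#'
#' @param config A [simulation_config()].
#' @param ann Output of [simulate_annotation()].
#' @param genome `DNAStringSet` from `assemble_genome()`.
#' @param design Sample sheet.
#' @return A list: `assembled` (transcript model tibble), `junctions`,
#'   `truth` (per transcript: `is_candidate`, `passes_filters`,
#'   `failing_filter`, `true_category`), `orf_truth`, `cpm_decoy_id`, and the
#'   modified `genome`.
#' @export
simulate_chimeric_transcripts <- function(config, ann, genome, design) {
  plant <- ann$plant
  genes <- ann$genes
  gene_base <- setNames(genes$base, genes$gene_id)

  anchor <- function(role_name) dplyr::filter(plant, .data$role == role_name)
  coding_anchors <- anchor("chimeric_coding")
  nc_anchors <- anchor("chimeric_noncoding")
  anti_anchor <- anchor("intron_antisense")[1, ]
  tss_anchor <- anchor("tss")[1, ]

  rows <- list()
  truth <- list()
  add_tx <- function(id, chrom, strand, exon_mat, is_candidate, passes,
                     failing = NA_character_, category = NA_character_) {
    rows[[length(rows) + 1]] <<- tibble(
      transcript_id = id, gene_id = id, chrom = chrom,
      start = exon_mat[, 1], end = exon_mat[, 2], strand = strand,
      transcript_type = "other", peptide = NA_character_)
    truth[[length(truth) + 1]] <<- tibble(
      transcript_id = id, is_candidate = is_candidate,
      passes_filters = passes, failing_filter = failing,
      true_category = category)
  }
  two_exon <- function(a, gid) {
    e1 <- c(a$start + 50L, a$start + 250L)
    e2 <- gene_base[[gid]] + GENE_EXONS$e2
    rbind(e1, e2)
  }

  # coding-gene survivors (first carries the planted ORF)
  for (i in 1:3) {
    a <- coding_anchors[i, ]
    add_tx(sprintf("chim_coding_%d", i), a$chrom, "+",
           two_exon(a, a$gene_id), TRUE, TRUE, category = "TE_coding_gene")
  }
  # junction decoy and CPM decoy share the coding-gene geometry
  a <- coding_anchors[4, ]
  add_tx("chim_decoy_junction", a$chrom, "+", two_exon(a, a$gene_id),
         TRUE, FALSE, failing = "junction")
  a <- coding_anchors[5, ]
  add_tx("chim_decoy_cpm", a$chrom, "+", two_exon(a, a$gene_id),
         TRUE, FALSE, failing = "expression")
  # noncoding-gene survivors
  for (i in 1:2) {
    a <- nc_anchors[i, ]
    add_tx(sprintf("chim_noncoding_%d", i), a$chrom, "+",
           two_exon(a, a$gene_id), TRUE, TRUE, category = "TE_noncoding_gene")
  }
  # wholly-TE single-exon transcripts and the gap no-gene transcript use
  # unplanted plus-strand base TEs on chr1
  free_tes <- ann$tes |>
    filter(.data$chrom == "chr1", !.data$uid %in% plant$uid) |>
    arrange(.data$start) |>
    head(3)
  for (i in 1:2) {
    te <- free_tes[i, ]
    add_tx(sprintf("chim_te_only_%d", i), te$chrom, "+",
           rbind(c(te$start + 20L, te$end - 20L)),
           TRUE, TRUE, category = "TE_transcript")
  }
  te <- free_tes[3, ]
  gap_start <- floor(0.60 * config$chrom_length_bp) + 2000L
  add_tx("chim_no_gene_gap", te$chrom, "+",
         rbind(c(te$start + 50L, te$start + 250L),
               c(gap_start, gap_start + 150L)),
         TRUE, TRUE, category = "TE_no_gene")
  # antisense transcript inside a coding gene's intron
  b <- gene_base[[anti_anchor$gene_id]]
  add_tx("chim_antisense", anti_anchor$chrom, "-",
         rbind(c(b + 1910L, b + 1990L), c(b + 2150L, b + 2250L)),
         TRUE, TRUE, category = "TE_no_gene")
  # novel-first-exon decoy: first exon extends into the known alternative
  # first exon of a TSS-planted gene
  b <- gene_base[[tss_anchor$gene_id]]
  add_tx("chim_decoy_known_exon", tss_anchor$chrom, "+",
         rbind(c(b + 500L, b + 800L), b + GENE_EXONS$e3),
         TRUE, FALSE, failing = "novel_first_exon")
  # non-TE assembled transcripts: must not become candidates
  gap2 <- floor(0.60 * config$chrom_length_bp) + 10000L
  for (i in 1:2) {
    add_tx(sprintf("asm_non_te_%d", i), "chr2", "+",
           rbind(c(gap2 + i * 3000L, gap2 + i * 3000L + 200L),
                 c(gap2 + i * 3000L + 1000L, gap2 + i * 3000L + 1200L)),
           FALSE, FALSE)
  }

  assembled <- build_transcript_models(bind_rows(rows))
  truth <- bind_rows(truth)

  # plant the ORF cassette into chim_coding_1's spliced sequence
  cassette <- planted_orf_cassette()
  tx1 <- assembled |> filter(.data$transcript_id == "chim_coding_1")
  ex <- tx1$exons[[1]]
  genome[[tx1$chrom]] <- Biostrings::replaceAt(
    genome[[tx1$chrom]],
    IRanges::IRanges(ex$start + 1L, ex$end),
    Biostrings::DNAStringSet(c(substr(cassette$spliced, 1, 200),
                               substr(cassette$spliced, 201, 600))))
  orf_truth <- tibble(
    transcript_id = "chim_coding_1", start = cassette$start,
    length_nt = cassette$length_nt, peptide = cassette$peptide)

  # junction support per sample
  with_stream(config$seed, "chimeric", {
    multi <- assembled |> filter(.data$n_exons > 1)
    jrows <- purrr::map_dfr(seq_len(nrow(multi)), function(i) {
      tx <- multi[i, ]
      intr <- first_intron(tx)
      reads <- if (tx$transcript_id == "chim_decoy_junction") {
        sample(0:1, nrow(design), replace = TRUE)
      } else {
        r <- rpois(nrow(design), 8)
        r[1] <- max(r[1], 3)
        r
      }
      bind_cols(
        tibble(chrom = tx$chrom, intron_start = intr$start,
               intron_end = intr$end, strand = tx$strand),
        as_tibble(setNames(as.list(reads), design$sample_id)))
    })
    noise <- purrr::map_dfr(1:5, function(i) {
      bind_cols(
        tibble(chrom = "chr2", intron_start = 700000L + i * 1000L,
               intron_end = 700000L + i * 1000L + 300L, strand = "+"),
        as_tibble(setNames(as.list(rpois(nrow(design), 4)),
                           design$sample_id)))
    })
    junctions <- bind_rows(jrows, noise)
    list(assembled = assembled, junctions = junctions, truth = truth,
         orf_truth = orf_truth, cpm_decoy_id = "chim_decoy_cpm",
         genome = genome)
  })
}

#' Simulate CpG methylation with planted subfamily shifts
#'
#' Places CpG sites inside every TE copy (3 per copy) and at TE-free
#' positions, draws NB coverage and Beta-binomial methylation around a
#' per-site mean, and shifts the site means of the planted LINE subfamilies
#' by `meth_shift` in exposed samples. The methylation arm covers one sex and
#' one exposure (plus matched controls), mirroring a single paired contrast.
#'
#' @param config A [simulation_config()].
#' @param tes TE annotation tibble.
#' @param design Sample sheet; the first sex and first exposure are used.
#' @return A list: `cpgs` (long tibble with `sample_id`), `design` (the
#'   sample subset), `truth` (`subfamily`, `true_meth_shift`).
#' @export
simulate_methylation <- function(config, tes, design) {
  meth_design <- design |>
    filter(.data$sex == config$sexes[1],
           .data$exposure %in% c("none", config$exposures[1]))
  planted_subfams <- subfamily_catalog(config) |>
    filter(.data$te_class == "LINE") |>
    head(config$n_planted_hypo_subfams) |>
    pull("subfamily")

  with_stream(config$seed, "methylation", {
    in_te <- purrr::map_dfr(seq_len(nrow(tes)), function(i) {
      w <- tes$end[i] - tes$start[i]
      offs <- sort(sample.int(w - 20L, 3) + 10L)
      tibble(chrom = tes$chrom[i], pos = tes$start[i] + offs,
             subfamily = tes$subfamily[i])
    })
    out_pos <- sort(sample.int(floor(0.03 * config$chrom_length_bp),
                               config$n_cpgs_outside)) +
      floor(0.96 * config$chrom_length_bp)
    outside <- tibble(chrom = "chr1", pos = as.integer(out_pos),
                      subfamily = NA_character_)
    sites <- bind_rows(in_te, outside)
    planted_site <- !is.na(sites$subfamily) &
      sites$subfamily %in% planted_subfams
    mu <- ifelse(planted_site,
                 runif(nrow(sites), 0.45, 0.85),
                 pmin(pmax(rbeta(nrow(sites), 5, 2), 0.02), 0.98))

    phi <- config$meth_concentration
    cpgs <- purrr::map_dfr(seq_len(nrow(meth_design)), function(j) {
      exposed <- meth_design$condition[j] == "exposed"
      mu_eff <- if (exposed) {
        pmin(pmax(mu + config$meth_shift * planted_site, 0.01), 0.99)
      } else mu
      coverage <- pmax(rnbinom(nrow(sites), mu = config$coverage_mean,
                               size = 1 / config$coverage_dispersion), 1L)
      p <- rbeta(nrow(sites), phi * mu_eff, phi * (1 - mu_eff))
      tibble(chrom = sites$chrom, pos = sites$pos, strand = "+",
             methylated = rbinom(nrow(sites), coverage, p),
             coverage = coverage,
             sample_id = meth_design$sample_id[j])
    })
    list(cpgs = cpgs, design = meth_design,
         truth = tibble(subfamily = planted_subfams,
                        true_meth_shift = config$meth_shift))
  })
}
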