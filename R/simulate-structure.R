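# Structural generators: TE copy sequences, annotation placement, genes,
# cCREs, peaks, and genome assembly. All randomness is drawn inside a single
# with_stream() block per generator so streams stay independent.

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

random_peptide <- function(n) {
  paste(sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], ""), n,
               replace = TRUE), collapse = "")
}

# Substitute each unprotected position independently with rate `rate`,
# drawing one of the three other bases.
substitute_bases <- function(chars, rate, protect = integer()) {
  hit <- which(runif(length(chars)) < rate)
  hit <- setdiff(hit, protect)
  for (i in hit) {
    chars[i] <- sample(setdiff(BASES, chars[i]), 1)
  }
  chars
}

#' Simulate TE copy sequences from subfamily consensuses
#'
#' Each subfamily gets a random consensus; the motif-bearing subfamily (the
#' first LTR subfamily, an ORR1E analog) carries the configured motif
#' instances at fixed offsets inside the core region. Copies are the
#' consensus with i.i.d. substitutions at `copy_divergence` (motif positions
#' are left intact so planted presence is exact); a trailing
#' `frac_motif_ablated` fraction of the motif subfamily's copies instead has
#' every motif instance ablated by targeted substitutions and extra
#' substitutions planted in its core region, creating the conservation
#' contrast between motif-bearing and motif-lacking copies.
#'
#' @param config A [simulation_config()].
#' @return A list: `consensus` (named character by subfamily), `copies`
#'   (tibble `subfamily`, `copy_index`, `sequence`, `motif_ablated`), and
#'   `motif_truth` (motif subfamily rows with `with_motif`).
#' @export
simulate_te_sequences <- function(config) {
  catalog <- subfamily_catalog(config)
  with_stream(config$seed, "sequences", {
    consensus <- vapply(catalog$subfamily, function(s) {
      random_dna(config$consensus_length)
    }, character(1))
    motif_sf <- catalog$subfamily[catalog$carries_motif]
    motifs <- rep_len(config$motif_strings,
                      length.out = length(config$motif_offsets))
    motif_positions <- integer()
    cons_chars <- strsplit(consensus[[motif_sf]], "")[[1]]
    for (k in seq_along(config$motif_offsets)) {
      off <- config$motif_offsets[k]
      mchars <- strsplit(motifs[[k]], "")[[1]]
      pos <- off + seq_along(mchars)  # 1-based
      cons_chars[pos] <- mchars
      motif_positions <- c(motif_positions, pos)
    }
    consensus[[motif_sf]] <- paste(cons_chars, collapse = "")

    n_copies <- config$copies_per_subfamily
    n_ablated <- round(config$frac_motif_ablated * n_copies)
    core <- (config$core_region[1] + 1):config$core_region[2]
    copies <- purrr::map_dfr(catalog$subfamily, function(sf) {
      cons <- strsplit(consensus[[sf]], "")[[1]]
      is_motif_sf <- sf == motif_sf
      purrr::map_dfr(seq_len(n_copies), function(i) {
        ablated <- is_motif_sf && i > n_copies - n_ablated
        protect <- if (is_motif_sf) motif_positions else integer()
        chars <- substitute_bases(cons, config$copy_divergence, protect)
        if (ablated) {
          shift_base <- function(b) BASES[(match(b, BASES) %% 4) + 1]
          for (off in config$motif_offsets) {
            for (rel in c(2L, 4L)) {
              chars[off + rel] <- shift_base(cons[off + rel])
            }
          }
          chars[core] <- substitute_bases(
            chars[core], config$ablated_core_extra_divergence)
        }
        tibble(subfamily = sf, copy_index = i,
               sequence = paste(chars, collapse = ""),
               motif_ablated = ablated)
      })
    })
    motif_truth <- copies |>
      filter(.data$subfamily == motif_sf) |>
      mutate(with_motif = !.data$motif_ablated) |>
      select("subfamily", "copy_index", "with_motif")
    list(consensus = consensus, copies = copies, motif_truth = motif_truth,
         motif_subfamily = motif_sf)
  })
}

# Relative gene architecture (all genes share it; 0-based offsets from the
# gene base). tx1 uses e1/e2/e3, tx2 uses e1b/e2/e3 so the isoforms differ
# at the 5' end and tx2's TSS can get a TE planted over it.
GENE_EXONS <- list(
  e1 = c(0L, 400L), e1b = c(600L, 900L),
  e2 = c(1500L, 1900L), e3 = c(3200L, 3600L)
)
GENE_SPAN <- 3600L

gene_category_cycle <- c("coding2", "coding_mix", "linc", "coding_alt",
                         "coding2", "other")

#' Simulate the TE and gene annotation with planted geometry
#'
#' Places TE copies on a jittered grid in the first 60% of each chromosome
#' and genes (two isoforms each, differing at the 5' end) on a regular pitch
#' in the 62-95% band, then relocates designated copies to plant the
#' geometry every downstream stage is tested on: TEs over the alternative
#' isoform's TSS, TEs inside exons/introns and over TTSs, anchor TEs for
#' chimeric transcripts, and cCRE intervals of the five ENCODE types (half
#' overlapping TEs).
#'
#' @param config A [simulation_config()].
#' @param sequences Output of [simulate_te_sequences()].
#' @return A list: `tes` (annotation tibble with clades assigned), `taxa_map`,
#'   `gene_models`, `genes` (per-gene bookkeeping), `ccres`, `plant` (planted
#'   roles per TE), `catalog`.
#' @export
simulate_annotation <- function(config, sequences = simulate_te_sequences(config)) {
  catalog <- subfamily_catalog(config)
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  L <- config$chrom_length_bp
  te_region_end <- floor(0.60 * L)
  n_total <- nrow(catalog) * config$copies_per_subfamily
  per_chrom <- ceiling(n_total / config$n_chroms)
  slot_w <- floor(te_region_end / per_chrom)
  if (slot_w < config$consensus_length + 10) {
    abort("requested TE copies exceed genome capacity")
  }

  with_stream(config$seed, "annotation", {
    # --- base TE placement on a jittered grid ---
    copies <- sequences$copies |> select("subfamily", "copy_index")
    copies <- copies[sample.int(nrow(copies)), ]
    copies$chrom <- chroms[(seq_len(n_total) - 1) %% config$n_chroms + 1]
    copies <- copies |>
      group_by(.data$chrom) |>
      mutate(slot = row_number() - 1L) |>
      ungroup() |>
      mutate(
        start = .data$slot * slot_w +
          sample.int(slot_w - config$consensus_length, n(), replace = TRUE) - 1L,
        end = .data$start + config$consensus_length,
        strand = sample(c("+", "-"), n(), replace = TRUE)
      )

    # --- genes ---
    region_lo <- ceiling(0.62 * L)
    pitch <- floor((0.95 * L - 0.62 * L) / config$n_genes_per_chrom)
    if (pitch < GENE_SPAN + 2400) abort("gene pitch too small for gene span")
    genes <- purrr::map_dfr(seq_along(chroms), function(ci) {
      tibble(
        gene_index = seq_len(config$n_genes_per_chrom),
        chrom = chroms[ci],
        base = region_lo + (seq_len(config$n_genes_per_chrom) - 1L) * pitch
      )
    }) |>
      mutate(
        gene_id = sprintf("gene_%03d", row_number()),
        strand = ifelse(.data$gene_index %% 4 == 0, "-", "+"),
        category = rep_len(gene_category_cycle, n())
      )

    tx_types <- list(
      coding2 = c("protein_coding", "protein_coding"),
      coding_mix = c("protein_coding", "retained_intron"),
      coding_alt = c("retained_intron", "protein_coding"),
      linc = c("lincRNA", "lincRNA"),
      other = c("processed_transcript", "other")
    )
    exon_rows <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      types <- tx_types[[g$category]]
      base_pep <- random_peptide(150)
      alt_pep <- paste0(substr(base_pep, 1, 149), "W")  # one-residue change
      mk <- function(which_tx, exon_keys, type) {
        pep <- if (type != "protein_coding") {
          NA_character_
        } else if (which_tx == 1) {
          base_pep
        } else if (g$category == "coding2" && g$gene_index %% 2 == 1) {
          base_pep       # planted "same" protein product
        } else {
          alt_pep        # planted "different" protein product
        }
        purrr::map_dfr(exon_keys, function(k) {
          tibble(
            transcript_id = sprintf("%s_tx%d", g$gene_id, which_tx),
            gene_id = g$gene_id, chrom = g$chrom,
            start = g$base + GENE_EXONS[[k]][1],
            end = g$base + GENE_EXONS[[k]][2],
            strand = g$strand, transcript_type = type, peptide = pep
          )
        })
      }
      bind_rows(mk(1, c("e1", "e2", "e3"), types[1]),
                mk(2, c("e1b", "e2", "e3"), types[2]))
    })
    gene_models <- build_transcript_models(exon_rows)

    # --- planted relocations ---
    # pool of relocatable copies: non-motif SINE/LTR copies, taken from the
    # end of the shuffled placement so base coverage stays dense
    motif_sf <- catalog$subfamily[catalog$carries_motif]
    pool_rows <- which(copies$subfamily != motif_sf &
                         copies$subfamily %in%
                           catalog$subfamily[catalog$te_class %in% c("SINE", "LTR")])
    pool_rows <- rev(pool_rows)
    take <- local({
      k <- 0L
      function() {
        k <<- k + 1L
        if (k > length(pool_rows)) abort("relocation pool exhausted")
        pool_rows[k]
      }
    })
    plant <- list()
    relocate <- function(row, chrom, start, role, gene_id = NA_character_) {
      copies$chrom[row] <<- chrom
      copies$start[row] <<- as.integer(start)
      copies$end[row] <<- as.integer(start + config$consensus_length)
      plant[[length(plant) + 1]] <<- tibble(
        role = role, subfamily = copies$subfamily[row],
        copy_index = copies$copy_index[row], chrom = chrom,
        start = as.integer(start), gene_id = gene_id)
    }

    plus_genes <- genes |> filter(.data$strand == "+")
    # TSS-in-TE: TE over tx2's TSS (gene base + 600) of the first
    # n_te_tss_transcripts plus-strand genes
    tss_genes <- head(plus_genes, config$n_te_tss_transcripts)
    for (i in seq_len(nrow(tss_genes))) {
      g <- tss_genes[i, ]
      relocate(take(), g$chrom, g$base + 600 - 150, "tss", g$gene_id)
    }
    remaining <- plus_genes |> dplyr::slice(-seq_len(nrow(tss_genes)))
    # genomic-feature labels: exon, intron (x2, one doubles as the antisense
    # chimeric host), TTS — one gene each per chromosome
    for (ch in chroms) {
      gs <- remaining |> filter(.data$chrom == ch)
      if (nrow(gs) < 4) abort("not enough spare plus-strand genes")
      relocate(take(), ch, gs$base[1] + 1600, "exon", gs$gene_id[1])
      relocate(take(), ch, gs$base[2] + 2000, "intron", gs$gene_id[2])
      relocate(take(), ch, gs$base[3] + 2000, "intron_antisense", gs$gene_id[3])
      relocate(take(), ch, gs$base[4] + GENE_SPAN - 150, "tts", gs$gene_id[4])
      remaining <- remaining |> filter(!.data$gene_id %in% gs$gene_id[1:4])
    }
    # anchor TEs for chimeric transcripts: upstream of spare genes
    chim_coding <- remaining |>
      filter(.data$category %in% c("coding2", "coding_mix", "coding_alt")) |>
      head(5)  # 3 survivors + junction decoy + CPM decoy
    chim_nc <- remaining |> filter(.data$category == "linc") |> head(2)
    if (nrow(chim_coding) < 5 || nrow(chim_nc) < 2) {
      abort("not enough spare genes for chimeric planting")
    }
    for (i in seq_len(nrow(chim_coding))) {
      g <- chim_coding[i, ]
      relocate(take(), g$chrom, g$base - 2900, "chimeric_coding", g$gene_id)
    }
    for (i in seq_len(nrow(chim_nc))) {
      g <- chim_nc[i, ]
      relocate(take(), g$chrom, g$base - 2900, "chimeric_noncoding", g$gene_id)
    }

    copies <- copies |>
      arrange(.data$chrom, .data$start) |>
      mutate(uid = sprintf("te_%06d", row_number()))
    tes <- copies |>
      left_join(catalog, by = "subfamily") |>
      select("chrom", "start", "end", "strand", "subfamily", "family",
             "te_class", "uid", "copy_index")
    taxa_map <- catalog |> select("subfamily", "taxon")
    tes$clade <- "Other"
    tes <- assign_clades(tes, taxa_map)
    plant <- bind_rows(plant) |>
      left_join(select(tes, "subfamily", "copy_index", "uid"),
                by = c("subfamily", "copy_index"))

    # --- cCREs: half overlapping TEs, half in gene-region gaps ---
    te_overlap_rows <- which(!tes$uid %in% plant$uid)
    te_overlap_rows <- te_overlap_rows[round(seq(1, length(te_overlap_rows),
                                                 length.out = 30))]
    ccre_te <- tibble(
      chrom = tes$chrom[te_overlap_rows],
      start = tes$start[te_overlap_rows] + 100L,
      end = tes$start[te_overlap_rows] + 450L,
      ccre_type = rep_len(ccre_types, length(te_overlap_rows))
    )
    gap_genes <- genes[round(seq(1, nrow(genes), length.out = 30)), ]
    ccre_free <- tibble(
      chrom = gap_genes$chrom,
      start = gap_genes$base + GENE_SPAN + 500L,
      end = gap_genes$base + GENE_SPAN + 800L,
      ccre_type = rep_len(rev(ccre_types), nrow(gap_genes))
    )
    ccres <- bind_rows(ccre_te, ccre_free) |> arrange(.data$chrom, .data$start)

    list(tes = tes, taxa_map = taxa_map, gene_models = gene_models,
         genes = genes, ccres = ccres, plant = plant, catalog = catalog,
         chroms = chroms)
  })
}

# Random genome with every TE copy's sequence written at its interval.
assemble_genome <- function(config, tes, sequences) {
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  genome <- with_stream(config$seed, "misc", {
    Biostrings::DNAStringSet(
      setNames(vapply(chroms, function(ch) random_dna(config$chrom_length_bp),
                      character(1)), chroms))
  })
  seq_lut <- sequences$copies |>
    mutate(key = paste(.data$subfamily, .data$copy_index))
  lut <- setNames(seq_lut$sequence, seq_lut$key)
  for (ch in chroms) {
    sub <- tes |> filter(.data$chrom == ch)
    if (nrow(sub) == 0) next
    at <- IRanges::IRanges(sub$start + 1L, sub$end)
    vals <- unname(lut[paste(sub$subfamily, sub$copy_index)])
    genome[[ch]] <- Biostrings::replaceAt(genome[[ch]], at,
                                          Biostrings::DNAStringSet(vals))
  }
  genome
}

#' Simulate an ATAC-seq peak set with summits
#'
#' Each summit falls inside a TE with probability `te_summit_fraction`
#' (uniform over TE copies, then uniform within the copy) and otherwise at a
#' uniform non-TE position; the peak is a fixed window around the summit.
#'
#' @param config A [simulation_config()].
#' @param tes TE annotation tibble.
#' @return A list: `peaks` (tibble `peak_id`, `chrom`, `start`, `end`,
#'   `summit`) and `truth` (`peak_id`, `in_te`, `te_uid`).
#' @export
simulate_peaks <- function(config, tes) {
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  L <- config$chrom_length_bp
  te_gr <- as_granges0(tes)
  with_stream(config$seed, "peaks", {
    in_te <- runif(config$n_peaks) < config$te_summit_fraction
    summit <- integer(config$n_peaks)
    chrom <- character(config$n_peaks)
    te_uid <- rep(NA_character_, config$n_peaks)
    for (i in seq_len(config$n_peaks)) {
      if (in_te[i]) {
        row <- sample.int(nrow(tes), 1)
        chrom[i] <- tes$chrom[row]
        summit[i] <- tes$start[row] +
          sample.int(tes$end[row] - tes$start[row], 1) - 1L
        te_uid[i] <- tes$uid[row]
      } else {
        repeat {
          ch <- sample(chroms, 1)
          pos <- sample.int(L, 1) - 1L
          hit <- IRanges::overlapsAny(points_granges0(ch, pos), te_gr)
          if (!hit) break
        }
        chrom[i] <- ch
        summit[i] <- pos
      }
    }
    peaks <- tibble(
      peak_id = sprintf("peak_%06d", seq_len(config$n_peaks)),
      chrom = chrom,
      start = pmax(summit - config$peak_halfwidth, 0L),
      end = pmin(summit + config$peak_halfwidth + 1L, L),
      summit = summit
    )
    list(peaks = peaks,
         truth = tibble(peak_id = peaks$peak_id, in_te = in_te,
                        te_uid = te_uid))
  })
}
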