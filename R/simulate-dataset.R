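#' Simulate the complete synthetic multi-omics dataset
#'
#' Runs every sub-generator under independent RNG streams derived from the
#' master seed and returns a fully self-consistent dataset with planted
#' ground truth: genome, TE annotation with taxa map, gene models, consensus
#' and copy sequences, peaks, five tiers of count matrices, assembled
#' chimeric transcripts with junction support, CpG methylation, and a truth
#' list covering every planted feature.
#'
#' @param config A [simulation_config()].
#' @return An object of class `te_sim`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  sequences <- simulate_te_sequences(config)
  ann <- simulate_annotation(config, sequences)
  genome <- assemble_genome(config, ann$tes, sequences)
  design <- design_sheet(config)
  chim <- simulate_chimeric_transcripts(config, ann, genome, design)
  genome <- chim$genome
  pk <- simulate_peaks(config, ann$tes)
  meth <- simulate_methylation(config, ann$tes, design)

  subfams <- ann$catalog$subfamily
  low_subfams <- tail(subfams[ann$catalog$te_class == "DNA"], 2)
  eligible_subfams <- setdiff(subfams, low_subfams)
  n_sf <- max(1, round(config$frac_differential * length(eligible_subfams)))

  tx_ids <- ann$gene_models$transcript_id
  tss_gene_ids <- unique(ann$plant$gene_id[ann$plant$role == "tss"])
  te_tss_tx <- paste0(tss_gene_ids, "_tx2")
  unexpressed_tx <- head(te_tss_tx, 4)
  eligible_tx <- setdiff(tx_ids, unexpressed_tx)
  must_tx <- head(setdiff(te_tss_tx, unexpressed_tx), 6)

  chim_ids <- chim$assembled$transcript_id
  survivors <- chim$truth$transcript_id[chim$truth$passes_filters]

  planted <- list(
    subfamily_expression = with_stream(config$seed, "counts", salt = 11L,
      plant_effects(config, eligible_subfams, n_sf, paired_sexes = TRUE)),
    subfamily_accessibility = with_stream(config$seed, "counts", salt = 12L,
      plant_effects(config, eligible_subfams, n_sf, paired_sexes = TRUE)),
    locus_accessibility = with_stream(config$seed, "counts", salt = 13L,
      plant_effects(config, pk$peaks$peak_id,
                    max(1, round(config$frac_differential * config$n_peaks)))),
    transcript_expression = with_stream(config$seed, "counts", salt = 14L,
      plant_effects(config, eligible_tx,
                    max(1, round(config$frac_differential * length(tx_ids))),
                    must_include = must_tx)),
    chimeric_expression = with_stream(config$seed, "counts", salt = 15L,
      plant_effects(config, survivors, 3))
  )

  tiers <- list(
    subfamily_expression = simulate_counts(
      config, subfams, design, planted$subfamily_expression,
      base_meanlog = log(800), base_sdlog = 0.7,
      low_features = low_subfams, salt = 1L),
    subfamily_accessibility = simulate_counts(
      config, subfams, design, planted$subfamily_accessibility,
      base_meanlog = log(800), base_sdlog = 0.7,
      low_features = low_subfams, salt = 2L),
    locus_accessibility = simulate_counts(
      config, pk$peaks$peak_id, design, planted$locus_accessibility,
      base_meanlog = log(150), base_sdlog = 0.6, salt = 3L),
    transcript_expression = simulate_counts(
      config, tx_ids, design, planted$transcript_expression,
      base_meanlog = log(300), base_sdlog = 0.8,
      low_features = unexpressed_tx, salt = 4L),
    chimeric_expression = simulate_counts(
      config, chim_ids, design, planted$chimeric_expression,
      base_meanlog = log(300), base_sdlog = 0.5,
      low_features = chim$cpm_decoy_id, salt = 5L)
  )
  counts <- purrr::map(tiers, "counts")
  counts_truth <- purrr::imap_dfr(tiers, function(t, nm) {
    mutate(t$truth, tier = nm)
  })

  structure(list(
    config = config,
    catalog = ann$catalog,
    tes = ann$tes,
    taxa_map = ann$taxa_map,
    gene_models = ann$gene_models,
    genes = ann$genes,
    ccres = ann$ccres,
    plant = ann$plant,
    genome = genome,
    consensus = sequences$consensus,
    te_sequences = sequences$copies,
    motif_subfamily = sequences$motif_subfamily,
    peaks = pk$peaks,
    design = design,
    counts = counts,
    assembled = chim$assembled,
    junctions = chim$junctions,
    methylation = meth$cpgs,
    methylation_design = meth$design,
    truth = list(
      counts = counts_truth,
      peaks = pk$truth,
      te_tss_transcripts = tibble(
        transcript_id = te_tss_tx,
        gene_id = tss_gene_ids,
        planted_unexpressed = te_tss_tx %in% unexpressed_tx),
      chimeric = chim$truth,
      orf = chim$orf_truth,
      motif = sequences$motif_truth,
      methylation = meth$truth
    )
  ), class = "te_sim")
}

#' @export
print.te_sim <- function(x, ...) {
  cat("<te_sim> synthetic TE multi-omics dataset\n")
  cat("  seed:", x$config$seed, "\n")
  cat("  TEs:", nrow(x$tes), "copies,", nrow(x$catalog), "subfamilies\n")
  cat("  genes:", nrow(x$genes), " transcripts:", nrow(x$gene_models), "\n")
  cat("  peaks:", nrow(x$peaks), " samples:", nrow(x$design), "\n")
  cat("  count tiers:", paste(names(x$counts), collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits every file the analysis functions read — genome FASTA, TE BED and
#' taxa map, gene and assembled-transcript GTFs, consensus FASTA, peak file
#' (summit dialect), count TSVs, sample sheet, junction TSV, methylation TSV,
#' cCRE BED, truth tables — plus a `manifest.json` recording the seed, the
#' scalar configuration, and an md5 checksum per file.
#'
#' @param sim A `te_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)

  Biostrings::writeXStringSet(sim$genome, p("genome.fa"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$consensus), p("consensus.fa"))
  write_te_bed(sim$tes, p("tes.bed"))
  readr::write_tsv(sim$taxa_map, p("taxa_map.tsv"), progress = FALSE)
  write_gtf(sim$gene_models, p("genes.gtf"))
  write_gtf(sim$assembled, p("assembled.gtf"))
  readr::write_tsv(
    tibble(chrom = sim$peaks$chrom, start = sim$peaks$start,
           end = sim$peaks$end,
           summit_offset = sim$peaks$summit - sim$peaks$start,
           peak_id = sim$peaks$peak_id),
    p("peaks.tsv"), col_names = FALSE, progress = FALSE)
  for (nm in names(sim$counts)) {
    readr::write_tsv(sim$counts[[nm]], p(paste0("counts_", nm, ".tsv")),
                     progress = FALSE)
  }
  readr::write_tsv(sim$design, p("sample_sheet.tsv"), progress = FALSE)
  readr::write_tsv(sim$junctions, p("junctions.tsv"), progress = FALSE)
  readr::write_tsv(sim$methylation, p("methylation.tsv"), progress = FALSE)
  readr::write_tsv(sim$ccres, p("ccre.bed"), col_names = FALSE,
                   progress = FALSE)
  for (nm in names(sim$truth)) {
    readr::write_tsv(sim$truth[[nm]], p(paste0("truth_", nm, ".tsv")),
                     progress = FALSE)
  }

  files <- sort(setdiff(list.files(dir), "manifest.json"))
  manifest <- list(
    seed = sim$config$seed,
    config = purrr::keep(unclass(sim$config), function(v) {
      is.atomic(v) && length(v) <= 10
    }),
    checksums = as.list(tools::md5sum(file.path(dir, files)))
  )
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(dir)
}

# Write transcript models as a GENCODE-dialect GTF (transcript + exon rows,
# 1-based inclusive).
write_gtf <- function(transcripts, path) {
  ex <- exon_table(transcripts)
  attr_of <- function(tid, gid, ttype) {
    sprintf('gene_id "%s"; transcript_id "%s"; transcript_type "%s";',
            gid, tid, ttype)
  }
  tx_lines <- transcripts |>
    mutate(lo = purrr::map_int(.data$exons, ~ min(.x$start)) + 1L,
           hi = purrr::map_int(.data$exons, ~ max(.x$end))) |>
    mutate(line = sprintf("%s\tteomics\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                          .data$chrom, .data$lo, .data$hi, .data$strand,
                          attr_of(.data$transcript_id, .data$gene_id,
                                  .data$transcript_type)))
  ex_lines <- ex |>
    mutate(line = sprintf("%s\tteomics\texon\t%d\t%d\t.\t%s\t.\t%s",
                          .data$chrom, .data$start + 1L, .data$end,
                          .data$strand,
                          attr_of(.data$transcript_id, .data$gene_id,
                                  .data$transcript_type)))
  writeLines(c(tx_lines$line, ex_lines$line), path)
  invisible(path)
}
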