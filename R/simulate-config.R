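#' Configuration for the synthetic multi-omics dataset
#'
#' Defines every knob of the generator. The defaults describe the study
#' conditions the package is validated under: a sex-by-exposure liver design
#' with 6 samples per group, negative-binomial counts with dispersion 0.1 and
#' planted two-fold-per-unit-log2 effects on 10% of features, ~20% of peak
#' summits inside TEs, TE copies diverged 5% from a consensus carrying an
#' Ikzf3-Elf3-Elf3 motif run (AGGAAG / CTTCCT) in its core, 28 LINE
#' subfamilies with a planted -0.2 methylation shift, and chimeric decoys
#' violating each of the three transcript filters.
#'
#' @param seed Master seed; each sub-generator derives its own RNG stream.
#' @param n_chroms,chrom_length_bp Genome shape.
#' @param n_subfamilies Named integer vector of subfamilies per TE class.
#' @param copies_per_subfamily Copies of each subfamily placed in the genome.
#' @param consensus_length Consensus (and copy) length in bp.
#' @param copy_divergence Per-base substitution probability from consensus.
#' @param motif_strings Named motif instances embedded in the motif-bearing
#'   subfamily's consensus.
#' @param motif_offsets 0-based consensus offsets of the embedded motifs.
#' @param core_region 0-based half-open consensus interval holding the motifs.
#' @param frac_motif_ablated Fraction of the motif subfamily's copies with
#'   all motif instances ablated by targeted substitution.
#' @param ablated_core_extra_divergence Extra substitution rate applied to
#'   the core region of ablated copies (plants the conservation contrast).
#' @param sexes,exposures,n_control,n_exposed Study design: per sex,
#'   `n_control` control samples plus `n_exposed` samples per exposure.
#' @param nb_dispersion NB dispersion of simulated counts.
#' @param effect_log2fc Magnitude of planted differential effects.
#' @param frac_differential Fraction of count features with planted effects.
#' @param library_sdlog SD of log-normal library-size factors (meanlog 0).
#' @param n_peaks,peak_halfwidth,te_summit_fraction Peak set shape and the
#'   target fraction of summits falling inside TEs.
#' @param n_genes_per_chrom,n_te_tss_transcripts Gene count and the number of
#'   genes whose alternative isoform gets a TE planted over its TSS.
#' @param n_planted_hypo_subfams LINE subfamilies with a planted methylation
#'   shift in exposed samples.
#' @param meth_shift Planted methylation shift (exposed minus control).
#' @param meth_concentration Beta concentration of per-sample methylation
#'   around the site mean.
#' @param coverage_mean,coverage_dispersion NB coverage model for CpGs.
#' @param n_cpgs_outside CpG sites placed outside any TE.
#' @return A `te_sim_config` list.
#' @export
simulation_config <- function(
    seed = 1,
    n_chroms = 2,
    chrom_length_bp = 1000000,
    n_subfamilies = c(DNA = 5, LINE = 28, SINE = 5, LTR = 5),
    copies_per_subfamily = 50,
    consensus_length = 300,
    copy_divergence = 0.05,
    motif_strings = c(Ikzf3 = "AGGAAG", Elf3 = "CTTCCT"),
    motif_offsets = c(105, 120, 135),
    core_region = c(100, 160),
    frac_motif_ablated = 0.3,
    ablated_core_extra_divergence = 0.15,
    sexes = c("F", "M"),
    exposures = c("expoA", "expoB"),
    n_control = 6,
    n_exposed = 6,
    nb_dispersion = 0.1,
    effect_log2fc = 2,
    frac_differential = 0.1,
    library_sdlog = 0.2,
    n_peaks = 500,
    peak_halfwidth = 200,
    te_summit_fraction = 0.2,
    n_genes_per_chrom = 40,
    n_te_tss_transcripts = 16,
    n_planted_hypo_subfams = 28,
    meth_shift = -0.2,
    meth_concentration = 50,
    coverage_mean = 35,
    coverage_dispersion = 0.1,
    n_cpgs_outside = 400) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_chroms >= 1, cfg$chrom_length_bp > 0,
    all(cfg$n_subfamilies >= 1), cfg$copies_per_subfamily >= 1,
    cfg$consensus_length > 0,
    cfg$copy_divergence >= 0, cfg$copy_divergence <= 1,
    cfg$te_summit_fraction >= 0, cfg$te_summit_fraction <= 1,
    cfg$frac_differential >= 0, cfg$frac_differential <= 1,
    cfg$frac_motif_ablated >= 0, cfg$frac_motif_ablated <= 1,
    cfg$n_control >= 2, cfg$n_exposed >= 2,
    cfg$core_region[1] >= 0, cfg$core_region[2] <= cfg$consensus_length
  )
  motif_len <- nchar(cfg$motif_strings)
  if (any(cfg$motif_offsets + rep_len(motif_len, length(cfg$motif_offsets)) >
          cfg$consensus_length)) {
    abort("motif longer than consensus at the configured offset")
  }
  if (cfg$n_planted_hypo_subfams > cfg$n_subfamilies[["LINE"]]) {
    abort("n_planted_hypo_subfams exceeds the number of LINE subfamilies")
  }
  structure(cfg, class = "te_sim_config")
}

#' Sample sheet implied by a simulation design
#'
#' Per sex: `n_control` control samples (exposure `"none"`) plus `n_exposed`
#' samples per exposure.
#'
#' @param config A [simulation_config()].
#' @return A tibble with `sample_id`, `sex`, `exposure`, `condition`.
#' @export
design_sheet <- function(config) {
  rows <- list()
  for (sx in config$sexes) {
    rows[[length(rows) + 1]] <- tibble(
      sample_id = sprintf("%s_control_%02d", sx, seq_len(config$n_control)),
      sex = sx, exposure = "none", condition = "control")
    for (ex in config$exposures) {
      rows[[length(rows) + 1]] <- tibble(
        sample_id = sprintf("%s_%s_%02d", sx, ex, seq_len(config$n_exposed)),
        sex = sx, exposure = ex, condition = "exposed")
    }
  }
  bind_rows(rows)
}

#' Samples entering one sex-by-exposure contrast
#'
#' Selects the exposed samples of one (sex, exposure) cell together with the
#' matched same-sex controls; cross-sex samples are never pooled.
#'
#' @param design Sample sheet from [design_sheet()].
#' @param sex,exposure The contrast cell.
#' @return The design subset.
#' @export
contrast_samples <- function(design, sex, exposure) {
  dplyr::filter(design, .data$sex == !!sex,
                .data$exposure %in% c("none", !!exposure))
}

subfamily_catalog <- function(config) {
  taxa_cycle <- c("Mus_musculus", "Mus_genus", "Murinae", "Muridae",
                  "Rodentia", "Glires", "Theria")
  cat <- purrr::map_dfr(names(config$n_subfamilies), function(cl) {
    tibble(
      subfamily = sprintf("%s_sf%02d", cl, seq_len(config$n_subfamilies[[cl]])),
      te_class = cl,
      family = paste0(cl, "_family")
    )
  })
  cat$taxon <- rep_len(taxa_cycle, nrow(cat))
  # the motif-bearing subfamily: first LTR subfamily (ORR1E analog)
  cat$carries_motif <- cat$subfamily == cat$subfamily[cat$te_class == "LTR"][1]
  cat
}
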