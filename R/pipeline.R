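#' Run the full TE multi-omics analysis on a synthetic dataset
#'
#' Generates (or accepts) a synthetic dataset and runs the three analysis
#' arms over every sex-by-exposure contrast against matched same-sex
#' controls: (1) subfamily expression/accessibility differential calls with
#' the tiered thresholds, sex-concordance correlations and class enrichment
#' of sex-shared DA-subfamilies; (2) OCR/DAR summit-to-TE assignment, DA-TE
#' calls with genomic-feature and cCRE annotation, subfamily enrichment and
#' exposure specificity; (3) known TE-derived transcripts (expression
#' filter, type composition, protein comparison), chimeric-transcript
#' filtering/classification with ORF extraction, and per-TE methylation with
#' the paired Wilcoxon contrast. Optionally writes every result table plus a
#' reproducibility manifest.
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory; NULL skips writing.
#' @param sim A pre-built `te_sim` (defaults to `simulate_dataset(config)`).
#' @param scan_p_threshold Motif-scan p-value cutoff used for the synthetic
#'   6-bp motif cores (default 1e-3; an exact 6-mer match cannot attain the
#'   1e-4 scanning default).
#' @return A `te_pipeline` list of result tables.
#' @export
run_pipeline <- function(config = simulation_config(), outdir = NULL,
                         sim = NULL, scan_p_threshold = 1e-3) {
  log <- list()
  note <- function(stage, n) {
    log[[length(log) + 1]] <<- tibble(stage = stage, records = n)
    inform(paste0("[", stage, "] ", n, " records"))
  }

  if (is.null(sim)) sim <- simulate_dataset(config)
  config <- sim$config
  design <- sim$design
  background <- subfamily_summaries(sim$tes)
  note("annotation", nrow(sim$tes))

  contrasts <- tidyr::crossing(sex = config$sexes,
                               exposure = config$exposures)
  tier_of <- c(subfamily_expression = "subfamily_expression",
               subfamily_accessibility = "subfamily_accessibility",
               locus_accessibility = "dar",
               transcript_expression = "transcript",
               chimeric_expression = "chimeric")

  # --- differential testing, all tiers x contrasts ---
  diff_results <- list()
  for (nm in names(sim$counts)) {
    for (k in seq_len(nrow(contrasts))) {
      sx <- contrasts$sex[k]; ex <- contrasts$exposure[k]
      samp <- contrast_samples(design, sx, ex)
      sub_counts <- sim$counts[[nm]][, c("feature_id", samp$sample_id)]
      fit <- nb_differential(sub_counts, samp)
      fit <- classify_differential(fit, tier_of[[nm]])
      diff_results[[paste(nm, sx, ex, sep = ".")]] <-
        mutate(tidy(fit), tier = nm, sex = sx, exposure = ex)
    }
  }
  differential <- bind_rows(diff_results)
  note("differential", nrow(differential))

  # --- subfamily arm: concordance and shared-class enrichment ---
  concordance <- purrr::map_dfr(
    c("subfamily_expression", "subfamily_accessibility"), function(nm) {
      purrr::map_dfr(config$exposures, function(ex) {
        f <- diff_results[[paste(nm, config$sexes[1], ex, sep = ".")]]
        m <- diff_results[[paste(nm, config$sexes[2], ex, sep = ".")]]
        shared <- intersect(f$feature_id[f$status != "ns"],
                            m$feature_id[m$status != "ns"])
        out <- if (length(shared) >= 3) {
          sex_concordance(f, m, shared)
        } else {
          tibble(r = NA_real_, n_shared = length(shared))
        }
        mutate(out, tier = nm, exposure = ex)
      })
    })
  shared_first <- {
    ex1 <- config$exposures[1]
    f <- diff_results[[paste("subfamily_accessibility", config$sexes[1],
                             ex1, sep = ".")]]
    m <- diff_results[[paste("subfamily_accessibility", config$sexes[2],
                             ex1, sep = ".")]]
    intersect(f$feature_id[f$status != "ns"], m$feature_id[m$status != "ns"])
  }
  shared_class_enrichment <- if (length(shared_first) > 0) {
    class_enrichment_shared(shared_first, background)
  } else {
    NULL
  }

  # --- chromatin arm ---
  ocr_assign <- assign_summits_to_tes(sim$peaks, sim$tes)
  ocr_te_fraction <- mean(ocr_assign$is_te_derived)
  note("ocr_te", sum(ocr_assign$is_te_derived))

  da_te_tabs <- list()
  for (k in seq_len(nrow(contrasts))) {
    sx <- contrasts$sex[k]; ex <- contrasts$exposure[k]
    res <- diff_results[[paste("locus_accessibility", sx, ex, sep = ".")]]
    dars <- sim$peaks |>
      inner_join(filter(res, .data$status != "ns"),
                 by = c(peak_id = "feature_id")) |>
      mutate(contrast = paste(sx, ex, sep = "."))
    da_te_tabs[[k]] <- call_da_tes(dars, sim$tes)
  }
  da_tes <- bind_rows(da_te_tabs)
  note("da_te", nrow(da_tes))

  da_annot <- if (nrow(da_tes) > 0) {
    uids <- unique(da_tes$uid)
    sub_tes <- sim$tes[match(uids, sim$tes$uid), ]
    feats <- genomic_feature_assignment(sub_tes, sim$gene_models)
    ccre <- annotate_ccre(sub_tes, sim$ccres)
    left_join(feats, ccre, by = "te_uid")
  } else NULL
  da_enrichment <- if (nrow(da_tes) > 0) {
    subfamily_enrichment(distinct(da_tes, .data$uid, .keep_all = TRUE),
                         background)
  } else NULL
  specificity <- purrr::map(setNames(config$sexes, config$sexes),
    function(sx) {
      sets <- purrr::map(setNames(config$exposures, config$exposures),
        function(ex) {
          da_tes$uid[da_tes$contrast == paste(sx, ex, sep = ".")]
        })
      sets <- purrr::keep(sets, ~ length(.x) > 0)
      if (length(sets) >= 2) exposure_specificity(sets) else NULL
    })

  # --- known TE-derived transcripts ---
  tx_cpm <- cpm(sim$counts$transcript_expression)
  te_tx <- find_te_derived_transcripts(sim$gene_models, sim$tes) |>
    expressed_filter(tx_cpm, design)
  expressed_calls <- filter(te_tx, .data$expressed)
  note("te_transcripts", nrow(expressed_calls))
  composition <- transcript_type_composition(expressed_calls, sim$gene_models)
  type_enrichment <- subfamily_enrichment_by_type(expressed_calls, background)
  protein_cmp <- compare_protein_products(expressed_calls, sim$gene_models)

  # --- chimeric transcripts ---
  chim_lib <- colSums(counts_to_matrix(sim$counts$transcript_expression)) +
    colSums(counts_to_matrix(sim$counts$chimeric_expression))
  chim_cpm <- cpm(sim$counts$chimeric_expression, library_sizes = chim_lib)
  candidates <- detect_te_first_exon(sim$assembled, sim$tes) |>
    filter_novel_first_exon(sim$gene_models) |>
    filter_junction_support(sim$junctions) |>
    filter_expression(chim_cpm, design) |>
    classify_chimeric(sim$gene_models, sim$tes)
  survivors <- filter(candidates, .data$passes_filters)
  note("chimeric_survivors", nrow(survivors))
  orfs <- if (nrow(survivors) > 0) {
    spliced <- extract_spliced_sequence(survivors, sim$genome)
    purrr::map_dfr(names(spliced), function(id) {
      o <- find_orf(spliced[[id]])
      if (is.null(o)) {
        tibble(transcript_id = id, start = NA_integer_,
               length_nt = NA_integer_, peptide = NA_character_)
      } else {
        mutate(o, transcript_id = id)[, c("transcript_id", "start",
                                          "length_nt", "peptide")]
      }
    })
  } else NULL

  # --- motif conservation (ORR1E-analog subfamily) ---
  motif_copies <- sim$te_sequences |>
    filter(.data$subfamily == sim$motif_subfamily)
  copy_seqs <- setNames(motif_copies$sequence,
                        paste0(motif_copies$subfamily, "_",
                               motif_copies$copy_index))
  pwms <- purrr::imap(as.list(config$motif_strings),
                      function(m, nm) pwm_from_string(m, motif_id = nm))
  motif_groups <- motif_presence_groups(
    copy_seqs, pwms, sim$consensus[[sim$motif_subfamily]],
    config$core_region, p_threshold = scan_p_threshold)
  note("motif_with", sum(motif_groups$presence$with_motif))

  # --- methylation ---
  cpgs <- filter_cpgs(sim$methylation)
  line_subfams <- sim$catalog$subfamily[sim$catalog$te_class == "LINE"]
  meth <- methylation_contrast(cpgs, sim$tes, sim$methylation_design,
                               subfamilies = line_subfams)
  note("methylation_pairs", meth$test$n_pairs)

  result <- structure(list(
    config = config, sim = sim, background = background,
    differential = differential, concordance = concordance,
    shared_class_enrichment = shared_class_enrichment,
    ocr_assignments = ocr_assign, ocr_te_fraction = ocr_te_fraction,
    da_tes = da_tes, da_annotation = da_annot,
    da_enrichment = da_enrichment, specificity = specificity,
    te_transcripts = te_tx, composition = composition,
    type_enrichment = type_enrichment, protein_comparison = protein_cmp,
    chimeric = candidates, orfs = orfs,
    motif_groups = motif_groups, methylation = meth,
    log = bind_rows(log)
  ), class = "te_pipeline")

  if (!is.null(outdir)) write_pipeline(result, outdir)
  result
}

write_pipeline <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  wt <- function(x, name) {
    if (!is.null(x) && is.data.frame(x)) {
      readr::write_tsv(x, p(paste0(name, ".tsv")), progress = FALSE)
    }
  }
  wt(result$differential, "differential")
  wt(result$concordance, "concordance")
  wt(result$shared_class_enrichment, "shared_class_enrichment")
  wt(result$ocr_assignments, "ocr_te_assignments")
  wt(result$da_tes, "da_tes")
  wt(result$da_annotation, "da_te_annotation")
  wt(result$da_enrichment, "da_te_enrichment")
  wt(result$te_transcripts, "te_transcripts")
  wt(result$composition, "transcript_type_composition")
  wt(result$type_enrichment, "subfamily_enrichment_by_type")
  wt(result$protein_comparison, "protein_comparison")
  wt(select(result$chimeric, -"exons"), "chimeric_candidates")
  wt(result$orfs, "chimeric_orfs")
  wt(result$motif_groups$presence, "motif_presence")
  wt(result$motif_groups$profiles, "conservation_profiles")
  wt(result$methylation$per_subfamily, "methylation_per_subfamily")
  wt(result$methylation$test, "methylation_test")
  wt(result$log, "stage_log")
  summary <- list(
    seed = result$config$seed,
    ocr_te_fraction = result$ocr_te_fraction,
    n_da_tes = nrow(result$da_tes),
    core_identity_difference = result$motif_groups$core_identity_difference,
    methylation_p = result$methylation$test$pvalue
  )
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(seed = result$config$seed,
                   checksums = as.list(tools::md5sum(file.path(outdir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.te_pipeline <- function(x, ...) {
  cat("<te_pipeline> synthetic TE multi-omics analysis\n")
  print(x$log, n = Inf)
  invisible(x)
}
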