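#' Read a peak file with summits
#'
#' Two dialects are supported: `"summit_bed"` — BED-like TSV whose 4th column
#' is the summit offset relative to the peak start (optional 5th/6th columns
#' are peak name and strand); `"narrowPeak"` — the ENCODE 10-column layout
#' with the summit offset in column 10 and the peak name in column 4.
#'
#' @param path Path to the peak file.
#' @param dialect `"summit_bed"` or `"narrowPeak"`.
#' @return A tibble with `peak_id`, `chrom`, `start`, `end`, `summit`
#'   (absolute 0-based base).
#' @export
read_peaks <- function(path, dialect = c("summit_bed", "narrowPeak")) {
  dialect <- match.arg(dialect)
  raw <- readr::read_tsv(path, col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0) {
    return(tibble(peak_id = character(), chrom = character(),
                  start = integer(), end = integer(), summit = integer()))
  }
  if (dialect == "summit_bed") {
    if (ncol(raw) < 4) abort("summit_bed dialect needs >= 4 columns")
    peaks <- tibble(
      peak_id = if (ncol(raw) >= 5) raw[[5]] else sprintf("peak_%06d", seq_len(nrow(raw))),
      chrom = raw[[1]],
      start = parse_coord(raw[[2]], path, FALSE),
      end = parse_coord(raw[[3]], path, FALSE),
      summit = NA_integer_
    )
    peaks$summit <- peaks$start + parse_coord(raw[[4]], path, FALSE)
  } else {
    if (ncol(raw) < 10) abort("narrowPeak dialect needs 10 columns")
    peaks <- tibble(
      peak_id = raw[[4]],
      chrom = raw[[1]],
      start = parse_coord(raw[[2]], path, FALSE),
      end = parse_coord(raw[[3]], path, FALSE),
      summit = NA_integer_
    )
    peaks$summit <- peaks$start + parse_coord(raw[[10]], path, FALSE)
  }
  validate_peaks(peaks)
}

validate_peaks <- function(peaks) {
  check_intervals(peaks, "peak")
  bad <- peaks$summit < peaks$start | peaks$summit >= peaks$end
  if (any(bad)) {
    abort(paste0("summit outside its peak interval for: ",
                 paste(head(peaks$peak_id[bad], 5), collapse = ", ")))
  }
  peaks
}

# Assign single-base positions to TE copies. Returns one row per input point:
# uid of the containing TE or NA. Nested/overlapping TEs are resolved to the
# shortest element, then leftmost start, then lexicographic subfamily.
assign_points_to_tes <- function(chrom, pos, tes) {
  n <- length(pos)
  if (n == 0 || nrow(tes) == 0) return(rep(NA_character_, n))
  hits <- GenomicRanges::findOverlaps(points_granges0(chrom, pos),
                                      as_granges0(tes))
  if (length(hits) == 0) return(rep(NA_character_, n))
  h <- tibble(
    point = S4Vectors::queryHits(hits),
    te_row = S4Vectors::subjectHits(hits)
  ) |>
    mutate(
      width = tes$end[.data$te_row] - tes$start[.data$te_row],
      start = tes$start[.data$te_row],
      subfamily = tes$subfamily[.data$te_row]
    ) |>
    arrange(.data$point, .data$width, .data$start, .data$subfamily) |>
    group_by(.data$point) |>
    slice(1) |>
    ungroup()
  out <- rep(NA_character_, n)
  out[h$point] <- tes$uid[h$te_row]
  out
}

#' Assign peak summits to TE copies
#'
#' A peak is TE-derived iff its single-base summit lies within a TE interval
#' (half-open containment). When a summit falls in nested or overlapping TEs
#' the shortest element wins (the innermost, typically youngest insertion),
#' with ties broken by leftmost start then lexicographic subfamily.
#'
#' @param peaks Tibble with `peak_id`, `chrom`, `start`, `end`, `summit`.
#' @param tes TE annotation tibble.
#' @return A tibble with `peak_id`, `te_uid` (NA when not in a TE),
#'   `is_te_derived`.
#' @export
assign_summits_to_tes <- function(peaks, tes) {
  validate_peaks(peaks)
  uid <- assign_points_to_tes(peaks$chrom, peaks$summit, tes)
  tibble(peak_id = peaks$peak_id, te_uid = uid, is_te_derived = !is.na(uid))
}

#' Call differentially accessible TEs from DARs
#'
#' A TE is differentially accessible (DA-TE) iff the summit of a
#' differentially accessible region (DAR) lies within it. The DA-TE inherits
#' the DAR's direction; when several DARs of one contrast hit the same TE,
#' the record of the DAR with the smallest FDR is kept.
#'
#' @param dars Peak tibble restricted to DARs, additionally carrying `status`
#'   (`up`/`down`), `fdr`, `log2fc`, and optionally a `contrast` column.
#' @param tes TE annotation tibble.
#' @return A tibble with one row per (TE, contrast): annotation columns plus
#'   `peak_id`, `status`, `fdr`, `log2fc`.
#' @export
call_da_tes <- function(dars, tes) {
  dars <- dplyr::filter(dars, .data$status %in% c("up", "down"))
  if (!"contrast" %in% names(dars)) dars$contrast <- "contrast_1"
  if (nrow(dars) == 0) {
    return(bind_cols(empty_te_annotation(),
                     tibble(contrast = character(), peak_id = character(),
                            status = character(), fdr = double(),
                            log2fc = double()))[0, ])
  }
  validate_peaks(dars)
  asg <- assign_summits_to_tes(dars, tes)
  dars$te_uid <- asg$te_uid
  dars |>
    filter(!is.na(.data$te_uid)) |>
    arrange(.data$fdr) |>
    group_by(.data$te_uid, .data$contrast) |>
    slice(1) |>
    ungroup() |>
    select("te_uid", "contrast", "peak_id", "status", "fdr", "log2fc") |>
    inner_join(tes, by = c(te_uid = "uid")) |>
    rename(uid = "te_uid") |>
    select("chrom", "start", "end", "strand", "subfamily", "family",
           "te_class", "clade", "uid", "contrast", "peak_id", "status",
           "fdr", "log2fc")
}

#' Label TEs by the genomic feature they overlap
#'
#' Each TE receives exactly one label with precedence TSS > TTS > exon >
#' intron > intergenic: the highest-precedence feature any of its bases
#' overlaps. TSS/TTS regions are symmetric windows around the transcript's
#' start/termination base (default +/- 1 kb); introns are transcript spans
#' minus exons.
#'
#' @param tes TE annotation tibble.
#' @param gene_models Transcript model tibble from [read_gene_models()].
#' @param tss_window,tts_window Half-widths in bp of the TSS/TTS windows.
#' @return A tibble with `te_uid`, `genomic_feature`.
#' @export
genomic_feature_assignment <- function(tes, gene_models,
                                       tss_window = 1000, tts_window = 1000) {
  stopifnot(tss_window >= 0, tts_window >= 0)
  te_gr <- as_granges0(tes)
  win <- function(pos, w) {
    GenomicRanges::GRanges(gene_models$chrom,
      IRanges::IRanges(pmax(pos - w, 0) + 1L, pos + w + 1L))
  }
  overlaps_any <- function(gr) {
    IRanges::overlapsAny(te_gr, gr, ignore.strand = TRUE)
  }
  in_tss <- overlaps_any(win(gene_models$tss, tss_window))
  in_tts <- overlaps_any(win(gene_models$tts, tts_window))
  ex <- exon_table(gene_models)
  in_exon <- overlaps_any(as_granges0(ex))
  spans <- gene_models |>
    mutate(start = purrr::map_int(.data$exons, ~ min(.x$start)),
           end = purrr::map_int(.data$exons, ~ max(.x$end)))
  in_span <- overlaps_any(as_granges0(spans))
  tibble(
    te_uid = tes$uid,
    genomic_feature = dplyr::case_when(
      in_tss ~ "TSS",
      in_tts ~ "TTS",
      in_exon ~ "exon",
      in_span ~ "intron",
      TRUE ~ "intergenic"
    )
  )
}

ccre_types <- c("PLS", "pELS", "dELS", "DNase-H3K4me3", "CTCF-only")

#' Annotate TEs with ENCODE cCRE types
#'
#' A TE overlapping at least one candidate cis-regulatory element receives
#' the label of the cCRE with the largest overlap (ties resolved PLS > pELS >
#' dELS > DNase-H3K4me3 > CTCF-only); TEs overlapping none are labelled
#' `None`.
#'
#' @param tes TE annotation tibble.
#' @param ccres Tibble with `chrom`, `start`, `end`, `ccre_type` (one of the
#'   five ENCODE types).
#' @return A tibble with `te_uid`, `ccre`.
#' @export
annotate_ccre <- function(tes, ccres) {
  bad <- setdiff(unique(ccres$ccre_type), ccre_types)
  if (length(bad) > 0) {
    abort(paste0("unknown cCRE type(s): ", paste(bad, collapse = ", ")))
  }
  out <- tibble(te_uid = tes$uid, ccre = "None")
  if (nrow(ccres) == 0 || nrow(tes) == 0) return(out)
  hits <- GenomicRanges::findOverlaps(as_granges0(tes), as_granges0(ccres))
  if (length(hits) == 0) return(out)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- pmin(tes$end[q], ccres$end[s]) - pmax(tes$start[q], ccres$start[s])
  best <- tibble(te_row = q,
                 ccre = ccres$ccre_type[s],
                 overlap = ov,
                 rank = match(ccres$ccre_type[s], ccre_types)) |>
    arrange(.data$te_row, dplyr::desc(.data$overlap), .data$rank) |>
    group_by(.data$te_row) |>
    slice(1) |>
    ungroup()
  out$ccre[best$te_row] <- best$ccre
  out
}

#' Subfamily enrichment of a DA-TE set against the genome background
#'
#' For each subfamily present in the set: the fraction of DA-TE copies it
#' contributes divided by its genome-background fraction (copy-count basis by
#' default; `basis = "bp"` uses base-pair fractions for the ratio). An upper
#' tail hypergeometric p-value (population = all TE copies, successes =
#' subfamily copies, draws = set size) is reported alongside, BH-adjusted
#' across subfamilies; the p-value is always copy-based. A zero background
#' fraction yields an NA ratio rather than an infinity.
#'
#' @param da_tes DA-TE tibble (needs `uid`, `subfamily`; `start`/`end` for
#'   `basis = "bp"`).
#' @param background Subfamily summary tibble from [subfamily_summaries()].
#' @param basis `"copies"` or `"bp"`.
#' @return A tibble with `unit`, `name`, `count_in_set`, `fraction_in_set`,
#'   `fraction_in_background`, `ratio`, `log2_ratio`, `pvalue`, `fdr`.
#' @export
subfamily_enrichment <- function(da_tes, background,
                                 basis = c("copies", "bp")) {
  basis <- match.arg(basis)
  if (nrow(da_tes) == 0) abort("empty DA-TE set")
  missing_bg <- setdiff(unique(da_tes$subfamily), background$subfamily)
  if (length(missing_bg) > 0) {
    abort(paste0("subfamilies absent from background: ",
                 paste(missing_bg, collapse = ", ")))
  }
  set_tab <- da_tes |>
    group_by(.data$subfamily) |>
    summarise(count_in_set = dplyr::n(),
              bp_in_set = if (basis == "bp") sum(.data$end - .data$start) else NA_real_,
              .groups = "drop")
  n_set <- nrow(da_tes)
  pop <- sum(background$copy_count)
  set_tab <- set_tab |>
    left_join(background, by = "subfamily") |>
    mutate(
      fraction_in_set = if (basis == "bp") {
        .data$bp_in_set / sum(.data$bp_in_set)
      } else {
        .data$count_in_set / n_set
      },
      fraction_in_background = if (basis == "bp") .data$bp_fraction else .data$copy_fraction,
      ratio = ifelse(.data$fraction_in_background > 0,
                     .data$fraction_in_set / .data$fraction_in_background,
                     NA_real_),
      log2_ratio = log2(.data$ratio),
      pvalue = phyper(.data$count_in_set - 1, .data$copy_count,
                      pop - .data$copy_count, n_set, lower.tail = FALSE)
    )
  set_tab |>
    mutate(unit = "subfamily", fdr = bh_fdr(.data$pvalue)) |>
    select("unit", name = "subfamily", "count_in_set", "fraction_in_set",
           "fraction_in_background", "ratio", "log2_ratio", "pvalue", "fdr") |>
    arrange(.data$pvalue)
}

#' TE-class enrichment among sex-shared DA-subfamilies
#'
#' The fraction of one class among the shared DA-subfamilies divided by the
#' fraction of the same class among all TE subfamilies (counting
#' subfamilies, not copies).
#'
#' @param shared_da_subfamilies Character vector of subfamily names DA in
#'   both sexes.
#' @param all_subfamilies Subfamily summary tibble (needs `subfamily`,
#'   `te_class`).
#' @return A tibble with `unit = "class"`, `name`, `count_in_set`,
#'   `fraction_in_set`, `fraction_in_background`, `ratio`, `log2_ratio`.
#' @export
class_enrichment_shared <- function(shared_da_subfamilies, all_subfamilies) {
  if (length(shared_da_subfamilies) == 0) abort("empty shared DA-subfamily set")
  if (nrow(all_subfamilies) == 0) abort("empty subfamily background")
  shared <- all_subfamilies |>
    filter(.data$subfamily %in% shared_da_subfamilies)
  bg_tab <- all_subfamilies |> count(.data$te_class, name = "n_background")
  set_tab <- shared |> count(.data$te_class, name = "count_in_set")
  bg_tab |>
    left_join(set_tab, by = "te_class") |>
    mutate(
      count_in_set = dplyr::coalesce(.data$count_in_set, 0L),
      fraction_in_set = .data$count_in_set / length(unique(shared$subfamily)),
      fraction_in_background = .data$n_background / nrow(all_subfamilies),
      ratio = .data$fraction_in_set / .data$fraction_in_background,
      log2_ratio = ifelse(.data$ratio > 0, log2(.data$ratio), -Inf),
      unit = "class"
    ) |>
    select("unit", name = "te_class", "count_in_set", "fraction_in_set",
           "fraction_in_background", "ratio", "log2_ratio")
}

#' Exposure specificity of DA-TEs
#'
#' Over the union of DA-TEs across exposures (within one sex), counts in how
#' many exposures each TE is differentially accessible and reports the
#' fraction responding to exactly one exposure.
#'
#' @param da_sets Named list mapping exposure to a character vector of DA-TE
#'   uids.
#' @return A list with `per_te` (tibble `te_uid`, `multiplicity`),
#'   `unique_fraction`, `n_exposures`.
#' @export
exposure_specificity <- function(da_sets) {
  if (length(da_sets) < 2) abort("need at least 2 exposures")
  per_te <- tibble(
    te_uid = unlist(lapply(da_sets, unique), use.names = FALSE)
  ) |>
    count(.data$te_uid, name = "multiplicity") |>
    arrange(.data$te_uid)
  list(
    per_te = per_te,
    unique_fraction = mean(per_te$multiplicity == 1),
    n_exposures = length(da_sets)
  )
}
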