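#' Find known transcripts with TE-derived TSSs
#'
#' A transcript is TE-derived iff its single strand-aware TSS base lies
#' within a TE interval; nested/overlapping TEs are resolved as in
#' [assign_summits_to_tes()] (shortest element wins).
#'
#' @param transcripts Transcript model tibble from [read_gene_models()].
#' @param tes TE annotation tibble.
#' @return A tibble of calls: `transcript_id`, `gene_id`, `transcript_type`,
#'   `gene_biotype`, `te_uid`, `te_class`, `subfamily`, and `expressed = NA`
#'   until [expressed_filter()] is applied.
#' @export
find_te_derived_transcripts <- function(transcripts, tes) {
  uid <- assign_points_to_tes(transcripts$chrom, transcripts$tss, tes)
  transcripts |>
    mutate(te_uid = uid) |>
    filter(!is.na(.data$te_uid)) |>
    left_join(select(tes, "uid", "te_class", "subfamily"),
              by = c(te_uid = "uid")) |>
    mutate(expressed = NA) |>
    select("transcript_id", "gene_id", "transcript_type", "gene_biotype",
           "te_uid", "te_class", "subfamily", "expressed")
}

# Shared CPM quorum: TRUE iff value > (or >=) threshold in strictly more than
# half of the samples of at least one condition group.
cpm_quorum <- function(cpm_tbl, ids, design, threshold, inclusive) {
  m <- counts_to_matrix(cpm_tbl)
  missing_ids <- setdiff(ids, rownames(m))
  if (length(missing_ids) > 0) {
    abort(paste0("feature(s) missing from CPM matrix: ",
                 paste(head(missing_ids, 5), collapse = ", ")))
  }
  cond <- design$condition[match(colnames(m), design$sample_id)]
  groups <- split(seq_len(ncol(m)), cond)
  unname(vapply(ids, function(id) {
    v <- m[id, ]
    any(vapply(groups, function(j) {
      hit <- if (inclusive) v[j] >= threshold else v[j] > threshold
      sum(hit) > length(j) / 2
    }, logical(1)))
  }, logical(1)))
}

#' Flag expressed TE-derived transcripts
#'
#' A call is expressed iff its CPM exceeds `threshold` (strictly, CPM > 1 by
#' default) in strictly more than half of the samples of at least one
#' condition group.
#'
#' @param calls Call tibble from [find_te_derived_transcripts()].
#' @param cpm_tbl CPM tibble (from [cpm()]) covering the called transcripts.
#' @param design Sample sheet with `sample_id`, `condition`.
#' @param threshold CPM threshold (default 1).
#' @return `calls` with the `expressed` flag filled in.
#' @export
expressed_filter <- function(calls, cpm_tbl, design, threshold = 1) {
  calls$expressed <- unname(
    cpm_quorum(cpm_tbl, calls$transcript_id, design, threshold,
               inclusive = FALSE))
  calls
}

#' Transcript-type composition of TE-derived calls
#'
#' Counts and fractions of each transcript type among TE-derived calls, and
#' the same among the remaining (non-TE-derived) transcripts for contrast.
#'
#' @param calls Call tibble (typically filtered to `expressed`).
#' @param all_transcripts Full transcript model tibble.
#' @return A tibble with `group` (`te_derived`/`non_te_derived`),
#'   `transcript_type`, `n`, `fraction`.
#' @export
transcript_type_composition <- function(calls, all_transcripts) {
  comp <- function(tbl, label) {
    if (nrow(tbl) == 0) {
      return(tibble(group = character(), transcript_type = character(),
                    n = integer(), fraction = double()))
    }
    tbl |>
      count(.data$transcript_type, name = "n") |>
      mutate(group = label, fraction = .data$n / sum(.data$n)) |>
      select("group", "transcript_type", "n", "fraction")
  }
  non_te <- all_transcripts |>
    filter(!.data$transcript_id %in% calls$transcript_id)
  bind_rows(comp(calls, "te_derived"), comp(non_te, "non_te_derived"))
}

#' Subfamily enrichment within each transcript type
#'
#' For each (subfamily, transcript type): the fraction of that type's
#' TE-derived calls contributed by the subfamily, divided by the subfamily's
#' genome-background copy fraction, with a copy-based hypergeometric p-value
#' as in [subfamily_enrichment()].
#'
#' @param calls Call tibble with `subfamily`, `transcript_type`.
#' @param background Subfamily summary tibble.
#' @return An enrichment tibble with an extra `transcript_type` column.
#' @export
subfamily_enrichment_by_type <- function(calls, background) {
  if (nrow(calls) == 0) {
    return(tibble(transcript_type = character(), unit = character(),
                  name = character(), count_in_set = integer(),
                  fraction_in_set = double(), fraction_in_background = double(),
                  ratio = double(), log2_ratio = double(), pvalue = double(),
                  fdr = double()))
  }
  calls |>
    group_by(.data$transcript_type) |>
    dplyr::group_modify(function(d, key) {
      subfamily_enrichment(
        tibble(uid = d$te_uid, subfamily = d$subfamily), background)
    }) |>
    ungroup()
}

#' Compare protein products of TE-derived and canonical isoforms
#'
#' For each TE-derived protein-coding call: `same` if its peptide exactly
#' equals the peptide of at least one non-TE-derived coding isoform of the
#' same gene, `different` otherwise, `no_canonical` if the gene has no
#' non-TE-derived coding isoform, and `noncoding` for non-coding calls.
#'
#' @param calls Call tibble.
#' @param transcripts Transcript model tibble with a `peptide` column
#'   populated for protein-coding transcripts.
#' @return A tibble with `transcript_id`, `gene_id`, `protein_comparison`,
#'   `peptide_length`, `compared_against`.
#' @export
compare_protein_products <- function(calls, transcripts) {
  pep <- setNames(transcripts$peptide, transcripts$transcript_id)
  coding <- transcripts$gene_biotype == "coding" &
    transcripts$transcript_type == "protein_coding"
  canon <- transcripts |>
    filter(coding, !.data$transcript_id %in% calls$transcript_id)
  purrr::map_dfr(seq_len(nrow(calls)), function(i) {
    cl <- calls[i, ]
    if (cl$transcript_type != "protein_coding") {
      return(tibble(transcript_id = cl$transcript_id, gene_id = cl$gene_id,
                    protein_comparison = "noncoding",
                    peptide_length = NA_integer_, compared_against = 0L))
    }
    p <- pep[[cl$transcript_id]]
    if (is.null(p) || is.na(p)) {
      abort(paste0("coding transcript without peptide: ", cl$transcript_id))
    }
    others <- canon$peptide[canon$gene_id == cl$gene_id]
    others <- others[!is.na(others)]
    cmp <- if (length(others) == 0) {
      "no_canonical"
    } else if (any(others == p)) {
      "same"
    } else {
      "different"
    }
    tibble(transcript_id = cl$transcript_id, gene_id = cl$gene_id,
           protein_comparison = cmp, peptide_length = nchar(p),
           compared_against = length(others))
  })
}
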