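# Strand-aware first/second exon of a transcript model row (exons sorted by
# genomic position; on "-" the first exon is the rightmost interval).
first_exon <- function(tx_row) {
  ex <- tx_row$exons[[1]]
  if (tx_row$strand == "-") ex[nrow(ex), ] else ex[1, ]
}

# Intron between the 1st and 2nd exon, genomic coordinates; NULL for
# single-exon transcripts.
first_intron <- function(tx_row) {
  ex <- tx_row$exons[[1]]
  n <- nrow(ex)
  if (n < 2) return(NULL)
  if (tx_row$strand == "-") {
    list(start = ex$end[n - 1], end = ex$start[n])
  } else {
    list(start = ex$end[1], end = ex$start[2])
  }
}

#' Detect assembled transcripts with a TE-derived first exon
#'
#' A candidate chimeric transcript is an assembled transcript whose
#' strand-aware TSS base lies within a TE (shortest-element tie-break for
#' nested TEs). Each candidate carries a filter ledger, filled in by the
#' `filter_*` functions, and a `category` set by [classify_chimeric()].
#'
#' @param assembled Assembled transcript model tibble (same shape as
#'   [read_gene_models()] output).
#' @param tes TE annotation tibble.
#' @return A candidate tibble: the transcript model columns plus `te_uid`,
#'   ledger columns (`filter_novel_first_exon`, `filter_junction`,
#'   `filter_expression`, with `_reason` companions) initialized to NA, and
#'   `category = "unclassified"`.
#' @export
detect_te_first_exon <- function(assembled, tes) {
  uid <- assign_points_to_tes(assembled$chrom, assembled$tss, tes)
  assembled |>
    mutate(te_uid = uid) |>
    filter(!is.na(.data$te_uid)) |>
    mutate(
      filter_novel_first_exon = NA_character_,
      filter_novel_first_exon_reason = NA_character_,
      filter_junction = NA_character_,
      filter_junction_reason = NA_character_,
      filter_expression = NA_character_,
      filter_expression_reason = NA_character_,
      category = "unclassified"
    )
}

#' Filter: the TE-derived first exon must be novel
#'
#' Fails a candidate whose first exon overlaps any annotated exon by at least
#' 1 bp. The overlap test is strand-agnostic by default (the conservative
#' reading); set `strand_aware = TRUE` to only count same-strand overlaps.
#'
#' @param candidates Candidate tibble from [detect_te_first_exon()].
#' @param gene_models Annotated transcript model tibble.
#' @param strand_aware Restrict the overlap test to same-strand exons.
#' @return `candidates` with `filter_novel_first_exon` set.
#' @export
filter_novel_first_exon <- function(candidates, gene_models,
                                    strand_aware = FALSE) {
  if (nrow(candidates) == 0) return(candidates)
  ex <- exon_table(gene_models)
  fe <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    e <- first_exon(candidates[i, ])
    tibble(chrom = candidates$chrom[i], start = e$start, end = e$end,
           strand = candidates$strand[i])
  })
  hit <- IRanges::overlapsAny(as_granges0(fe), as_granges0(ex),
                                    ignore.strand = !strand_aware)
  candidates |>
    mutate(
      filter_novel_first_exon = ifelse(hit, "fail", "pass"),
      filter_novel_first_exon_reason = ifelse(
        hit, "first exon overlaps an annotated exon", NA_character_)
    )
}

#' Filter: the first splice junction must be read-supported
#'
#' Passes a multi-exon candidate iff its exon1-exon2 junction has at least
#' `min_reads` supporting reads in at least one sample (`rule =
#' "any_sample"`, the default) or in every sample of at least one condition
#' (`rule = "all_of_condition"`, which requires `design`). Junctions absent
#' from the table count as zero support. Single-exon candidates record
#' `not_applicable`.
#'
#' @param candidates Candidate tibble.
#' @param junctions Tibble `chrom`, `intron_start`, `intron_end`, `strand`,
#'   then one read-count column per sample (0-based half-open intron).
#' @param min_reads Minimum supporting reads (default 2).
#' @param rule Quorum rule, see above.
#' @param design Sample sheet, required for `rule = "all_of_condition"`.
#' @return `candidates` with `filter_junction` set.
#' @export
filter_junction_support <- function(candidates, junctions, min_reads = 2,
                                    rule = c("any_sample", "all_of_condition"),
                                    design = NULL) {
  rule <- match.arg(rule)
  if (rule == "all_of_condition" && is.null(design)) {
    abort("rule = 'all_of_condition' requires a design")
  }
  if (nrow(candidates) == 0) return(candidates)
  meta_cols <- c("chrom", "intron_start", "intron_end", "strand")
  sample_cols <- setdiff(names(junctions), meta_cols)
  jm <- as.matrix(junctions[, sample_cols, drop = FALSE])
  key <- paste(junctions$chrom, junctions$intron_start, junctions$intron_end)
  res <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    intr <- first_intron(candidates[i, ])
    if (is.null(intr)) {
      return(tibble(filter_junction = "not_applicable",
                    filter_junction_reason = "single-exon transcript"))
    }
    row <- match(paste(candidates$chrom[i], intr$start, intr$end), key)
    reads <- if (is.na(row)) rep(0, length(sample_cols)) else jm[row, ]
    ok <- if (rule == "any_sample") {
      any(reads >= min_reads)
    } else {
      cond <- design$condition[match(sample_cols, design$sample_id)]
      any(vapply(split(reads, cond), function(v) all(v >= min_reads),
                 logical(1)))
    }
    tibble(
      filter_junction = ifelse(ok, "pass", "fail"),
      filter_junction_reason = ifelse(
        ok, NA_character_,
        paste0("max junction support ", max(reads), " < ", min_reads))
    )
  })
  candidates$filter_junction <- res$filter_junction
  candidates$filter_junction_reason <- res$filter_junction_reason
  candidates
}

#' Filter: the candidate must be expressed
#'
#' Passes iff CPM is at least `threshold` (inclusive, CPM >= 1 by default) in
#' strictly more than half of the samples of at least one condition group.
#'
#' @param candidates Candidate tibble.
#' @param cpm_tbl CPM tibble covering all candidates.
#' @param design Sample sheet with `sample_id`, `condition`.
#' @param threshold CPM threshold (default 1, inclusive).
#' @return `candidates` with `filter_expression` set.
#' @export
filter_expression <- function(candidates, cpm_tbl, design, threshold = 1) {
  if (nrow(candidates) == 0) return(candidates)
  ok <- cpm_quorum(cpm_tbl, candidates$transcript_id, design, threshold,
                   inclusive = TRUE)
  candidates |>
    mutate(
      filter_expression = ifelse(ok, "pass", "fail"),
      filter_expression_reason = ifelse(
        ok, NA_character_,
        "CPM quorum not met in any condition group")
    )
}

ledger_passes <- function(candidates) {
  pass1 <- candidates$filter_novel_first_exon %in% "pass"
  pass2 <- candidates$filter_junction %in% c("pass", "not_applicable")
  pass3 <- candidates$filter_expression %in% "pass"
  pass1 & pass2 & pass3
}

#' Classify surviving chimeric candidates into the four groups
#'
#' Candidates whose full filter ledger passes are classified with precedence
#' coding > noncoding > TE_transcript > TE_no_gene:
#' `TE_coding_gene` if any exon beyond the first overlaps an exon of an
#' annotated coding gene on the same strand; `TE_noncoding_gene` likewise for
#' noncoding genes; otherwise `TE_transcript` if every transcript base is
#' covered by the union of TE intervals (the covering elements are reported);
#' otherwise `TE_no_gene`. An antisense transcript inside a coding gene's
#' intron therefore lands in `TE_no_gene`.
#'
#' @param candidates Candidate tibble with the ledger filled in.
#' @param gene_models Annotated transcript model tibble.
#' @param tes TE annotation tibble.
#' @return `candidates` with `category`, `passes_filters` and `covering_tes`
#'   (comma-separated uids for `TE_transcript` rows) set; failed candidates
#'   stay `unclassified`.
#' @export
classify_chimeric <- function(candidates, gene_models, tes) {
  candidates$passes_filters <- ledger_passes(candidates)
  candidates$covering_tes <- NA_character_
  if (nrow(candidates) == 0) return(candidates)
  ex <- exon_table(gene_models)
  ex_coding <- as_granges0(filter(ex, .data$gene_biotype == "coding"))
  ex_noncod <- as_granges0(filter(ex, .data$gene_biotype == "noncoding"))
  te_gr <- as_granges0(tes)
  te_union <- GenomicRanges::reduce(te_gr, ignore.strand = TRUE)
  for (i in which(candidates$passes_filters)) {
    tx <- candidates[i, ]
    exi <- tx$exons[[1]]
    # exons beyond the strand-aware first exon
    rest <- if (tx$strand == "-") {
      exi[-nrow(exi), , drop = FALSE]
    } else {
      exi[-1, , drop = FALSE]
    }
    cat_i <- NULL
    if (nrow(rest) > 0) {
      rest_gr <- as_granges0(
        tibble(chrom = tx$chrom, start = rest$start, end = rest$end,
               strand = tx$strand))
      if (any(IRanges::overlapsAny(rest_gr, ex_coding,
                                         ignore.strand = FALSE))) {
        cat_i <- "TE_coding_gene"
      } else if (any(IRanges::overlapsAny(rest_gr, ex_noncod,
                                                ignore.strand = FALSE))) {
        cat_i <- "TE_noncoding_gene"
      }
    }
    if (is.null(cat_i)) {
      all_gr <- as_granges0(
        tibble(chrom = tx$chrom, start = exi$start, end = exi$end))
      uncovered <- GenomicRanges::setdiff(all_gr, te_union,
                                          ignore.strand = TRUE)
      if (sum(GenomicRanges::width(uncovered)) == 0) {
        cat_i <- "TE_transcript"
        cover <- IRanges::overlapsAny(te_gr, all_gr,
                                            ignore.strand = TRUE)
        candidates$covering_tes[i] <- paste(tes$uid[cover], collapse = ",")
      } else {
        cat_i <- "TE_no_gene"
      }
    }
    candidates$category[i] <- cat_i
  }
  candidates
}

#' Find the longest open reading frame in a spliced sequence
#'
#' Scans the given (already 5'-to-3') sequence for the longest ORF that
#' starts with ATG and ends at an in-frame stop codon. The reported length in
#' nucleotides includes the stop codon; the translated peptide excludes it.
#'
#' @param sequence A character scalar over A/C/G/T/N.
#' @param min_length Minimum ORF length in nt, stop included (default 300).
#' @return A one-row tibble `start` (0-based offset of the ATG), `length_nt`,
#'   `peptide`, or NULL when no qualifying ORF exists.
#' @export
find_orf <- function(sequence, min_length = 300) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    abort("sequence contains characters outside ACGTN")
  }
  n <- nchar(sequence)
  if (n < 6) return(NULL)
  codon_at <- function(pos) substr(sequence, pos, pos + 2)  # 1-based
  best <- NULL
  for (frame in 0:2) {
    starts <- seq(frame + 1, n - 2, by = 3)
    codons <- vapply(starts, codon_at, character(1))
    is_atg <- codons == "ATG"
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    stop_idx <- which(is_stop)
    for (a in which(is_atg)) {
      s <- stop_idx[stop_idx > a]
      if (length(s) == 0) next
      s <- s[1]
      len <- (s - a + 1) * 3
      if (len >= min_length && (is.null(best) || len > best$length_nt)) {
        orf_seq <- substr(sequence, starts[a], starts[a] + len - 1)
        pep <- as.character(Biostrings::translate(
          Biostrings::DNAString(substr(orf_seq, 1, len - 3))))
        best <- tibble(start = starts[a] - 1L, length_nt = len, peptide = pep)
      }
    }
  }
  best
}

#' Extract spliced transcript sequences from a genome
#'
#' Concatenates exon sequences in genomic order and reverse-complements for
#' minus-strand transcripts, yielding the 5'-to-3' spliced sequence.
#'
#' @param transcripts Transcript model tibble.
#' @param genome Named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences.
#' @return Named character vector of spliced sequences, keyed by
#'   `transcript_id`.
#' @export
extract_spliced_sequence <- function(transcripts, genome) {
  if (!inherits(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  out <- vapply(seq_len(nrow(transcripts)), function(i) {
    tx <- transcripts[i, ]
    ex <- tx$exons[[1]]
    chrseq <- genome[[tx$chrom]]
    parts <- vapply(seq_len(nrow(ex)), function(j) {
      as.character(Biostrings::subseq(chrseq, ex$start[j] + 1L, ex$end[j]))
    }, character(1))
    s <- paste(parts, collapse = "")
    if (tx$strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }, character(1))
  setNames(out, transcripts$transcript_id)
}
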