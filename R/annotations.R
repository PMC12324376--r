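#' Read a transposable-element annotation
#'
#' Reads a RepeatMasker-style table (UCSC `rmsk` dialect) or a BED6+ file into
#' a tidy TE annotation. Simple repeats, satellites and low-complexity records
#' are dropped, so only the four TE classes (DNA, LINE, SINE, LTR) are
#' retained; records with any other repeat class are skipped with a warning.
#' Coordinates are 0-based half-open throughout the package (`rmsk` tables are
#' already 0-based; BED likewise).
#'
#' @param path Path to the annotation file.
#' @param dialect `"rmsk"` for a tab-separated table with columns `genoName`,
#'   `genoStart`, `genoEnd`, `strand`, `repName`, `repClass`, `repFamily`
#'   (header optional), or `"bed"` for the BED6+ layout written by
#'   [write_te_bed()] (`chrom`, `start`, `end`, `subfamily`, `score`, `strand`,
#'   then optional `te_class`, `family`, `uid` columns).
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `subfamily`, `family`, `te_class`, `clade` (initially `"Other"`; see
#'   [assign_clades()]) and a deterministic file-order `uid`.
#' @seealso [assign_clades()], [subfamily_summaries()], [write_te_bed()]
#' @export
read_te_annotation <- function(path, dialect = c("rmsk", "bed")) {
  dialect <- match.arg(dialect)
  rmsk_cols <- c("genoName", "genoStart", "genoEnd", "strand",
                 "repName", "repClass", "repFamily")
  if (dialect == "rmsk") {
    first <- readLines(path, n = 1L)
    has_header <- length(first) == 1L && grepl("genoName", first, fixed = TRUE)
    raw <- readr::read_tsv(path,
      col_names = if (has_header) TRUE else rmsk_cols,
      col_types = readr::cols(.default = readr::col_character()),
      skip = if (has_header) 0L else 0L, progress = FALSE,
      show_col_types = FALSE)
    if (nrow(raw) == 0) return(empty_te_annotation())
    missing_cols <- setdiff(rmsk_cols, names(raw))
    if (length(missing_cols) > 0) {
      abort(paste0("rmsk table lacks columns: ",
                   paste(missing_cols, collapse = ", ")))
    }
    tes <- tibble(
      chrom = raw$genoName,
      start = parse_coord(raw$genoStart, path, has_header),
      end = parse_coord(raw$genoEnd, path, has_header),
      strand = normalize_strand(raw$strand),
      subfamily = raw$repName,
      family = raw$repFamily,
      te_class = raw$repClass
    )
  } else {
    raw <- readr::read_tsv(path, col_names = FALSE,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE, show_col_types = FALSE)
    if (nrow(raw) == 0) return(empty_te_annotation())
    if (ncol(raw) < 6) abort("BED dialect needs >= 6 columns")
    tes <- tibble(
      chrom = raw[[1]],
      start = parse_coord(raw[[2]], path, FALSE),
      end = parse_coord(raw[[3]], path, FALSE),
      strand = normalize_strand(raw[[6]]),
      subfamily = raw[[4]],
      family = if (ncol(raw) >= 8) raw[[8]] else NA_character_,
      te_class = if (ncol(raw) >= 7) raw[[7]] else NA_character_
    )
  }
  tes$uid <- sprintf("te_%06d", seq_len(nrow(tes)))
  check_intervals(tes, "TE record")

  drop_classes <- c("Simple_repeat", "Satellite", "Low_complexity")
  keep_classes <- c("DNA", "LINE", "SINE", "LTR")
  cls <- sub("\\?$", "", tes$te_class)
  tes <- tes[!cls %in% drop_classes, , drop = FALSE]
  cls <- sub("\\?$", "", tes$te_class)
  unknown <- !cls %in% keep_classes
  if (any(unknown)) {
    warn(paste0(sum(unknown), " record(s) with unrecognized repeat class ",
                "skipped: ", paste(unique(tes$te_class[unknown]), collapse = ", ")))
  }
  tes <- tes[!unknown, , drop = FALSE]
  tes$te_class <- sub("\\?$", "", tes$te_class)
  tes$clade <- "Other"
  tes[, c("chrom", "start", "end", "strand", "subfamily", "family",
          "te_class", "clade", "uid")]
}

empty_te_annotation <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         strand = character(), subfamily = character(), family = character(),
         te_class = character(), clade = character(), uid = character())
}

parse_coord <- function(x, path, has_header) {
  out <- suppressWarnings(as.integer(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    abort(paste0("malformed coordinate in ", path, " at line ",
                 bad[1] + as.integer(has_header)))
  }
  out
}

normalize_strand <- function(x) {
  # rmsk uses "C" for the reverse strand
  out <- ifelse(x == "C", "-", x)
  ifelse(out %in% c("+", "-"), out, ".")
}

#' Assign evolutionary clades to TE subfamilies
#'
#' Maps Dfam-style taxon names to the three named clades used to stratify
#' subfamily age: `Mus_genus`/`Mus_musculus` to `Mus_musculus`,
#' `Muridae`/`Murinae` to `Muridae`, and `Glires`/`Rodentia` to `Rodentia`.
#' Any other or missing taxon falls into `Other` (taxa older than Rodentia are
#' not distinguished).
#'
#' @param tes TE annotation tibble from [read_te_annotation()].
#' @param taxa_map Data frame with columns `subfamily` and `taxon`.
#' @return `tes` with the `clade` column filled in.
#' @export
assign_clades <- function(tes, taxa_map) {
  stopifnot(all(c("subfamily", "taxon") %in% names(taxa_map)))
  lut <- setNames(taxa_map$taxon, taxa_map$subfamily)
  taxon <- unname(lut[tes$subfamily])
  clade <- dplyr::case_when(
    taxon %in% c("Mus_genus", "Mus_musculus") ~ "Mus_musculus",
    taxon %in% c("Muridae", "Murinae") ~ "Muridae",
    taxon %in% c("Glires", "Rodentia") ~ "Rodentia",
    TRUE ~ "Other"
  )
  n_missing <- sum(is.na(taxon))
  if (n_missing > 0) {
    inform(paste0(n_missing, " TE record(s) without a taxa_map entry ",
                  "assigned clade 'Other'"))
  }
  tes$clade <- clade
  tes
}

#' Read gene models from a GTF file
#'
#' Imports a GENCODE-dialect GTF (1-based inclusive coordinates) and returns
#' one row per transcript with 0-based half-open exon coordinates nested in a
#' list-column. The transcription start and termination sites are single-base
#' positions derived strand-aware (`tss` is the leftmost base on `+`, the
#' rightmost on `-`). `transcript_type` is collapsed to the types tallied
#' downstream (protein_coding, retained_intron, processed_transcript, lincRNA,
#' other) and `gene_biotype` to coding/noncoding.
#'
#' @param path Path to a GTF file with `gene_id`, `transcript_id` and
#'   `transcript_type` attributes on exon rows.
#' @return A tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `transcript_type`, `gene_biotype`, `tss`, `tts`, `n_exons` and
#'   a list-column `exons` of tibbles (`start`, `end`, 0-based half-open,
#'   sorted by genomic position).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  is_exon <- mc$type == "exon"
  tx_ids <- unique(mc$transcript_id[!is.na(mc$transcript_id)])
  exon_tx <- unique(mc$transcript_id[is_exon])
  orphan <- setdiff(tx_ids, exon_tx)
  if (length(orphan) > 0) {
    abort(paste0("transcript(s) without exon rows: ",
                 paste(orphan, collapse = ", ")))
  }
  ex <- gr[is_exon]
  exmc <- S4Vectors::mcols(ex)
  ttype <- if ("transcript_type" %in% names(exmc)) {
    exmc$transcript_type
  } else if ("transcript_biotype" %in% names(exmc)) {
    exmc$transcript_biotype
  } else {
    rep(NA_character_, length(ex))
  }
  exons <- tibble(
    transcript_id = exmc$transcript_id,
    gene_id = exmc$gene_id,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    transcript_type = as.character(ttype)
  )
  build_transcript_models(exons)
}

# Exon table (transcript_id, gene_id, chrom, start, end, strand,
# transcript_type [, peptide]) -> one-row-per-transcript model tibble with
# strand-aware tss/tts and nested exons. Shared by the GTF reader and the
# synthetic generator.
build_transcript_models <- function(exons) {
  check_intervals(exons, "exon")
  known_types <- c("protein_coding", "retained_intron", "processed_transcript",
                   "lincRNA")
  has_pep <- "peptide" %in% names(exons)
  exons |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = first(.data$gene_id),
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      transcript_type = {
        tt <- first(.data$transcript_type)
        if (is.na(tt) || !tt %in% known_types) "other" else tt
      },
      tss = if (first(.data$strand) == "-") max(.data$end) - 1L else min(.data$start),
      tts = if (first(.data$strand) == "-") min(.data$start) else max(.data$end) - 1L,
      n_exons = dplyr::n(),
      exons = list(data.frame(start = start, end = end)),
      peptide = if (has_pep) first(.data$peptide) else NA_character_,
      .groups = "drop"
    ) |>
    mutate(gene_biotype = ifelse(.data$transcript_type == "protein_coding",
                                 "coding", "noncoding")) |>
    select("transcript_id", "gene_id", "chrom", "strand", "transcript_type",
           "gene_biotype", "tss", "tts", "n_exons", "exons", "peptide")
}

# Flat exon table from a transcript model tibble.
exon_table <- function(transcripts) {
  transcripts |>
    select("transcript_id", "gene_id", "chrom", "strand", "gene_biotype",
           "transcript_type", "exons") |>
    tidyr::unnest("exons")
}

#' Summarise TE subfamilies against the genome background
#'
#' Computes per-subfamily copy counts, total base pairs, and the fractions of
#' all TE copies / all TE bases each subfamily represents. These fractions are
#' the genome background used by the enrichment statistics. By default copy
#' lengths are summed without merging overlapping copies (RepeatMasker copies
#' rarely overlap and the statistic stays linear); set `merge_overlaps = TRUE`
#' to measure the union of intervals instead.
#'
#' @param tes TE annotation tibble.
#' @param merge_overlaps Merge overlapping copies of a subfamily before
#'   counting bases.
#' @return A tibble with `subfamily`, `te_class`, `clade`, `copy_count`,
#'   `bp_total`, `copy_fraction`, `bp_fraction`; the fraction columns each sum
#'   to 1.
#' @export
subfamily_summaries <- function(tes, merge_overlaps = FALSE) {
  if (nrow(tes) == 0) abort("empty TE annotation: no background definable")
  bp_fun <- if (merge_overlaps) {
    function(d) {
      gr <- GenomicRanges::reduce(as_granges0(d))
      sum(GenomicRanges::width(gr))
    }
  } else {
    function(d) sum(d$end - d$start)
  }
  out <- tes |>
    group_by(.data$subfamily) |>
    summarise(
      te_class = first(.data$te_class),
      clade = first(.data$clade),
      copy_count = dplyr::n(),
      bp_total = bp_fun(dplyr::pick(dplyr::everything())),
      .groups = "drop"
    ) |>
    mutate(
      copy_fraction = .data$copy_count / sum(.data$copy_count),
      bp_fraction = .data$bp_total / sum(.data$bp_total)
    )
  out
}

#' Write a TE annotation as BED6+
#'
#' Writes `chrom`, `start`, `end`, `subfamily`, `score` (0), `strand`,
#' `te_class`, `family`, `uid` — the layout [read_te_annotation()] reads back
#' with `dialect = "bed"`.
#'
#' @param tes TE annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_te_bed <- function(tes, path) {
  out <- tibble(
    chrom = tes$chrom, start = tes$start, end = tes$end,
    name = tes$subfamily, score = 0L, strand = tes$strand,
    te_class = tes$te_class, family = tes$family, uid = tes$uid
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
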