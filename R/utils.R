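# Internal helpers: seeded RNG streams, coordinate conversion, validation.

# Fixed label -> offset table so every sub-generator owns an RNG stream derived
# from the master seed; adding a stream never perturbs existing ones.
.stream_offsets <- c(
  annotation  = 101L,
  sequences   = 211L,
  genes       = 307L,
  peaks       = 401L,
  counts      = 503L,
  chimeric    = 601L,
  methylation = 701L,
  ccre        = 809L,
  misc        = 907L
)

stream_seed <- function(seed, label) {
  if (!label %in% names(.stream_offsets)) {
    abort(paste0("unknown RNG stream label: ", label))
  }
  (as.integer(seed) %% 2000000L) * 1000L + .stream_offsets[[label]]
}

# Evaluate `code` under the stream's seed (plus an optional salt for
# repeated draws from one stream), restoring the caller's RNG state.
with_stream <- function(seed, label, code, salt = 0L) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, label) + as.integer(salt))
  force(code)
}

# 0-based half-open tibble (chrom, start, end, [strand]) -> GRanges (1-based).
as_granges0 <- function(x, keep = character()) {
  strand <- if ("strand" %in% names(x)) {
    ifelse(x$strand %in% c("+", "-"), x$strand, "*")
  } else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
  for (k in keep) S4Vectors::mcols(gr)[[k]] <- x[[k]]
  gr
}

# Single-base positions (0-based) -> width-1 GRanges.
points_granges0 <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
}

check_intervals <- function(x, what = "interval") {
  if (any(x$start < 0) || any(x$start >= x$end)) {
    abort(paste0("invalid ", what, ": need 0 <= start < end"))
  }
  invisible(x)
}

is_count_matrix <- function(counts) {
  is.data.frame(counts) && names(counts)[1] == "feature_id" && ncol(counts) >= 2
}

# Counts tibble (feature_id + sample columns) -> integer matrix.
counts_to_matrix <- function(counts) {
  if (!is_count_matrix(counts)) {
    abort("counts must be a data frame with a leading feature_id column")
  }
  m <- as.matrix(counts[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- counts$feature_id
  if (any(m < 0)) abort("counts must be non-negative")
  m
}

matrix_to_tibble <- function(m) {
  dplyr::bind_cols(tibble(feature_id = rownames(m)), as_tibble(m))
}
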