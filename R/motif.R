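BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix
#'
#' Normalizes a count or probability matrix into a PWM with
#' pseudocount-smoothed per-position base probabilities. Scores downstream
#' are log2 odds against the background and are quantized to 1e-4 bits so
#' that exact score-distribution p-values are well defined.
#'
#' @param mat A 4 x L numeric matrix (rows A, C, G, T) of counts or
#'   probabilities.
#' @param motif_id Identifier string.
#' @param background Named background probabilities over A/C/G/T (default
#'   uniform).
#' @param pseudocount Pseudocount added to each cell of the probability
#'   matrix before log-odds (default 0.01).
#' @return An object of class `te_pwm`.
#' @export
pwm <- function(mat, motif_id = "motif",
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                pseudocount = 0.01) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) abort("PWM matrix needs 4 rows (A, C, G, T)")
  rownames(mat) <- BASES
  probs <- sweep(mat, 2, colSums(mat), "/")
  probs <- sweep(probs + pseudocount, 2, 1 + 4 * pseudocount, "/")
  background <- background[BASES] / sum(background[BASES])
  structure(
    list(motif_id = motif_id, matrix = probs, background = background,
         pseudocount = pseudocount),
    class = "te_pwm"
  )
}

#' @export
print.te_pwm <- function(x, ...) {
  cat("<te_pwm>", x$motif_id, "length", ncol(x$matrix), "\n")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Make a PWM from a consensus motif string
#'
#' Convenience constructor: each position gives probability `certainty` to
#' the consensus base and splits the remainder over the other three.
#'
#' @param motif Motif string over ACGT.
#' @param certainty Probability of the consensus base (default 0.97).
#' @inheritParams pwm
#' @return A `te_pwm`.
#' @export
pwm_from_string <- function(motif, motif_id = motif, certainty = 0.97,
                            pseudocount = 0.01) {
  chars <- strsplit(toupper(motif), "")[[1]]
  stopifnot(all(chars %in% BASES))
  mat <- vapply(chars, function(b) {
    p <- rep((1 - certainty) / 3, 4)
    p[match(b, BASES)] <- certainty
    p
  }, numeric(4))
  pwm(mat, motif_id = motif_id, pseudocount = pseudocount)
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR PFM text layout (`>ID name` header, then four lines
#' `A [ 1 2 3 ]` ... in ACGT order; bare whitespace-separated rows are also
#' accepted).
#'
#' @param path Path to the PFM file.
#' @inheritParams pwm
#' @return A named list of `te_pwm` objects.
#' @export
read_jaspar_pfm <- function(path, background = c(A = 0.25, C = 0.25,
                                                 G = 0.25, T = 0.25),
                            pseudocount = 0.01) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) abort("no '>' headers found: not JASPAR PFM format")
  out <- list()
  for (i in seq_along(heads)) {
    from <- heads[i] + 1
    to <- if (i < length(heads)) heads[i + 1] - 1 else length(lines)
    block <- lines[from:to]
    if (length(block) != 4) {
      abort(paste0("motif block at line ", heads[i], " does not have 4 rows"))
    }
    rows <- lapply(block, function(l) {
      l <- gsub("^[ACGTacgt]\\s*\\[|\\]\\s*$", "", trimws(l))
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1) {
      abort(paste0("ragged motif block at line ", heads[i]))
    }
    id <- strsplit(sub("^>\\s*", "", lines[heads[i]]), "\\s+")[[1]][1]
    out[[id]] <- pwm(do.call(rbind, rows), motif_id = id,
                     background = background, pseudocount = pseudocount)
  }
  out
}

# Integerized log2-odds score matrix (units of 1e-4 bits).
SCORE_SCALE <- 1e4

pwm_int_scores <- function(x) {
  s <- log2(sweep(x$matrix, 1, x$background, "/"))
  round(s * SCORE_SCALE)
}

reverse_complement_pwm <- function(x) {
  m <- x$matrix[4:1, rev(seq_len(ncol(x$matrix))), drop = FALSE]
  rownames(m) <- BASES
  y <- x
  y$matrix <- m
  y$background <- setNames(x$background[4:1], BASES)
  y
}

# Exact distribution of the integer window score under the background model:
# named vector prob, names = integer scores (ascending).
score_distribution <- function(int_scores, background) {
  dist <- c(`0` = 1)
  for (j in seq_len(ncol(int_scores))) {
    sc <- as.numeric(names(dist))
    new <- list()
    for (b in 1:4) {
      new[[b]] <- setNames(dist * background[b], sc + int_scores[b, j])
    }
    merged <- unlist(new, use.names = TRUE)
    dist <- tapply(merged, as.numeric(names(merged)), sum)
    dist <- setNames(as.numeric(dist), names(dist))
  }
  dist[order(as.numeric(names(dist)))]
}

#' Exact p-value of a PWM score
#'
#' The probability, under the background model, that a random window of the
#' motif's length scores at least `score`. Computed by exact
#' dynamic-programming convolution over the integerized (1e-4 bit) score
#' grid; monotone non-increasing in `score`.
#'
#' @param x A `te_pwm`.
#' @param score Log2-odds score in bits.
#' @return The exact upper-tail probability.
#' @export
score_pvalue <- function(x, score) {
  dist <- score_distribution(pwm_int_scores(x), x$background)
  sc <- as.numeric(names(dist))
  target <- round(score * SCORE_SCALE)
  vapply(target, function(t) sum(dist[sc >= t]), numeric(1))
}

# Per-window integer scores on one strand; NA bases (N) contribute 0.
window_scores <- function(int_scores, idx) {
  L <- ncol(int_scores)
  n <- length(idx)
  if (n < L) return(numeric(0))
  n_win <- n - L + 1
  total <- numeric(n_win)
  for (j in seq_len(L)) {
    v <- unname(int_scores[, j][idx[j:(j + n_win - 1)]])
    v[is.na(v)] <- 0
    total <- total + v
  }
  total
}

#' Scan a sequence with a PWM
#'
#' Scores every window on both strands (log2 odds against the background;
#' `N` bases contribute zero) and reports windows whose exact score p-value
#' is at most `p_threshold`. Minus-strand hits are windows matching the
#' reverse complement of the motif; offsets always refer to the forward
#' sequence.
#'
#' @param x A `te_pwm`.
#' @param sequence Character scalar over ACGTN.
#' @param p_threshold Exact p-value cutoff (default 1e-4).
#' @param sequence_id Identifier copied into the output.
#' @return A tibble `sequence_id`, `motif_id`, `offset` (0-based window
#'   start), `strand`, `score` (bits), `pvalue`; zero rows when the motif is
#'   longer than the sequence.
#' @export
scan_sequence <- function(x, sequence, p_threshold = 1e-4,
                          sequence_id = "seq") {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    abort("sequence contains characters outside ACGTN")
  }
  idx <- match(strsplit(sequence, "")[[1]], BASES)
  L <- ncol(x$matrix)
  empty <- tibble(sequence_id = character(), motif_id = character(),
                  offset = integer(), strand = character(),
                  score = double(), pvalue = double())
  if (length(idx) < L) return(empty)

  int_fwd <- pwm_int_scores(x)
  dist <- score_distribution(int_fwd, x$background)
  sc <- as.numeric(names(dist))
  pv <- rev(cumsum(rev(dist)))  # upper tail at each attainable score
  pval_of <- function(s) {
    vapply(s, function(si) {
      k <- which(sc >= si)
      if (length(k) == 0) 0 else pv[k[1]]
    }, numeric(1))
  }

  hits <- list()
  for (strand in c("+", "-")) {
    ints <- if (strand == "+") int_fwd else pwm_int_scores(reverse_complement_pwm(x))
    w <- window_scores(ints, idx)
    p <- pval_of(w)
    keep <- which(p <= p_threshold)
    if (length(keep) > 0) {
      hits[[strand]] <- tibble(
        sequence_id = sequence_id, motif_id = x$motif_id,
        offset = keep - 1L, strand = strand,
        score = w[keep] / SCORE_SCALE, pvalue = p[keep]
      )
    }
  }
  if (length(hits) == 0) return(empty)
  bind_rows(hits) |> arrange(.data$offset, .data$strand)
}

#' Globally align a TE copy to its subfamily consensus
#'
#' Needleman-Wunsch global alignment (match +2, mismatch -1, gap of length L
#' costs 4 + L) with per-consensus-column identity flags. An insertion in
#' the copy has no consensus column; a deletion shows as `-` in the copy.
#'
#' @param copy_sequence,consensus Character scalars over ACGT(N).
#' @return A list with `score`, `columns` (tibble `column` 1-based consensus
#'   position, `consensus_base`, `copy_base`, `identical`) and `copy_to_column`
#'   (integer vector mapping each 0-based copy position to its 1-based
#'   consensus column, NA for insertions).
#' @export
align_to_consensus <- function(copy_sequence, consensus) {
  stopifnot(nchar(copy_sequence) > 0, nchar(consensus) > 0)
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 2, mismatch = -1, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = toupper(copy_sequence), subject = toupper(consensus),
    type = "global", substitutionMatrix = sub_mat,
    gapOpening = 4, gapExtension = 1)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sbj <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  col_idx <- cumsum(sbj != "-")
  copy_pos <- cumsum(pat != "-")
  in_cons <- sbj != "-"
  columns <- tibble(
    column = col_idx[in_cons],
    consensus_base = sbj[in_cons],
    copy_base = pat[in_cons],
    identical = sbj[in_cons] == pat[in_cons] & pat[in_cons] != "-"
  )
  copy_to_column <- rep(NA_integer_, nchar(copy_sequence))
  has_copy <- pat != "-"
  copy_to_column[copy_pos[has_copy]] <- ifelse(in_cons[has_copy],
                                               col_idx[has_copy], NA_integer_)
  list(score = Biostrings::score(aln), columns = columns,
       copy_to_column = copy_to_column)
}

#' Split TE copies by motif presence and profile their conservation
#'
#' Scans each copy with the given PWMs, projects hits onto the consensus via
#' pairwise alignment, and labels a copy `with_motif` iff at least one hit
#' overlaps the core region in consensus coordinates. Per-column identity
#' profiles (fraction of copies in the group matching the consensus base;
#' alignment gaps count as mismatches) are returned for both groups together
#' with the mean core-identity difference.
#'
#' @param copies Named character vector of copy sequences.
#' @param pwms A `te_pwm` or list of them.
#' @param consensus Consensus sequence string.
#' @param core_region Length-2 integer vector, 0-based half-open interval on
#'   the consensus.
#' @param p_threshold Scan p-value cutoff (default 1e-4).
#' @return A list with `presence` (tibble `sequence_id`, `with_motif`,
#'   `n_core_hits`), `profiles` (tibble `group`, `column`, `identity`,
#'   `n_copies`; identity NA for an empty group), and `core_summary` (tibble
#'   `group`, `n_copies`, `mean_core_identity`) plus
#'   `core_identity_difference` (with minus without).
#' @export
motif_presence_groups <- function(copies, pwms, consensus, core_region,
                                  p_threshold = 1e-4) {
  if (inherits(pwms, "te_pwm")) pwms <- list(pwms)
  stopifnot(length(core_region) == 2,
            core_region[1] >= 0, core_region[2] <= nchar(consensus),
            core_region[1] < core_region[2])
  core_cols <- (core_region[1] + 1):core_region[2]  # 1-based columns
  n_cons <- nchar(consensus)
  ids <- names(copies) %||% sprintf("copy_%03d", seq_along(copies))

  ident_mat <- matrix(FALSE, nrow = length(copies), ncol = n_cons,
                      dimnames = list(ids, NULL))
  with_motif <- logical(length(copies))
  n_core_hits <- integer(length(copies))
  for (i in seq_along(copies)) {
    aln <- align_to_consensus(copies[[i]], consensus)
    ident <- rep(FALSE, n_cons)
    ok <- aln$columns$identical
    ident[aln$columns$column[ok]] <- TRUE
    ident_mat[i, ] <- ident
    hits <- bind_rows(lapply(pwms, scan_sequence, sequence = copies[[i]],
                             p_threshold = p_threshold, sequence_id = ids[i]))
    if (nrow(hits) > 0) {
      L_by_motif <- vapply(pwms, function(p) ncol(p$matrix), integer(1))
      names(L_by_motif) <- vapply(pwms, function(p) p$motif_id, character(1))
      in_core <- vapply(seq_len(nrow(hits)), function(h) {
        L <- L_by_motif[[hits$motif_id[h]]]
        pos <- hits$offset[h] + seq_len(L)  # 1-based copy positions
        cols <- aln$copy_to_column[pos]
        any(!is.na(cols) & cols %in% core_cols)
      }, logical(1))
      n_core_hits[i] <- sum(in_core)
      with_motif[i] <- any(in_core)
    }
  }

  presence <- tibble(sequence_id = ids, with_motif = with_motif,
                     n_core_hits = n_core_hits)
  profile_of <- function(rows, label) {
    n <- length(rows)
    identity <- if (n == 0) rep(NA_real_, n_cons) else
      colMeans(ident_mat[rows, , drop = FALSE])
    tibble(group = label, column = seq_len(n_cons), identity = identity,
           n_copies = n)
  }
  profiles <- bind_rows(
    profile_of(which(with_motif), "with_motif"),
    profile_of(which(!with_motif), "without_motif")
  )
  core_summary <- profiles |>
    filter(.data$column %in% core_cols) |>
    group_by(.data$group) |>
    summarise(n_copies = first(.data$n_copies),
              mean_core_identity = mean(.data$identity), .groups = "drop")
  d <- core_summary$mean_core_identity[core_summary$group == "with_motif"] -
    core_summary$mean_core_identity[core_summary$group == "without_motif"]
  list(presence = presence, profiles = profiles, core_summary = core_summary,
       core_identity_difference = if (length(d) == 1) d else NA_real_)
}
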