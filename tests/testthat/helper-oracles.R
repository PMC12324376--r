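# Independent brute-force oracles used to cross-check the implementation.

# All-pairs containment: for each point, every TE whose half-open interval
# contains it; resolved shortest, then leftmost, then lexicographic subfamily.
oracle_assign_points <- function(chrom, pos, tes) {
  vapply(seq_along(pos), function(i) {
    hit <- which(tes$chrom == chrom[i] & tes$start <= pos[i] & pos[i] < tes$end)
    if (length(hit) == 0) return(NA_character_)
    o <- order(tes$end[hit] - tes$start[hit], tes$start[hit],
               tes$subfamily[hit])
    tes$uid[hit[o[1]]]
  }, character(1))
}

# Any-overlap genomic feature label with precedence TSS > TTS > exon >
# intron > intergenic, loop-based.
oracle_feature_label <- function(tes, gene_models, w = 1000) {
  ex <- tidyr::unnest(dplyr::select(gene_models, "transcript_id", "chrom",
                                    "exons"), "exons")
  overlaps <- function(a1, a2, b1, b2) a1 < b2 & b1 < a2
  vapply(seq_len(nrow(tes)), function(i) {
    s <- tes$start[i]; e <- tes$end[i]; ch <- tes$chrom[i]
    gm <- gene_models[gene_models$chrom == ch, ]
    if (any(overlaps(s, e, pmax(gm$tss - w, 0), gm$tss + w + 1))) return("TSS")
    if (any(overlaps(s, e, pmax(gm$tts - w, 0), gm$tts + w + 1))) return("TTS")
    exch <- ex[ex$chrom == ch, ]
    if (any(overlaps(s, e, exch$start, exch$end))) return("exon")
    spans <- vapply(gm$exons, function(d) c(min(d$start), max(d$end)),
                    numeric(2))
    if (length(spans) && any(overlaps(s, e, spans[1, ], spans[2, ]))) {
      return("intron")
    }
    "intergenic"
  }, character(1))
}

# Step-up BH definition applied literally.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- rep(NA_real_, n)
  running_min <- Inf
  for (k in n:1) {
    running_min <- min(running_min, p[o[k]] * n / k)
    adj[o[k]] <- min(running_min, 1)
  }
  adj
}

# Upper-tail hypergeometric by explicit enumeration with choose().
oracle_hyper_upper <- function(obs, successes, population, draws) {
  ks <- obs:min(successes, draws)
  sum(choose(successes, ks) * choose(population - successes, draws - ks)) /
    choose(population, draws)
}

# Exact paired Wilcoxon two-sided p by enumerating all 2^n sign vectors.
oracle_wilcoxon <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  p_le <- mean(vs <= v_obs)
  p_ge <- mean(vs >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Exhaustive PWM score distribution: score every one of the 4^L windows
# using the same quantized per-position score definition.
oracle_pwm_pvalue <- function(x, score) {
  smat <- round(log2(sweep(x$matrix, 1, x$background, "/")) * 1e4)
  L <- ncol(smat)
  grids <- expand.grid(rep(list(1:4), L))
  w_scores <- rowSums(vapply(seq_len(L), function(j) smat[grids[[j]], j],
                             numeric(nrow(grids))))
  w_probs <- apply(vapply(seq_len(L), function(j) x$background[grids[[j]]],
                          numeric(nrow(grids))), 1, prod)
  vapply(score, function(s) sum(w_probs[w_scores >= round(s * 1e4)]),
         numeric(1))
}

# Global affine-gap alignment score by dynamic programming, written
# independently of the alignment path used in the package (gap of length L
# costs open + L * extend).
oracle_nw_score <- function(a, b, match = 2, mismatch = -1,
                            open = 4, extend = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + extend * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(open + extend * (j - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Longest ATG..stop ORF by scanning every start position directly.
oracle_orf <- function(seq, min_length = 300) {
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (s in seq_len(max(0, n - 5))) {
    if (substr(seq, s, s + 2) != "ATG") next
    pos <- s + 3
    while (pos + 2 <= n) {
      cod <- substr(seq, pos, pos + 2)
      if (cod %in% stops) {
        len <- pos + 3 - s
        if (len >= min_length && (is.null(best) || len > best$length_nt)) {
          best <- list(start = s - 1L, length_nt = len)
        }
        break
      }
      pos <- pos + 3
    }
  }
  best
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small random TE annotation for property tests.
random_te_annotation <- function(n, chroms = c("chr1", "chr2"), span = 100000) {
  start <- sample.int(span, n, replace = TRUE)
  sf_idx <- sample.int(8, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample(50:2000, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    subfamily = sprintf("sf%02d", sf_idx),
    family = "fam",
    te_class = c("DNA", "LINE", "SINE", "LTR")[(sf_idx - 1) %% 4 + 1],
    clade = "Other",
    uid = sprintf("te_%06d", seq_len(n))
  )
}
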