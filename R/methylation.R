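#' Read a CpG methylation table
#'
#' Bismark-style TSV with columns `chrom`, `pos` (0-based), `strand`,
#' `methylated`, `coverage`, and optionally `sample_id`. A header line is
#' detected automatically.
#'
#' @param path Path to the TSV.
#' @return A tibble of CpG records.
#' @export
read_methylation <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^chrom\\b", first)
  cols <- c("chrom", "pos", "strand", "methylated", "coverage", "sample_id")
  raw <- readr::read_tsv(path, col_names = has_header,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE)
  if (!has_header) names(raw) <- cols[seq_len(ncol(raw))]
  out <- tibble(
    chrom = raw$chrom,
    pos = as.integer(raw$pos),
    strand = raw$strand,
    methylated = as.integer(raw$methylated),
    coverage = as.integer(raw$coverage)
  )
  if ("sample_id" %in% names(raw)) out$sample_id <- raw$sample_id
  if (any(out$methylated > out$coverage)) {
    abort("methylated count exceeds coverage")
  }
  out
}

#' Filter CpG sites by coverage
#'
#' Retains only sites with at least `min_coverage` reads (default 20X).
#'
#' @param records CpG record tibble.
#' @param min_coverage Minimum coverage (default 20).
#' @return The filtered tibble.
#' @export
filter_cpgs <- function(records, min_coverage = 20) {
  dplyr::filter(records, .data$coverage >= min_coverage)
}

#' Aggregate CpG methylation over TE copies or subfamilies
#'
#' Assigns each CpG to its containing TE copy (shortest-element tie-break
#' for nested copies) and averages per-CpG methylation ratios
#' (`methylated / coverage`) — unweighted by default, coverage-weighted
#' pooling (summing methylated and total reads) with `weighted = TRUE`. At
#' subfamily level the mean is over all passing CpGs inside any copy of the
#' subfamily, not over copies. Units with no passing CpG are omitted (a
#' count is logged). When the records carry a `sample_id` column the
#' aggregation is per sample.
#'
#' @param cpgs CpG record tibble (already coverage-filtered; see
#'   [filter_cpgs()]).
#' @param tes TE annotation tibble.
#' @param level `"copy"` or `"subfamily"`.
#' @param weighted Coverage-weighted pooling instead of the unweighted mean
#'   of ratios.
#' @return A tibble with `unit`, `id` (uid or subfamily), optional
#'   `sample_id`, `mean_methylation`, `n_cpgs_used`.
#' @export
aggregate_te_methylation <- function(cpgs, tes, level = c("copy", "subfamily"),
                                     weighted = FALSE) {
  level <- match.arg(level)
  uid <- assign_points_to_tes(cpgs$chrom, cpgs$pos, tes)
  inside <- !is.na(uid)
  n_outside_units <- nrow(tes) - length(unique(uid[inside]))
  if (n_outside_units > 0) {
    inform(paste0(n_outside_units,
                  " TE cop(ies) with no passing CpG omitted from output"))
  }
  d <- cpgs[inside, , drop = FALSE]
  d$id <- if (level == "copy") {
    uid[inside]
  } else {
    tes$subfamily[match(uid[inside], tes$uid)]
  }
  groups <- if ("sample_id" %in% names(d)) c("id", "sample_id") else "id"
  d |>
    group_by(across(dplyr::all_of(groups))) |>
    summarise(
      mean_methylation = if (weighted) {
        sum(.data$methylated) / sum(.data$coverage)
      } else {
        mean(.data$methylated / .data$coverage)
      },
      n_cpgs_used = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(unit = level) |>
    select("unit", "id", dplyr::any_of("sample_id"), "mean_methylation",
           "n_cpgs_used")
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided paired test of matched values. Zero differences are dropped
#' (standard convention) and ties in the absolute differences receive
#' mid-ranks. For up to `exact_max` informative pairs the null distribution
#' of the positive-rank sum is computed exactly over all 2^n sign
#' assignments (by convolution, which enumerates the same distribution);
#' beyond that a normal approximation with continuity and tie correction is
#' used.
#'
#' @param x,y Numeric vectors of equal length (condition A and matched
#'   condition B).
#' @param exact_max Largest n for the exact null (default 25).
#' @return A one-row tibble with `statistic` (positive-rank sum `V`),
#'   `pvalue`, `n_pairs` (after zero removal), `method`.
#' @export
paired_wilcoxon <- function(x, y, exact_max = 25) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) abort("no nonzero paired differences: test undefined")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # doubled ranks are integers even with mid-ranks
    r2 <- as.integer(round(2 * r))
    dist <- c(1)  # prob * 2^n over grid of doubled rank sums, offset 0
    for (ri in r2) {
      shifted <- c(rep(0, ri), dist)
      dist <- c(dist, rep(0, ri)) + shifted
    }
    dist <- dist / 2^n
    sums <- seq_along(dist) - 1  # doubled-rank sums
    v2 <- round(2 * v)
    p_le <- sum(dist[sums <= v2])
    p_ge <- sum(dist[sums >= v2])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approximation"
  }
  tibble(statistic = v, pvalue = p, n_pairs = n, method = method)
}

#' Paired methylation contrast over TE subfamilies
#'
#' Aggregates CpG methylation to subfamily level per sample, averages within
#' condition, and tests the exposed-vs-control shift across subfamilies with
#' the exact paired Wilcoxon signed-rank test (pairs = subfamilies).
#'
#' @param cpgs CpG record tibble with `sample_id` (already coverage
#'   filtered).
#' @param tes TE annotation tibble.
#' @param design Sample sheet with `sample_id`, `condition`.
#' @param subfamilies Optional subfamily subset to test (e.g. DA-subfamilies).
#' @return A list with `per_subfamily` (tibble `subfamily`, `mean_control`,
#'   `mean_exposed`, `difference`) and `test` (the [paired_wilcoxon()] row).
#' @export
methylation_contrast <- function(cpgs, tes, design, subfamilies = NULL) {
  agg <- aggregate_te_methylation(cpgs, tes, level = "subfamily")
  agg$condition <- design$condition[match(agg$sample_id, design$sample_id)]
  per <- agg |>
    group_by(subfamily = .data$id, .data$condition) |>
    summarise(m = mean(.data$mean_methylation), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "m",
                       names_prefix = "mean_") |>
    filter(!is.na(.data$mean_control), !is.na(.data$mean_exposed)) |>
    mutate(difference = .data$mean_exposed - .data$mean_control)
  if (!is.null(subfamilies)) {
    per <- filter(per, .data$subfamily %in% subfamilies)
  }
  list(
    per_subfamily = per,
    test = paired_wilcoxon(per$mean_exposed, per$mean_control)
  )
}
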