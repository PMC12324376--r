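#' Counts per million
#'
#' Scales each count by its sample's library size times 1e6. Library sizes
#' default to column sums; pass `library_sizes` (named by sample) to use
#' pre-computed totals.
#'
#' @param counts Data frame with a leading `feature_id` column and one column
#'   of non-negative integer counts per sample.
#' @param library_sizes Optional named numeric vector of per-sample totals.
#' @return A tibble of the same shape with CPM values.
#' @export
cpm <- function(counts, library_sizes = NULL) {
  m <- counts_to_matrix(counts)
  ls <- resolve_library_sizes(m, library_sizes)
  matrix_to_tibble(sweep(m, 2, ls, "/") * 1e6)
}

resolve_library_sizes <- function(m, library_sizes) {
  if (is.null(library_sizes)) {
    ls <- colSums(m)
  } else {
    if (!all(colnames(m) %in% names(library_sizes))) {
      abort("library_sizes must be named for every sample")
    }
    ls <- library_sizes[colnames(m)]
  }
  zero <- names(ls)[ls <= 0]
  if (length(zero) > 0) {
    abort(paste0("zero library size for sample(s): ",
                 paste(zero, collapse = ", ")))
  }
  ls
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment: sorted p-values are scaled by n/rank and made monotone
#' from the largest down.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  n <- length(pvalues)
  ord <- order(pvalues)
  adj <- pvalues[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[ord] <- adj
  out
}

#' Tier thresholds for differential calls
#'
#' The five significance tiers applied downstream of the NB test, exactly as
#' used throughout the analysis (strict inequalities):
#' \describe{
#'   \item{subfamily_expression}{FDR < 0.001, |log2FC| > 0.8, and median CPM
#'     > 100 in control or exposed samples}
#'   \item{subfamily_accessibility}{FDR < 0.001, |log2FC| > 0.15, same CPM
#'     prefilter}
#'   \item{dar}{FDR < 0.01, |log2FC| > log2(1.5)}
#'   \item{transcript}{FDR < 0.01, |log2FC| > 1}
#'   \item{chimeric}{FDR < 0.05, |log2FC| > log2(1.5)}
#' }
#'
#' @param tier Tier name; with no argument, the full table is returned.
#' @return A tibble with `tier`, `fdr_max`, `abs_log2fc_min`,
#'   `median_cpm_min` (NA when no CPM prefilter applies).
#' @export
tier_thresholds <- function(tier = NULL) {
  tt <- tibble(
    tier = c("subfamily_expression", "subfamily_accessibility", "dar",
             "transcript", "chimeric"),
    fdr_max = c(0.001, 0.001, 0.01, 0.01, 0.05),
    abs_log2fc_min = c(0.8, 0.15, log2(1.5), 1, log2(1.5)),
    median_cpm_min = c(100, 100, NA, NA, NA)
  )
  if (is.null(tier)) return(tt)
  row <- tt[tt$tier == tier, , drop = FALSE]
  if (nrow(row) == 0) abort(paste0("unknown tier name: ", tier))
  row
}

#' Negative-binomial differential test
#'
#' Tests each feature for a condition effect (exposed vs control) with a
#' negative-binomial likelihood-ratio test. Per-feature dispersions are
#' estimated by method of moments on library-size-normalized counts and shrunk
#' toward the common (pooled) dispersion with weight proportional to the
#' residual degrees of freedom; the GLM (log link, library-size offset) is
#' then fit at the fixed shrunk dispersion and the condition effect tested
#' with a 1-df likelihood-ratio chi-square. Fold changes are computed from
#' normalized group means with a prior count of 0.5 per group, and p-values
#' are BH-adjusted across all tested features (one multiple-testing family per
#' contrast).
#'
#' @param counts Data frame with a leading `feature_id` column and integer
#'   counts, one column per sample.
#' @param design Data frame with columns `sample_id` and `condition`
#'   (`control`/`exposed`); extra columns (`sex`, `exposure`) are carried
#'   through unchecked.
#' @param library_sizes Optional named per-sample totals (defaults to column
#'   sums).
#' @param prior_count Prior count added to each normalized group mean before
#'   taking log2 (default 0.5).
#' @param prior_df Prior degrees of freedom pulling per-feature dispersions
#'   toward the common value (default 10).
#' @return An object of class `te_diff`; `tidy()` returns the per-feature
#'   table (`feature_id`, `log2fc`, `pvalue`, `fdr`, `median_cpm_control`,
#'   `median_cpm_exposed`, `status = "ns"` until [classify_differential()]).
#' @export
nb_differential <- function(counts, design, library_sizes = NULL,
                            prior_count = 0.5, prior_df = 10) {
  m <- counts_to_matrix(counts)
  if (any(m != round(m))) abort("counts must be integers")
  if (!all(colnames(m) %in% design$sample_id)) {
    abort("every count column needs a design row")
  }
  cond <- design$condition[match(colnames(m), design$sample_id)]
  if (!all(cond %in% c("control", "exposed"))) {
    abort("condition must be 'control' or 'exposed'")
  }
  n_ctrl <- sum(cond == "control"); n_exp <- sum(cond == "exposed")
  if (n_ctrl < 2 || n_exp < 2) {
    abort("each condition needs at least 2 samples")
  }
  ls <- resolve_library_sizes(m, library_sizes)

  # normalized counts on a common pseudo-library scale
  norm <- sweep(m, 2, mean(ls) / ls, "*")
  grp <- cond == "exposed"
  disp <- shrunk_dispersions(norm, grp, prior_df)

  cpm_m <- sweep(m, 2, ls, "/") * 1e6
  med_ctrl <- apply(cpm_m[, !grp, drop = FALSE], 1, median)
  med_exp <- apply(cpm_m[, grp, drop = FALSE], 1, median)
  mean_ctrl <- rowMeans(norm[, !grp, drop = FALSE])
  mean_exp <- rowMeans(norm[, grp, drop = FALSE])
  log2fc <- log2((mean_exp + prior_count) / (mean_ctrl + prior_count))

  cond_f <- factor(cond, levels = c("control", "exposed"))
  log_ls <- log(ls)
  pvalue <- vapply(seq_len(nrow(m)), function(i) {
    nb_lrt_pvalue(m[i, ], cond_f, log_ls, disp[i])
  }, numeric(1))

  result <- tibble(
    feature_id = rownames(m),
    log2fc = unname(log2fc),
    pvalue = pvalue,
    fdr = bh_fdr(pvalue),
    median_cpm_control = unname(med_ctrl),
    median_cpm_exposed = unname(med_exp),
    status = "ns"
  )
  structure(
    list(result = result, dispersion = disp,
         n_control = n_ctrl, n_exposed = n_exp,
         library_sizes = ls),
    class = "te_diff"
  )
}

# Method-of-moments per-feature NB dispersion on normalized counts, pooled
# within condition, shrunk toward the common dispersion with weight
# proportional to residual df.
shrunk_dispersions <- function(norm, grp, prior_df) {
  per_group <- function(sub) {
    mu <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    ifelse(mu > 0, (v - mu) / mu^2, NA_real_)
  }
  est <- cbind(per_group(norm[, !grp, drop = FALSE]),
               per_group(norm[, grp, drop = FALSE]))
  phi_i <- rowMeans(est, na.rm = TRUE)
  phi_i[!is.finite(phi_i)] <- 0
  phi_i <- pmax(phi_i, 0)
  phi_common <- mean(phi_i[phi_i > 0])
  if (!is.finite(phi_common)) phi_common <- 1e-4
  resid_df <- ncol(norm) - 2
  phi <- (resid_df * phi_i + prior_df * phi_common) / (resid_df + prior_df)
  pmax(phi, 1e-6)
}

# 1-df NB likelihood-ratio p for a condition effect at fixed dispersion phi.
nb_lrt_pvalue <- function(y, cond_f, log_ls, phi) {
  if (all(y == 0)) return(1)
  fam <- MASS::negative.binomial(theta = 1 / phi)
  fit1 <- try(suppressWarnings(
    glm(y ~ cond_f + offset(log_ls), family = fam)), silent = TRUE)
  fit0 <- try(suppressWarnings(
    glm(y ~ 1 + offset(log_ls), family = fam)), silent = TRUE)
  if (inherits(fit1, "try-error") || inherits(fit0, "try-error")) return(NA_real_)
  lr <- max(0, fit0$deviance - fit1$deviance)
  pchisq(lr, df = 1, lower.tail = FALSE)
}

#' Classify differential results into up / down / ns
#'
#' Applies a tier's thresholds (see [tier_thresholds()]) with strict
#' inequalities: `up` if `fdr < fdr_max` and `log2fc > abs_log2fc_min`;
#' `down` if `fdr < fdr_max` and `log2fc < -abs_log2fc_min`; otherwise `ns`.
#' When the tier carries a median-CPM prefilter, features whose median CPM
#' does not exceed it in either condition are `ns` regardless.
#'
#' @param results A `te_diff` object or its tidy per-feature tibble.
#' @param tier Tier name, or a one-row data frame of thresholds.
#' @return The same type as `results`, with `status` filled in.
#' @export
classify_differential <- function(results, tier) {
  if (inherits(results, "te_diff")) {
    results$result <- classify_differential(results$result, tier)
    results$tier <- if (is.character(tier)) tier else tier$tier
    return(results)
  }
  th <- if (is.character(tier)) tier_thresholds(tier) else as_tibble(tier)
  cpm_ok <- if (is.na(th$median_cpm_min)) {
    rep(TRUE, nrow(results))
  } else {
    pmax(results$median_cpm_control, results$median_cpm_exposed) > th$median_cpm_min
  }
  results$status <- dplyr::case_when(
    cpm_ok & results$fdr < th$fdr_max & results$log2fc > th$abs_log2fc_min ~ "up",
    cpm_ok & results$fdr < th$fdr_max & results$log2fc < -th$abs_log2fc_min ~ "down",
    TRUE ~ "ns"
  )
  results
}

#' Correlation of fold changes between sexes
#'
#' Pearson correlation of paired log2 fold changes over a shared feature set,
#' used to ask whether female and male livers respond concordantly to the
#' same exposure.
#'
#' @param results_female,results_male Tidy differential tables (or `te_diff`
#'   objects) for the same contrast in each sex.
#' @param shared_features Optional character vector restricting the
#'   comparison; defaults to all features present in both tables.
#' @return A one-row tibble with `r`, `n_shared`.
#' @export
sex_concordance <- function(results_female, results_male,
                            shared_features = NULL) {
  f <- if (inherits(results_female, "te_diff")) results_female$result else results_female
  m <- if (inherits(results_male, "te_diff")) results_male$result else results_male
  shared <- shared_features %||% intersect(f$feature_id, m$feature_id)
  shared <- intersect(intersect(shared, f$feature_id), m$feature_id)
  if (length(shared) < 3) {
    abort("fewer than 3 shared features: correlation undefined")
  }
  x <- f$log2fc[match(shared, f$feature_id)]
  y <- m$log2fc[match(shared, m$feature_id)]
  tibble(r = cor(x, y), n_shared = length(shared))
}

#' @exportS3Method generics::tidy
tidy.te_diff <- function(x, ...) x$result

#' @exportS3Method generics::glance
glance.te_diff <- function(x, ...) {
  tibble(
    n_features = nrow(x$result),
    n_control = x$n_control,
    n_exposed = x$n_exposed,
    n_up = sum(x$result$status == "up"),
    n_down = sum(x$result$status == "down"),
    common_dispersion = mean(x$dispersion),
    tier = x$tier %||% NA_character_
  )
}

#' @export
print.te_diff <- function(x, ...) {
  cat("<te_diff> NB differential test:", nrow(x$result), "features,",
      x$n_control, "control vs", x$n_exposed, "exposed\n")
  print(x$result, n = 6)
  invisible(x)
}
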