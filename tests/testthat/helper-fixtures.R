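# Shared fixtures, built once per test run and memoised in the session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# The default synthetic dataset (the study conditions).
shared_sim <- function() {
  memo("sim", function() simulate_dataset(simulation_config(seed = 101)))
}

# One full pipeline run on the shared dataset, with outputs on disk.
shared_pipeline <- function() {
  memo("pipeline", function() {
    dir <- file.path(tempdir(), "teomics_pipeline_run1")
    suppressMessages(run_pipeline(sim = shared_sim(), outdir = dir))
  })
}

shared_pipeline_dir <- function() {
  shared_pipeline()
  file.path(tempdir(), "teomics_pipeline_run1")
}

# Compact configuration matching the documented bookkeeping example:
# 4 classes x 5 subfamilies x 50 copies on 2 x 1 Mb chromosomes.
small_config <- function(seed = 5) {
  simulation_config(
    seed = seed,
    n_subfamilies = c(DNA = 5, LINE = 5, SINE = 5, LTR = 5),
    n_planted_hypo_subfams = 5
  )
}

# A tiny two-condition design for direct count matrices.
tiny_design <- function(n_per_group = 6) {
  tibble::tibble(
    sample_id = paste0("s", seq_len(2 * n_per_group)),
    condition = rep(c("control", "exposed"), each = n_per_group)
  )
}

# NB count tibble with the given per-feature group means.
nb_counts <- function(mu_control, mu_exposed, n_per_group = 6,
                      dispersion = 0.1) {
  n <- length(mu_control)
  mu <- cbind(matrix(rep(mu_control, n_per_group), ncol = n_per_group),
              matrix(rep(mu_exposed, n_per_group), ncol = n_per_group))
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow = n)
  colnames(counts) <- paste0("s", seq_len(2 * n_per_group))
  dplyr::bind_cols(tibble::tibble(feature_id = paste0("f", seq_len(n))),
                   tibble::as_tibble(counts))
}
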