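# Shared fixtures, all generated in code.

# A small, fast study design: same structure as the default, fewer CpGs.
small_config <- function(seed = 7, n_cpgs = 300L, n_per_domain = 10L, ...) {
  sim_config(n_cpgs = n_cpgs, n_per_domain = n_per_domain, seed = seed, ...)
}

small_sim <- function(seed = 7, ...) {
  simulate_cohorts(small_config(seed = seed, ...))
}

# Random valid beta matrix with identifiers.
rand_beta <- function(p, n, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(p * n, 0.05, 0.95), nrow = p,
              dimnames = list(sprintf("cg%03d", seq_len(p)),
                              sprintf("s%02d", seq_len(n))))
  m
}

# Hand-built latent model around explicit loadings (for selection tests).
toy_model <- function(loadings_vec) {
  ids <- names(loadings_vec)
  loadings <- matrix(loadings_vec, ncol = 1,
                     dimnames = list(ids, "PC1"))
  structure(list(cpg_ids = ids,
                 center = setNames(rep(0.5, length(ids)), ids),
                 loadings = loadings,
                 explained_variance = 1,
                 scores = NULL, sign_oriented = FALSE, n_train = 4L),
            class = "eldar_model")
}

# Split a simulated pool into per-dataset cohorts (matrices + sheets).
split_cohorts <- function(sim) {
  ids <- split(sim$sheet$sample_id, sim$sheet$dataset)
  list(matrices = lapply(ids, function(i) sim$beta[, i, drop = FALSE]),
       sheets = lapply(ids, function(i) sim$sheet[sim$sheet$sample_id %in% i, ]))
}
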