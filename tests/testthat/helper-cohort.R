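# Shared fixtures built in code. The default cohort is generated once per
# test run and memoized; tests that mutate it must copy first.

.fixture_env <- new.env(parent = emptyenv())

fixture_cohort <- function(seed = 101) {
  key <- paste0("cohort", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_cohort(sim_config(seed = seed))
  .fixture_env[[key]]
}

# A small, fast cohort for structural tests (not for power-sensitive checks).
fixture_small_cohort <- function(seed = 7) {
  key <- paste0("small", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- sim_config(
      n_normal = 20, n_osteopenia = 25, n_osteoporosis = 30,
      n_features = c(methylation = 40, metabolite = 30, microbiota = 25),
      n_signature = c(methylation = 4, metabolite = 4, microbiota = 4),
      n_group_signature = c(methylation = 5, metabolite = 4, microbiota = 4),
      n_fracture_features = c(methylation = 2, metabolite = 2, microbiota = 2),
      rewiring_pairs = 3, n_variants = 60, n_qtl_effects = 2, seed = seed)
    .fixture_env[[key]] <- generate_cohort(cfg)
  }
  .fixture_env[[key]]
}

# Tiny DLSF config for structural (non-power) tests.
fast_dlsf_config <- function(...) {
  dlsf_config(latent_dim = 4, hidden_dim = 16, epochs_pretrain = 30,
              epochs_joint = 30, ...)
}

# Ideal two-block affinity matrix.
block_affinity <- function(sizes = c(10, 10)) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  S <- outer(lab, lab, "==") * 1
  diag(S) <- 0
  rownames(S) <- colnames(S) <- paste0("s", seq_len(n))
  S
}
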