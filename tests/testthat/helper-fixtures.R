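# Shared fixtures, computed once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# The standard synthetic benchmark: 120 microbes, 20 diseases, rank 4,
# density 0.05, view noise 0.1.
fixture_data <- function(seed = 1L) {
  key <- paste0("data_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_synthetic(synthetic_spec(seed = seed))
  }
  .fixture_cache[[key]]
}

fixture_fused <- function(seed = 1L, cfg = default_config()) {
  key <- paste0("fused_", seed, "_", cfg$ablation, "_", cfg$alpha)
  if (is.null(.fixture_cache[[key]])) {
    data <- fixture_data(seed)
    .fixture_cache[[key]] <- list(
      SMpp = do.call(fuse_side, c(unname(data$microbe_sims), list(cfg = cfg))),
      SDpp = do.call(fuse_side, c(unname(data$disease_sims), list(cfg = cfg)))
    )
  }
  .fixture_cache[[key]]
}

# A small problem for fast training tests: 40 microbes, 10 diseases.
small_problem <- function(seed = 7L) {
  key <- paste0("small_", seed)
  if (is.null(.fixture_cache[[key]])) {
    spec <- synthetic_spec(n_microbes = 40L, n_diseases = 10L, latent_rank = 3L,
                           association_density = 0.1, view_noise_sd = 0.1,
                           seed = seed)
    data <- generate_synthetic(spec)
    # divisor 5 keeps >= 2 KNN neighbors on the 10-disease side (single-neighbor
    # affinity graphs can make the cross-diffusion oscillate)
    cfg <- default_config(layer_size = 32L, epochs = 100L, seed = seed,
                          knn_divisor = 5L)
    .fixture_cache[[key]] <- list(
      data = data,
      cfg = cfg,
      SMpp = do.call(fuse_side, c(unname(data$microbe_sims), list(cfg = cfg))),
      SDpp = do.call(fuse_side, c(unname(data$disease_sims), list(cfg = cfg)))
    )
  }
  .fixture_cache[[key]]
}

# Random symmetric similarity-like matrix with unit diagonal, values in [0,1].
random_similarity <- function(n, seed) {
  set.seed(seed)
  S <- matrix(runif(n * n), n, n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  ids <- paste0("e", seq_len(n))
  dimnames(S) <- list(ids, ids)
  S
}

pair_keys <- function(idx) paste(idx[, 1L], idx[, 2L])
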