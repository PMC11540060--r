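#' Specification of a synthetic benchmark
#'
#' Parameters of the latent-factor generator. The defaults define the
#' package's standard test fixture: 120 microbes, 20 diseases, a rank-4
#' shared latent structure, 5% association density and view noise with
#' standard deviation 0.1.
#'
#' @param n_microbes,n_diseases Entity counts.
#' @param latent_rank Dimension of the shared latent factors.
#' @param association_density Fraction of pairs labeled positive, in (0, 1).
#' @param view_noise_sd Standard deviation of the symmetric noise added to
#'   each of the three kernel views per side.
#' @param fs_noise_sd Standard deviation of the noise on the
#'   functional/semantic similarity.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the spec.
#' @return A validated list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_microbes = 120L, n_diseases = 20L,
                           latent_rank = 4L, association_density = 0.05,
                           view_noise_sd = 0.1, fs_noise_sd = 0.1,
                           seed = 1L) {
  spec <- list(n_microbes = as.integer(n_microbes),
               n_diseases = as.integer(n_diseases),
               latent_rank = as.integer(latent_rank),
               association_density = association_density,
               view_noise_sd = view_noise_sd,
               fs_noise_sd = fs_noise_sd,
               seed = as.integer(seed))
  stopifnot(spec$n_microbes >= 2L, spec$n_diseases >= 2L, spec$latent_rank >= 1L,
            spec$association_density > 0, spec$association_density < 1,
            spec$view_noise_sd >= 0, spec$fs_noise_sd >= 0)
  if (round(spec$association_density * spec$n_microbes * spec$n_diseases) < 1) {
    stop("association_density yields zero positive pairs")
  }
  structure(spec, class = "synthetic_spec")
}

#' @keywords internal
cosine_rows <- function(X) {
  nr <- sqrt(rowSums(X^2))
  Xn <- X / nr
  C <- tcrossprod(Xn)
  C <- pmin(pmax(C, 0), 1)
  diag(C) <- 1
  C
}

#' @keywords internal
noisy_view <- function(C, sd, ids) {
  n <- nrow(C)
  E <- matrix(stats::rnorm(n * n, sd = sd), n, n)
  E <- (E + t(E)) / 2
  M <- pmin(pmax(C + E, 0), 1)
  diag(M) <- 1
  dimnames(M) <- list(ids, ids)
  M
}

#' Generate a synthetic microbe-disease benchmark
#'
#' Emulates the statistical structure the method assumes: microbes and
#' diseases share a low-rank latent geometry; associations are the
#' top-density fraction of the latent inner products (so the positive count
#' is exact and fold arithmetic deterministic); each of the three kernel
#' views per side is the cosine similarity of the latent factors corrupted by
#' independent symmetric noise, clipped to `[0, 1]` with unit diagonal; the
#' functional (microbe) and semantic (disease) similarities are noisy copies
#' of the same cosine structure.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `A` (binary association matrix), `microbe_sims` and
#'   `disease_sims` (named lists `cos`, `gip`, `sig`, `fs` of similarity
#'   matrices), `latents` (`U`, `V`) and `truth` (noiseless cosine matrices
#'   per side).
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  nm <- spec$n_microbes; nd <- spec$n_diseases; r <- spec$latent_rank
  U <- matrix(stats::rnorm(nm * r), nm, r)
  V <- matrix(stats::rnorm(nd * r), nd, r)
  mids <- paste0("m", seq_len(nm))
  dids <- paste0("d", seq_len(nd))

  aff <- U %*% t(V)
  npos <- round(spec$association_density * nm * nd)
  A <- matrix(0, nm, nd, dimnames = list(mids, dids))
  A[order(aff, decreasing = TRUE)[seq_len(npos)]] <- 1

  Cm <- cosine_rows(U); dimnames(Cm) <- list(mids, mids)
  Cd <- cosine_rows(V); dimnames(Cd) <- list(dids, dids)
  microbe_sims <- list(cos = noisy_view(Cm, spec$view_noise_sd, mids),
                       gip = noisy_view(Cm, spec$view_noise_sd, mids),
                       sig = noisy_view(Cm, spec$view_noise_sd, mids),
                       fs  = noisy_view(Cm, spec$fs_noise_sd, mids))
  disease_sims <- list(cos = noisy_view(Cd, spec$view_noise_sd, dids),
                       gip = noisy_view(Cd, spec$view_noise_sd, dids),
                       sig = noisy_view(Cd, spec$view_noise_sd, dids),
                       fs  = noisy_view(Cd, spec$fs_noise_sd, dids))
  list(A = A, microbe_sims = microbe_sims, disease_sims = disease_sims,
       latents = list(U = U, V = V), truth = list(cos_m = Cm, cos_d = Cd),
       spec = spec)
}

#' Write a synthetic dataset to a directory
#'
#' One labeled CSV per matrix plus a YAML manifest of the generating spec.
#'
#' @param data Output of [generate_synthetic()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_synthetic <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(data$A, file.path(dir, "associations.csv"))
  for (nm in names(data$microbe_sims)) {
    write_matrix(data$microbe_sims[[nm]],
                 file.path(dir, paste0("microbe_", nm, ".csv")))
  }
  for (nm in names(data$disease_sims)) {
    write_matrix(data$disease_sims[[nm]],
                 file.path(dir, paste0("disease_", nm, ".csv")))
  }
  yaml::write_yaml(unclass(data$spec), file.path(dir, "manifest.yaml"))
  invisible(dir)
}
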