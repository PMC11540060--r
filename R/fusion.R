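#' Full-kernel row normalization
#'
#' Rescales a similarity matrix so that every diagonal entry is exactly 1/2
#' and every off-diagonal entry `S[i,j]` becomes
#' `S[i,j] / (2 * sum_{k != i} S[i,k])`, making each row sum to 1. This is
#' the "full kernel" used as the initial state of the cross-diffusion.
#'
#' @param S Square nonnegative similarity matrix.
#' @param uniform_fallback If `TRUE`, a row whose off-diagonal entries are all
#'   zero is replaced by a uniform distribution over the other entities
#'   instead of raising an error.
#' @return Row-stochastic matrix with diagonal 0.5.
#' @export
normalize_full <- function(S, uniform_fallback = FALSE) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  n <- nrow(S)
  off <- S
  diag(off) <- 0
  rs <- rowSums(off)
  isolated <- rs == 0
  if (any(isolated)) {
    if (!uniform_fallback) {
      ids <- if (!is.null(rownames(S))) rownames(S)[isolated] else which(isolated)
      stop("entity with all-zero off-diagonal similarity: ",
           paste(ids, collapse = ", "),
           " (set uniform_fallback = TRUE to substitute a uniform row)")
    }
    off[isolated, ] <- 1
    off[cbind(which(isolated), which(isolated))] <- 0
    rs[isolated] <- n - 1
  }
  out <- off / (2 * rs)
  diag(out) <- 0.5
  dimnames(out) <- dimnames(S)
  out
}

#' Sparse KNN affinity
#'
#' Per row, keeps the `n_neighbors` largest off-diagonal raw similarities
#' (ties broken toward the lower column index) and renormalizes them to sum
#' to 1; every other entry is 0. Self-similarity is excluded from the
#' candidate set.
#'
#' @param S Square nonnegative similarity matrix (raw, not normalized).
#' @param n_neighbors Number of neighbors to retain, `1 <= n_neighbors < nrow(S)`.
#' @return Sparse (many-zero) row-stochastic matrix.
#' @export
knn_affinity <- function(S, n_neighbors) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  n <- nrow(S)
  n_neighbors <- as.integer(n_neighbors)
  if (n_neighbors < 1L) stop("n_neighbors must be >= 1")
  if (n_neighbors >= n) stop("n_neighbors must be < matrix dimension (", n, ")")
  out <- matrix(0, n, n, dimnames = dimnames(S))
  for (i in seq_len(n)) {
    row <- S[i, ]
    row[i] <- -Inf
    # order() is stable: among ties the lower index wins
    keep <- order(row, decreasing = TRUE)[seq_len(n_neighbors)]
    tot <- sum(S[i, keep])
    if (tot > 0) out[i, keep] <- S[i, keep] / tot
  }
  out
}

#' Number of KNN neighbors from the divisor rule
#'
#' `floor(n_entities / divisor)`, with a floor of 1 so small problems remain
#' well defined.
#'
#' @param n_entities Number of entities on the side being fused.
#' @param divisor Divisor (default 10).
#' @return Integer neighbor count.
#' @export
knn_count <- function(n_entities, divisor = 10L) {
  max(1L, as.integer(floor(n_entities / divisor)))
}

#' Cross-diffusion of similarity views
#'
#' Iteratively updates each of the three row-normalized similarity views by
#' propagating the average of the *other* two views through its own KNN
#' affinity graph:
#' `SM_k^(t) = SKNN_k %*% mean_{j != k}(SM_j^(t-1)) %*% t(SKNN_k)`.
#' All views are updated simultaneously from the previous iterate. Iteration
#' stops when every view's relative Frobenius change drops below `tol`, or at
#' `max_iter` with a warning. The returned matrix is the elementwise mean of
#' the three converged views.
#'
#' @param views List of three row-stochastic matrices (from [normalize_full()]).
#' @param affinities List of three KNN affinity matrices (from [knn_affinity()]).
#' @param tol Relative Frobenius-norm convergence tolerance.
#' @param max_iter Iteration cap.
#' @param renormalize If `TRUE`, re-apply [normalize_full()] to each view
#'   after every update (off by default; the update is used as printed).
#' @return List with `SM` (fused mean matrix), `iterations`, `residuals`
#'   (matrix of per-view relative changes per iteration) and `converged`.
#' @export
cross_diffuse <- function(views, affinities, tol = 1e-6, max_iter = 1000L,
                          renormalize = FALSE) {
  stopifnot(length(views) == 3L, length(affinities) == 3L, tol > 0)
  dims <- vapply(views, nrow, integer(1L))
  if (length(unique(dims)) != 1L) stop("view dimensions disagree")
  cur <- views
  residuals <- matrix(NA_real_, nrow = 0L, ncol = 3L)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    nxt <- vector("list", 3L)
    for (k in 1:3) {
      others <- (Reduce(`+`, cur) - cur[[k]]) / 2  # mean of the other m-1 = 2 views
      nxt[[k]] <- affinities[[k]] %*% others %*% t(affinities[[k]])
      if (!all(is.finite(nxt[[k]]))) {
        stop("non-finite values in cross-diffusion at iteration ", it)
      }
      if (renormalize) nxt[[k]] <- normalize_full(nxt[[k]])
    }
    rel <- vapply(1:3, function(k) {
      denom <- sqrt(sum(cur[[k]]^2))
      if (denom == 0) return(Inf)
      sqrt(sum((nxt[[k]] - cur[[k]])^2)) / denom
    }, numeric(1L))
    residuals <- rbind(residuals, rel)
    cur <- nxt
    if (all(rel < tol)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("cross-diffusion did not converge in ", max_iter,
            " iterations (last residuals: ",
            paste(signif(residuals[nrow(residuals), ], 3), collapse = ", "), ")")
  }
  SM <- (cur[[1L]] + cur[[2L]] + cur[[3L]]) / 3
  dimnames(SM) <- dimnames(views[[1L]])
  rownames(residuals) <- NULL
  list(SM = SM, iterations = it, residuals = residuals, converged = converged)
}

#' Symmetrize a square matrix
#'
#' @param SM Square matrix.
#' @return `(SM + t(SM)) / 2`.
#' @export
symmetrize <- function(SM) {
  stopifnot(is.matrix(SM), nrow(SM) == ncol(SM))
  (SM + t(SM)) / 2
}

#' Convex merge with the functional/semantic similarity
#'
#' @param SMp Symmetrized diffusion output.
#' @param FS Functional (microbe) or semantic (disease) similarity matrix.
#' @param alpha Weight in `[0, 1]` on the diffused matrix.
#' @return `alpha * SMp + (1 - alpha) * FS`.
#' @export
merge_with_functional <- function(SMp, FS, alpha) {
  if (!all(dim(SMp) == dim(FS))) {
    stop("shape mismatch: ", paste(dim(SMp), collapse = "x"), " vs ",
         paste(dim(FS), collapse = "x"))
  }
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  out <- alpha * SMp + (1 - alpha) * FS
  dimnames(out) <- dimnames(SMp)
  out
}

#' Fuse one entity side end to end
#'
#' Composition of the full pipeline for one side (microbes or diseases):
#' row normalization of the three kernel views, KNN affinity construction,
#' cross-diffusion to a consensus matrix, symmetrization, and the convex
#' merge with the functional/semantic similarity. Under the `SF` ablation the
#' whole pipeline is replaced by the plain elementwise mean of the four
#' inputs.
#'
#' @param cos,gip,sig The three kernel similarity views (square, symmetric,
#'   values in `[0, 1]`, shared entity order).
#' @param fs Functional/semantic similarity matrix of the same entities.
#' @param cfg A [default_config()] list; uses `knn_divisor`, `fusion_tol`,
#'   `fusion_max_iter`, `alpha`, `renormalize_views`, `uniform_fallback` and
#'   `ablation`.
#' @return The fused feature matrix (square, symmetric).
#' @export
fuse_side <- function(cos, gip, sig, fs, cfg = default_config()) {
  raw <- list(cos, gip, sig)
  dims <- vapply(c(raw, list(fs)), nrow, integer(1L))
  if (length(unique(dims)) != 1L) stop("all four matrices must share dimensions")
  if (identical(cfg$ablation, "SF")) {
    out <- (cos + gip + sig + fs) / 4
    dimnames(out) <- dimnames(fs)
    return(out)
  }
  nn <- knn_count(nrow(fs), cfg$knn_divisor)
  views <- lapply(raw, normalize_full, uniform_fallback = cfg$uniform_fallback)
  aff <- lapply(raw, knn_affinity, n_neighbors = nn)
  diff <- cross_diffuse(views, aff, tol = cfg$fusion_tol,
                        max_iter = cfg$fusion_max_iter,
                        renormalize = cfg$renormalize_views)
  merge_with_functional(symmetrize(diff$SM), fs, cfg$alpha)
}
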