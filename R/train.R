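## ---- parameter flattening ---------------------------------------------------

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(vec, skeleton) {
  pos <- 0L
  fill <- function(sk) {
    if (is.list(sk)) return(lapply(sk, fill))
    n <- length(sk)
    out <- vec[pos + seq_len(n)]
    pos <<- pos + n
    dim(out) <- dim(sk)
    out
  }
  fill(skeleton)
}

# decoupled-weight-decay mask: decay weight matrices, never the JK coefficients
wd_mask <- function(params) {
  mk <- function(sk, decay) {
    if (is.list(sk)) return(lapply(sk, mk, decay = decay))
    rep(decay, length(sk))
  }
  unlist(lapply(names(params), function(nm) {
    mk(params[[nm]], decay = if (nm == "omega") 0 else 1)
  }), use.names = FALSE)
}

zero_like <- function(p) {
  if (is.list(p)) return(lapply(p, zero_like))
  out <- p
  out[] <- 0
  out
}

## ---- loss and gradient ------------------------------------------------------

#' @keywords internal
model_loss_grad <- function(params, prep, cfg, A, positives, negatives) {
  fwd <- model_forward(params, prep, cfg)
  idx <- rbind(positives, negatives)
  npair <- nrow(idx)
  grads <- zero_like(params)
  L <- cfg$layer_size

  if (cfg$ablation == "Dec") {
    Z <- fwd$lambda_m %*% t(fwd$lambda_d)
    scores <- sigmoid(Z)
    Gmat <- matrix(0, prep$nm, prep$nd)
    Gmat[idx] <- scores[idx] - A[idx]
    dLm <- Gmat %*% fwd$lambda_d
    dLd <- t(Gmat) %*% fwd$lambda_m
  } else {
    cc <- corr_all(fwd$lambda_m, fwd$lambda_d)
    scores <- sigmoid(cc$Z)
    Gmat <- matrix(0, prep$nm, prep$nd)
    Gmat[idx] <- scores[idx] - A[idx]
    rf_m <- rowSums(Gmat * cc$Z)
    rf_d <- colSums(Gmat * cc$Z)
    dcm <- (Gmat %*% cc$hd - rf_m * cc$hm) * cc$inm
    dcd <- (t(Gmat) %*% cc$hm - rf_d * cc$hd) * cc$ind
    dLm <- dcm - rowMeans(dcm)
    dLd <- dcd - rowMeans(dcd)
  }

  p <- pmin(pmax(scores[idx], 1e-7), 1 - 1e-7)
  a <- A[idx]
  loss <- -sum(a * log(p) + (1 - a) * log(1 - p))
  if (cfg$loss_reduction == "mean" && npair > 0L) {
    loss <- loss / npair
    dLm <- dLm / npair
    dLd <- dLd / npair
  }

  if (cfg$ablation == "Het") {
    dSM3 <- dLm
    dSD3 <- dLd
  } else {
    dSM3 <- dLm[, seq_len(L), drop = FALSE]
    dSD3 <- dLd[, seq_len(L), drop = FALSE]
    dHtilde <- rbind(dLm[, L + seq_len(L), drop = FALSE],
                     dLd[, L + seq_len(L), drop = FALSE])

    nlay <- cfg$n_hetero_layers
    omega <- if (cfg$jk_mode == "fixed") rep(1 / nlay, nlay) else params$omega
    dlayers <- vector("list", nlay)
    if (cfg$ablation == "JK") {
      for (l in seq_len(nlay)) dlayers[[l]] <- 0
      dlayers[[nlay]] <- dHtilde
    } else {
      for (l in seq_len(nlay)) dlayers[[l]] <- omega[l] * dHtilde
      if (cfg$jk_mode == "learnable") {
        grads$omega <- vapply(seq_len(nlay), function(l) {
          sum(fwd$layers[[l]] * dHtilde)
        }, numeric(1L))
      }
    }

    k <- cfg$k_neighborhood
    widths <- block_widths(L, k)
    ends <- cumsum(widths)
    starts <- ends - widths + 1L
    tP <- t(prep$P)
    dH_above <- 0
    for (l in rev(seq_len(nlay))) {
      cache <- fwd$caches[[l]]
      dHl <- dlayers[[l]] + dH_above
      dpre <- dHl * (cache$pre > 0)
      dQ_list <- vector("list", k + 1L)
      for (i in 0:k) {
        dpre_i <- dpre[, starts[i + 1L]:ends[i + 1L], drop = FALSE]
        grads$Whet[[l]][[i + 1L]] <- crossprod(cache$Qs[[i + 1L]], dpre_i)
        dQ_list[[i + 1L]] <- dpre_i %*% t(params$Whet[[l]][[i + 1L]])
      }
      # Horner accumulation of sum_i (t(P))^i dQ_i
      acc <- dQ_list[[k + 1L]]
      if (k > 0L) {
        for (i in (k - 1L):0L) acc <- tP %*% acc + dQ_list[[i + 1L]]
      }
      dH_above <- acc
    }
    dSM3 <- dSM3 + dH_above[seq_len(prep$nm), , drop = FALSE]
    dSD3 <- dSD3 + dH_above[prep$nm + seq_len(prep$nd), , drop = FALSE]
  }

  grads$Wm <- crossprod(prep$PXm, dSM3 * (fwd$pre_m > 0))
  grads$Wd <- crossprod(prep$PXd, dSD3 * (fwd$pre_d > 0))
  list(loss = loss, grads = grads, scores = scores)
}

## ---- negative sampling ------------------------------------------------------

#' Random negative sampling
#'
#' Uniform sample without replacement from the unlabeled (zero) entries of
#' the association matrix — the conventional treatment of the
#' positive-unlabeled setting.
#'
#' @param A Binary association matrix.
#' @param n Number of negatives to draw.
#' @param seed Integer seed; identical seeds give identical sets.
#' @param exclude Optional two-column index matrix of pairs that must not be
#'   drawn (e.g. held-out evaluation negatives).
#' @return Two-column integer matrix of (row, col) indices.
#' @export
sample_negatives_random <- function(A, n, seed, exclude = NULL) {
  zeros <- which(A == 0, arr.ind = TRUE)
  zeros <- drop_pairs(zeros, exclude)
  if (n > nrow(zeros)) {
    stop("requested ", n, " negatives but only ", nrow(zeros),
         " unlabeled pairs are available")
  }
  set.seed(seed)
  sel <- sample.int(nrow(zeros), n)
  unname(zeros[sel, , drop = FALSE])
}

#' @keywords internal
drop_pairs <- function(idx, exclude) {
  if (is.null(exclude) || nrow(exclude) == 0L) return(idx)
  keep <- !(paste(idx[, 1L], idx[, 2L]) %in%
              paste(exclude[, 1L], exclude[, 2L]))
  idx[keep, , drop = FALSE]
}

#' Cluster-guided negative sampling
#'
#' Represents each unlabeled pair by the concatenation of its microbe and
#' disease feature vectors, partitions the pairs into `n_clusters` by k-means
#' and draws negatives proportionally from every cluster (remainder assigned
#' round-robin). Drawing from all clusters spreads the sampled negatives over
#' the feature space instead of letting one dense region dominate.
#'
#' @param A Binary association matrix.
#' @param microbe_feats,disease_feats Feature matrices with one row per
#'   microbe/disease (e.g. the fused similarity rows).
#' @param n Number of negatives.
#' @param n_clusters Number of k-means clusters (capped at the number of
#'   distinct pairs).
#' @param seed Integer seed.
#' @param exclude Optional two-column index matrix of forbidden pairs.
#' @return Two-column integer matrix of (row, col) indices.
#' @export
sample_negatives_kmeans <- function(A, microbe_feats, disease_feats, n,
                                    n_clusters = 10L, seed = 1L,
                                    exclude = NULL) {
  stopifnot(nrow(microbe_feats) == nrow(A), nrow(disease_feats) == ncol(A))
  zeros <- which(A == 0, arr.ind = TRUE)
  zeros <- drop_pairs(zeros, exclude)
  if (n > nrow(zeros)) {
    stop("requested ", n, " negatives but only ", nrow(zeros),
         " unlabeled pairs are available")
  }
  set.seed(seed)
  if (n_clusters <= 1L) {
    sel <- sample.int(nrow(zeros), n)
    return(unname(zeros[sel, , drop = FALSE]))
  }
  feats <- cbind(microbe_feats[zeros[, 1L], , drop = FALSE],
                 disease_feats[zeros[, 2L], , drop = FALSE])
  centers <- min(n_clusters, nrow(unique(feats)))
  cl <- if (centers <= 1L) {
    rep(1L, nrow(zeros))
  } else {
    stats::kmeans(feats, centers = centers, nstart = 3L,
                  iter.max = 50L)$cluster
  }
  sizes <- tabulate(cl, nbins = max(cl))
  clusters <- which(sizes > 0L)
  # proportional quota (never exceeds capacity since n <= total pairs),
  # remainder assigned round-robin to non-empty clusters that still have room
  quota <- floor(n * sizes / sum(sizes))
  i <- 0L
  while (sum(quota) < n) {
    i <- i + 1L
    c_id <- clusters[((i - 1L) %% length(clusters)) + 1L]
    if (quota[c_id] < sizes[c_id]) quota[c_id] <- quota[c_id] + 1L
  }
  picks <- lapply(clusters, function(c_id) {
    members <- which(cl == c_id)
    if (quota[c_id] == 0L) return(integer(0L))
    members[sample.int(length(members), quota[c_id])]
  })
  sel <- sort(unlist(picks))
  unname(zeros[sel, , drop = FALSE])
}

## ---- fit / predict ----------------------------------------------------------

#' Fit the association model
#'
#' Trains all encoder/decoder weights by full-batch gradient descent on the
#' binary cross-entropy over the sampled positive and negative pairs, using
#' Adam with decoupled weight decay. The training association matrix enters
#' the model only through graph construction. All randomness (initialization,
#' negative sampling) is governed by `cfg$seed`.
#'
#' @param A_train Binary association matrix (test positives already removed
#'   for cross-validation use).
#' @param SMpp,SDpp Fused microbe/disease similarity matrices from
#'   [fuse_side()].
#' @param cfg A [default_config()] list.
#' @param positives Optional two-column index matrix of training positives;
#'   defaults to all ones of `A_train`.
#' @param negatives Optional two-column index matrix of training negatives;
#'   defaults to a fresh 1:1 sample under `cfg$neg_strategy`.
#' @param exclude_negatives Pairs the default negative sampler must avoid.
#' @return Object of class `"fuselink_fit"`: trained `params`, `loss_trace`,
#'   the index sets, and the config.
#' @export
fit_model <- function(A_train, SMpp, SDpp, cfg = default_config(),
                      positives = NULL, negatives = NULL,
                      exclude_negatives = NULL) {
  stopifnot(all(A_train %in% c(0, 1)))
  if (is.null(positives)) positives <- which(A_train == 1, arr.ind = TRUE)
  positives <- unname(positives)
  if (is.null(negatives)) {
    n_neg <- nrow(positives)
    negatives <- if (cfg$neg_strategy == "kmeans") {
      sample_negatives_kmeans(A_train, SMpp, SDpp, n_neg,
                              n_clusters = cfg$neg_clusters,
                              seed = cfg$seed, exclude = exclude_negatives)
    } else {
      sample_negatives_random(A_train, n_neg, seed = cfg$seed,
                              exclude = exclude_negatives)
    }
  }
  if (length(intersect(paste(positives[, 1L], positives[, 2L]),
                       paste(negatives[, 1L], negatives[, 2L])))) {
    stop("positive and negative training sets overlap")
  }

  prep <- prepare_model_inputs(A_train, SMpp, SDpp, cfg)
  params <- init_params(nrow(A_train), ncol(A_train), cfg)
  theta <- flatten_params(params)
  decay <- wd_mask(params)
  m <- numeric(length(theta))
  v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss_trace <- numeric(cfg$epochs)

  for (ep in seq_len(cfg$epochs)) {
    params <- unflatten_params(theta, params)
    lg <- model_loss_grad(params, prep, cfg, A_train, positives, negatives)
    if (!is.finite(lg$loss)) {
      stop("non-finite training loss at epoch ", ep)
    }
    loss_trace[ep] <- lg$loss
    g <- flatten_params(lg$grads)
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^ep)
    vhat <- v / (1 - b2^ep)
    theta <- theta - cfg$lr * (mhat / (sqrt(vhat) + eps) + cfg$wd * decay * theta)
  }
  params <- unflatten_params(theta, params)
  structure(list(params = params, cfg = cfg, loss_trace = loss_trace,
                 positives = positives, negatives = negatives),
            class = "fuselink_fit")
}

#' Predict the full score matrix
#'
#' Runs the forward pass with trained parameters and scores every
#' microbe-disease pair. Training associations are used only to build the
#' propagation graph; no score is overwritten with a label.
#'
#' @param model A `"fuselink_fit"` object.
#' @param A_train Association matrix used for graph construction (the same
#'   one passed to [fit_model()]).
#' @param SMpp,SDpp Fused similarity matrices.
#' @return Microbe-by-disease matrix of scores in (0, 1), labeled like
#'   `A_train`.
#' @export
predict_scores <- function(model, A_train, SMpp, SDpp) {
  stopifnot(inherits(model, "fuselink_fit"))
  cfg <- model$cfg
  prep <- prepare_model_inputs(A_train, SMpp, SDpp, cfg)
  fwd <- model_forward(model$params, prep, cfg)
  scores <- if (cfg$ablation == "Dec") {
    sigmoid(fwd$lambda_m %*% t(fwd$lambda_d))
  } else {
    sigmoid(corr_all(fwd$lambda_m, fwd$lambda_d)$Z)
  }
  dimnames(scores) <- dimnames(A_train)
  scores
}

#' @export
print.fuselink_fit <- function(x, ...) {
  cat("fuselink model fit\n")
  cat("  ablation:       ", x$cfg$ablation, "\n")
  cat("  epochs:         ", length(x$loss_trace), "\n")
  if (length(x$loss_trace)) {
    cat("  loss first/last:", signif(x$loss_trace[1L], 6), "/",
        signif(x$loss_trace[length(x$loss_trace)], 6), "\n")
  }
  cat("  training pairs: ", nrow(x$positives), "positive,",
      nrow(x$negatives), "negative\n")
  invisible(x)
}

#' Encode nodes without training
#'
#' Runs the encoder stack (homogeneous GCN, multi-neighborhood layers,
#' jumping knowledge) at the given or freshly initialized parameters and
#' returns the four embedding blocks.
#'
#' @param A Binary association matrix.
#' @param SMpp,SDpp Fused similarity matrices.
#' @param cfg A [default_config()] list.
#' @param params Optional parameter list; defaults to [init_params()] under
#'   `cfg$seed`.
#' @return List with `SM3`, `SD3` (homogeneous embeddings) and `SMtilde`,
#'   `SDtilde` (heterogeneous embeddings; `NULL` under the `Het` ablation).
#' @export
encode <- function(A, SMpp, SDpp, cfg = default_config(), params = NULL) {
  if (is.null(params)) params <- init_params(nrow(A), ncol(A), cfg)
  prep <- prepare_model_inputs(A, SMpp, SDpp, cfg)
  fwd <- model_forward(params, prep, cfg)
  nm <- nrow(A)
  list(
    SM3 = fwd$SM3,
    SD3 = fwd$SD3,
    SMtilde = if (!is.null(fwd$Htilde)) fwd$Htilde[seq_len(nm), , drop = FALSE],
    SDtilde = if (!is.null(fwd$Htilde)) fwd$Htilde[nm + seq_len(ncol(A)), , drop = FALSE]
  )
}
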