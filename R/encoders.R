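#' Degree-normalized propagation operator
#'
#' Builds the propagation operator of a graph convolution from a nonnegative
#' adjacency-like matrix `G`. The default is the standard symmetric
#' normalization `D^{-1/2} G D^{-1/2}` with `D = diag(rowSums(G))`;
#' `literal = TRUE` gives `D^{-1/2} G D^{+1/2}` instead (kept for comparison,
#' see the methods vignette). Zero-degree nodes get an all-zero row/column.
#'
#' @param G Square nonnegative matrix.
#' @param literal Use the `D^{-1/2} G D^{+1/2}` form.
#' @return Propagation matrix of the same dimension.
#' @export
norm_operator <- function(G, literal = FALSE) {
  stopifnot(is.matrix(G), nrow(G) == ncol(G))
  d <- rowSums(G)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  if (literal) {
    pos_sqrt <- sqrt(d)
    out <- inv_sqrt * G * rep(pos_sqrt, each = nrow(G))
  } else {
    out <- inv_sqrt * G * rep(inv_sqrt, each = nrow(G))
  }
  dimnames(out) <- dimnames(G)
  out
}

relu <- function(x) {
  x * (x > 0)
}

#' One-layer homogeneous graph convolution
#'
#' Encodes one entity side from its fused similarity graph: the layer input
#' features are the fused similarity matrix itself, propagated through the
#' degree-normalized operator and linearly mapped to `layer_size` dimensions,
#' followed by a ReLU: `relu(P %*% G %*% W)`.
#'
#' @param G Fused similarity matrix (square, nonnegative, positive row sums).
#' @param W Weight matrix, `nrow(G) x layer_size`.
#' @param activation Elementwise nonlinearity (default ReLU); use `identity`
#'   for linear probes.
#' @param literal_norm Passed to [norm_operator()].
#' @return `nrow(G) x ncol(W)` embedding matrix.
#' @export
gcn_homogeneous <- function(G, W, activation = relu, literal_norm = FALSE) {
  stopifnot(nrow(G) == ncol(G), nrow(W) == nrow(G))
  if (any(rowSums(G) <= 0)) {
    stop("zero-degree node in homogeneous graph; fuse inputs or enable ",
         "uniform_fallback in the config")
  }
  P <- norm_operator(G, literal = literal_norm)
  activation(P %*% G %*% W)
}

#' Build the bipartite heterogeneous graph
#'
#' Stacks microbes over diseases into one node set. The adjacency is the
#' symmetric block matrix `[[0, A], [t(A), 0]]`; the initial features are the
#' vertical stack of the two homogeneous embeddings. When `add_self_loops` is
#' `TRUE` the identity is added before normalization so nodes without any
#' training association still have a defined degree; otherwise their
#' propagation rows are all-zero and only the power-0 term carries their
#' features.
#'
#' @param A Binary microbe-by-disease association matrix.
#' @param SMt Microbe embedding matrix (`nrow(A)` rows).
#' @param SDt Disease embedding matrix (`ncol(A)` rows).
#' @param add_self_loops Add identity before normalization.
#' @param literal_norm Passed to [norm_operator()].
#' @return List with `G` (block adjacency, no self-loops), `P` (propagation
#'   operator) and `H0` (stacked initial features).
#' @export
build_hetero <- function(A, SMt, SDt, add_self_loops = TRUE,
                         literal_norm = FALSE) {
  if (ncol(SMt) != ncol(SDt)) {
    stop("embedding dimension mismatch: ", ncol(SMt), " vs ", ncol(SDt))
  }
  stopifnot(nrow(SMt) == nrow(A), nrow(SDt) == ncol(A))
  nm <- nrow(A); nd <- ncol(A)
  G <- rbind(cbind(matrix(0, nm, nm), A),
             cbind(t(A), matrix(0, nd, nd)))
  Gn <- if (add_self_loops) G + diag(nm + nd) else G
  P <- norm_operator(Gn, literal = literal_norm)
  H0 <- rbind(SMt, SDt)
  list(G = G, P = P, H0 = H0)
}

#' Column widths of the multi-neighborhood blocks
#'
#' The layer output concatenates `k_max + 1` propagation blocks while keeping
#' the total width at `layer_size`: each block gets
#' `floor(layer_size / (k_max + 1))` columns and the power-0 block absorbs the
#' remainder.
#'
#' @param layer_size Total output dimension.
#' @param k_max Highest propagation power.
#' @return Integer vector of `k_max + 1` block widths summing to `layer_size`.
#' @export
block_widths <- function(layer_size, k_max) {
  nb <- k_max + 1L
  if (layer_size < nb) stop("layer_size must be >= number of blocks (", nb, ")")
  base <- layer_size %/% nb
  w <- rep(base, nb)
  w[1L] <- w[1L] + layer_size - base * nb
  w
}

#' Multi-neighborhood graph convolution layer
#'
#' Concatenates, over powers `i = 0..k_max` of the propagation operator, the
#' blocks `P^i %*% H %*% W_i` (with `P^0 = I`), then applies the activation.
#' Mixing neighborhood orders in one layer lets each node see its 0th- to
#' k-th-order neighborhood simultaneously.
#'
#' @param P Propagation operator from [build_hetero()].
#' @param H Input features.
#' @param weights List of `k_max + 1` weight matrices, one per power; block
#'   `i` must have `ncol(H)` rows.
#' @param k_max Highest power.
#' @param activation Elementwise nonlinearity (default ReLU).
#' @return Feature matrix whose width is the sum of the block widths.
#' @export
multi_neighborhood_layer <- function(P, H, weights, k_max, activation = relu) {
  if (length(weights) != k_max + 1L) {
    stop("need ", k_max + 1L, " weight blocks, got ", length(weights))
  }
  Q <- H
  blocks <- vector("list", k_max + 1L)
  for (i in 0:k_max) {
    if (i > 0L) Q <- P %*% Q
    W <- weights[[i + 1L]]
    if (nrow(W) != ncol(H)) {
      stop("weight block ", i, " has ", nrow(W), " rows; expected ", ncol(H))
    }
    blocks[[i + 1L]] <- Q %*% W
  }
  activation(do.call(cbind, blocks))
}

#' Jumping-knowledge aggregation
#'
#' Weighted sum of per-layer representations: `H_tilde = sum_i omega_i H^(i)`.
#'
#' @param layers List of feature matrices of identical shape.
#' @param omegas Numeric weight vector, one per layer.
#' @return Aggregated feature matrix.
#' @export
jk_aggregate <- function(layers, omegas) {
  if (length(layers) != length(omegas)) {
    stop("length(omegas) must equal the number of layers")
  }
  dims <- vapply(layers, function(x) paste(dim(x), collapse = "x"), character(1L))
  if (length(unique(dims)) != 1L) stop("layer shapes disagree: ",
                                       paste(unique(dims), collapse = " vs "))
  out <- omegas[[1L]] * layers[[1L]]
  for (i in seq_along(layers)[-1L]) out <- out + omegas[[i]] * layers[[i]]
  out
}

#' Glorot-uniform parameter initialization
#'
#' Initializes all trainable weights of the encoder stack for given problem
#' dimensions under the run seed: one homogeneous weight matrix per side, one
#' weight block per power and per heterogeneous layer, and the
#' jumping-knowledge coefficients (uniform `1/l`).
#'
#' @param n_microbes,n_diseases Entity counts.
#' @param cfg A [default_config()] list.
#' @return List with elements `Wm`, `Wd`, `Whet` (list of layers, each a list
#'   of blocks) and `omega`.
#' @export
init_params <- function(n_microbes, n_diseases, cfg = default_config()) {
  set.seed(cfg$seed)
  glorot <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
  }
  L <- cfg$layer_size
  params <- list(
    Wm = glorot(n_microbes, L),
    Wd = glorot(n_diseases, L)
  )
  if (cfg$ablation != "Het") {
    widths <- block_widths(L, cfg$k_neighborhood)
    params$Whet <- lapply(seq_len(cfg$n_hetero_layers), function(l) {
      lapply(widths, function(w) glorot(L, w))
    })
    params$omega <- rep(1 / cfg$n_hetero_layers, cfg$n_hetero_layers)
  }
  params
}

#' Prepare fixed model inputs
#'
#' Precomputes the quantities the forward/backward passes reuse every epoch:
#' the homogeneous propagation products and the heterogeneous propagation
#' operator. The training associations enter only through the graph here.
#'
#' @param A Binary association matrix used for graph construction.
#' @param SMpp,SDpp Fused similarity matrices from [fuse_side()].
#' @param cfg A [default_config()] list.
#' @return List consumed by [model_forward()].
#' @keywords internal
prepare_model_inputs <- function(A, SMpp, SDpp, cfg) {
  if (cfg$ablation == "Hom") {
    # dense feature map: no propagation on the homogeneous side
    PXm <- SMpp
    PXd <- SDpp
  } else {
    if (any(rowSums(SMpp) <= 0) || any(rowSums(SDpp) <= 0)) {
      stop("zero-degree node in a fused similarity graph")
    }
    PXm <- norm_operator(SMpp, literal = cfg$literal_norm) %*% SMpp
    PXd <- norm_operator(SDpp, literal = cfg$literal_norm) %*% SDpp
  }
  out <- list(PXm = PXm, PXd = PXd, nm = nrow(A), nd = ncol(A),
              microbe_ids = rownames(A), disease_ids = colnames(A))
  if (cfg$ablation != "Het") {
    nm <- nrow(A); nd <- ncol(A)
    G <- rbind(cbind(matrix(0, nm, nm), A),
               cbind(t(A), matrix(0, nd, nd)))
    Gn <- if (cfg$add_self_loops) G + diag(nm + nd) else G
    out$P <- norm_operator(Gn, literal = cfg$literal_norm)
  }
  out
}

#' Forward pass of the encoder-decoder stack
#'
#' Runs the homogeneous convolutions, the heterogeneous multi-neighborhood
#' layers, jumping-knowledge aggregation and pair-feature assembly, keeping
#' the intermediates needed by the analytic backward pass.
#'
#' @param params Parameter list from [init_params()].
#' @param prep Precomputed inputs from [prepare_model_inputs()].
#' @param cfg A [default_config()] list.
#' @return List with embeddings (`SM3`, `SD3`, `Htilde`), pair features
#'   (`lambda_m`, `lambda_d`) and cached intermediates.
#' @keywords internal
model_forward <- function(params, prep, cfg) {
  pre_m <- prep$PXm %*% params$Wm
  pre_d <- prep$PXd %*% params$Wd
  SM3 <- relu(pre_m)
  SD3 <- relu(pre_d)
  out <- list(SM3 = SM3, SD3 = SD3, pre_m = pre_m, pre_d = pre_d)
  if (cfg$ablation == "Het") {
    out$lambda_m <- SM3
    out$lambda_d <- SD3
    return(out)
  }
  k <- cfg$k_neighborhood
  H <- rbind(SM3, SD3)
  layers <- vector("list", cfg$n_hetero_layers)
  caches <- vector("list", cfg$n_hetero_layers)
  for (l in seq_len(cfg$n_hetero_layers)) {
    Qs <- vector("list", k + 1L)
    Qs[[1L]] <- H
    for (i in seq_len(k)) Qs[[i + 1L]] <- prep$P %*% Qs[[i]]
    pre <- do.call(cbind, lapply(0:k, function(i) {
      Qs[[i + 1L]] %*% params$Whet[[l]][[i + 1L]]
    }))
    Hl <- relu(pre)
    layers[[l]] <- Hl
    caches[[l]] <- list(Qs = Qs, pre = pre)
    H <- Hl
  }
  omega <- if (cfg$jk_mode == "fixed") {
    rep(1 / cfg$n_hetero_layers, cfg$n_hetero_layers)
  } else {
    params$omega
  }
  Htilde <- if (cfg$ablation == "JK") {
    layers[[cfg$n_hetero_layers]]
  } else {
    jk_aggregate(layers, omega)
  }
  out$layers <- layers
  out$caches <- caches
  out$Htilde <- Htilde
  out$lambda_m <- cbind(SM3, Htilde[seq_len(prep$nm), , drop = FALSE])
  out$lambda_d <- cbind(SD3, Htilde[prep$nm + seq_len(prep$nd), , drop = FALSE])
  out
}
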