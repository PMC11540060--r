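test_that("the normalized operator matches the hand-built symmetric form", {
  # 3-node path graph
  G <- matrix(c(0, 1, 0,
                1, 0, 1,
                0, 1, 0), 3, 3)
  P <- norm_operator(G)
  d <- rowSums(G)
  expect_equal(P, diag(1 / sqrt(d)) %*% G %*% diag(1 / sqrt(d)))
  # literal variant uses D^{-1/2} G D^{+1/2}
  Pl <- norm_operator(G, literal = TRUE)
  expect_equal(Pl, diag(1 / sqrt(d)) %*% G %*% diag(sqrt(d)))
  # zero-degree nodes yield all-zero rows, no NaN
  G0 <- rbind(cbind(G, 0), 0)
  expect_true(all(is.finite(norm_operator(G0))))
  expect_equal(norm_operator(G0)[4, ], rep(0, 4))
})

test_that("one homogeneous GCN layer equals the explicit propagation product", {
  G <- matrix(c(0, 1, 0,
                1, 0, 1,
                0, 1, 0), 3, 3) + diag(3)
  W <- diag(3)
  out <- gcn_homogeneous(G, W, activation = identity)
  d <- rowSums(G)
  expect_equal(out,
               diag(1 / sqrt(d)) %*% G %*% diag(1 / sqrt(d)) %*% G %*% W)

  # nodes with identical graph rows get identical embeddings
  S <- matrix(0.4, 4, 4); diag(S) <- 1
  S[1, ] <- S[2, ] <- c(1, 1, 0.2, 0.2); S[, 1] <- S[, 2] <- c(1, 1, 0.2, 0.2)
  set.seed(1)
  W2 <- matrix(rnorm(4 * 3), 4, 3)
  # make the weight rows of the twin nodes identical so features match too
  W2[2, ] <- W2[1, ]
  emb <- gcn_homogeneous(S, W2)
  expect_equal(emb[1, ], emb[2, ])

  expect_error(gcn_homogeneous(matrix(0, 2, 2), matrix(1, 2, 2)), "zero-degree")
})

test_that("propagation powers match an explicit neighbor-sum oracle on small graphs", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(3:8, 1)
    G <- matrix(rbinom(n * n, 1, 0.4), n, n)
    G <- 1 * ((G + t(G)) > 0)
    diag(G) <- 0
    G <- G + diag(n)  # self-loops so all degrees are positive
    P <- norm_operator(G)
    H <- matrix(rnorm(n * 3), n, 3)
    d <- rowSums(G)
    oracle_step <- function(X) {
      # explicit neighbor sum: row i accumulates G[i,j] X[j,] / sqrt(d_i d_j)
      out <- matrix(0, n, ncol(X))
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (G[i, j] != 0) out[i, ] <- out[i, ] + X[j, ] / sqrt(d[i] * d[j])
      }
      out
    }
    X <- H
    Pi <- diag(n)
    for (i in 1:4) {
      X <- oracle_step(X)
      Pi <- P %*% Pi
      expect_lt(max(abs(Pi %*% H - X)), 1e-10)
    }
  }
})

test_that("the bipartite block graph has the required structure", {
  A1 <- matrix(1, 1, 1)
  hg <- build_hetero(A1, matrix(1, 1, 2), matrix(1, 1, 2))
  expect_equal(hg$G, matrix(c(0, 1, 1, 0), 2, 2))

  set.seed(3)
  A <- matrix(rbinom(6, 1, 0.5), 2, 3)
  hg <- build_hetero(A, matrix(rnorm(2 * 4), 2, 4), matrix(rnorm(3 * 4), 3, 4))
  expect_equal(dim(hg$G), c(5L, 5L))
  expect_equal(hg$G, t(hg$G))
  expect_true(all(hg$G[1:2, 1:2] == 0))
  expect_true(all(hg$G[3:5, 3:5] == 0))
  expect_equal(hg$G[1:2, 3:5], A, ignore_attr = TRUE)
  expect_equal(nrow(hg$H0), 5L)

  expect_error(build_hetero(A, matrix(0, 2, 4), matrix(0, 3, 5)), "mismatch")
})

test_that("with no associations and no self-loops only the power-0 term survives", {
  A <- matrix(0, 3, 2)
  SMt <- matrix(rnorm(3 * 4), 3, 4)
  SDt <- matrix(rnorm(2 * 4), 2, 4)
  hg <- build_hetero(A, SMt, SDt, add_self_loops = FALSE)
  expect_true(all(hg$P == 0))
  widths <- block_widths(4, 2)
  set.seed(8)
  weights <- lapply(widths, function(w) matrix(rnorm(4 * w), 4, w))
  out <- multi_neighborhood_layer(hg$P, hg$H0, weights, k_max = 2,
                                  activation = identity)
  expect_equal(out[, 1:widths[1]], hg$H0 %*% weights[[1]])
  expect_true(all(out[, -(1:widths[1])] == 0))
})

test_that("multi-neighborhood blocks equal explicit repeated propagation", {
  set.seed(21)
  A <- matrix(rbinom(5 * 3, 1, 0.5), 5, 3)
  H <- matrix(rnorm(8 * 6), 8, 6)
  hg <- build_hetero(A, H[1:5, ], H[6:8, ])
  widths <- block_widths(6, 2)
  weights <- lapply(widths, function(w) matrix(rnorm(6 * w), 6, w))
  out <- multi_neighborhood_layer(hg$P, H, weights, k_max = 2,
                                  activation = identity)
  ends <- cumsum(widths); starts <- ends - widths + 1
  Q <- H
  for (i in 0:2) {
    if (i > 0) Q <- hg$P %*% Q
    expect_equal(out[, starts[i + 1]:ends[i + 1], drop = FALSE],
                 Q %*% weights[[i + 1]])
  }

  # k_max = 0: no propagation at all
  W0 <- matrix(rnorm(6 * 6), 6, 6)
  out0 <- multi_neighborhood_layer(hg$P, H, list(W0), k_max = 0,
                                   activation = identity)
  expect_equal(out0, H %*% W0)

  expect_error(multi_neighborhood_layer(hg$P, H, weights[1:2], k_max = 2),
               "weight blocks")
})

test_that("block widths sum to layer_size with the remainder on the power-0 block", {
  expect_equal(block_widths(128, 4), c(28, 25, 25, 25, 25))
  expect_equal(sum(block_widths(128, 4)), 128)
  expect_equal(block_widths(6, 2), c(2, 2, 2))
  expect_equal(block_widths(7, 2), c(3, 2, 2))
  expect_error(block_widths(2, 4), "layer_size")
})

test_that("jumping-knowledge aggregation is the weighted layer sum", {
  H1 <- matrix(1:6, 2, 3)
  H2 <- matrix(6:1, 2, 3)
  expect_equal(jk_aggregate(list(H1), 1), H1)
  expect_equal(jk_aggregate(list(H1, H1), c(0.5, 0.5)), H1)
  expect_equal(jk_aggregate(list(H1, H2), c(1, 0)), H1)
  expect_equal(jk_aggregate(list(H1, H2), c(0.3, 0.7)), 0.3 * H1 + 0.7 * H2)
  expect_error(jk_aggregate(list(H1, H2), 1), "omegas")
  expect_error(jk_aggregate(list(H1, matrix(0, 3, 3)), c(1, 1)), "shapes")
})

test_that("encoding is permutation-equivariant with matched weights", {
  sp <- small_problem()
  cfg <- sp$cfg
  params <- init_params(nrow(sp$data$A), ncol(sp$data$A), cfg)
  enc <- encode(sp$data$A, sp$SMpp, sp$SDpp, cfg, params = params)

  set.seed(99)
  pm <- sample(nrow(sp$data$A))
  params_p <- params
  params_p$Wm <- params$Wm[pm, , drop = FALSE]
  enc_p <- encode(sp$data$A[pm, ], sp$SMpp[pm, pm], sp$SDpp, cfg,
                  params = params_p)
  expect_equal(enc_p$SM3, enc$SM3[pm, ], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(enc_p$SMtilde, enc$SMtilde[pm, ], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(enc_p$SDtilde, enc$SDtilde, tolerance = 1e-10)
})

test_that("embeddings stay finite across the tuning grid", {
  sp <- small_problem()
  for (alpha in c(0.1, 0.4)) {
    for (k in c(2L, 6L)) {
      for (n in c(1L, 4L)) {
        cfg <- default_config(alpha = alpha, k_neighborhood = k,
                              n_hetero_layers = n, layer_size = 32L,
                              seed = 5L)
        enc <- encode(sp$data$A, sp$SMpp, sp$SDpp, cfg)
        expect_true(all(is.finite(enc$SM3)))
        expect_true(all(is.finite(enc$SMtilde)))
        expect_true(all(is.finite(enc$SDtilde)))
      }
    }
  }
})

test_that("analytic gradients match central finite differences in every variant", {
  set.seed(42)
  nm <- 6L; nd <- 4L
  A <- matrix(rbinom(nm * nd, 1, 0.3), nm, nd)
  SMpp <- random_similarity(nm, 1)
  SDpp <- random_similarity(nd, 2)
  pos <- which(A == 1, arr.ind = TRUE)
  neg <- which(A == 0, arr.ind = TRUE)[1:3, , drop = FALSE]
  for (abl in c("full", "Hom", "Het", "JK", "Dec")) {
    cfg <- default_config(layer_size = 8L, k_neighborhood = 2L,
                          n_hetero_layers = 2L, seed = 3L, ablation = abl)
    prep <- fuselink:::prepare_model_inputs(A, SMpp, SDpp, cfg)
    params <- init_params(nm, nd, cfg)
    lg <- fuselink:::model_loss_grad(params, prep, cfg, A, pos, neg)
    theta <- fuselink:::flatten_params(params)
    g <- fuselink:::flatten_params(lg$grads)
    lossf <- function(t) {
      p <- fuselink:::unflatten_params(t, params)
      fuselink:::model_loss_grad(p, prep, cfg, A, pos, neg)$loss
    }
    set.seed(abl == "full")
    idx <- sample(length(theta), 12)
    num <- vapply(idx, function(i) {
      e <- 1e-5
      tp <- theta; tp[i] <- tp[i] + e
      tm <- theta; tm[i] <- tm[i] - e
      (lossf(tp) - lossf(tm)) / (2 * e)
    }, numeric(1))
    expect_lt(max(abs(num - g[idx])), 1e-6)
  }
})
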