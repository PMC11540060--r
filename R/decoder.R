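sigmoid <- function(x) 1 / (1 + exp(-x))

#' Assemble pair features
#'
#' The feature vector of each entity is the concatenation of its homogeneous
#' embedding row and its heterogeneous (jumping-knowledge) embedding row.
#' When the heterogeneous stage is ablated (`Het`), the homogeneous embedding
#' alone is used.
#'
#' @param SM3,SD3 Homogeneous embeddings (microbes, diseases).
#' @param SMtilde,SDtilde Heterogeneous embeddings, or `NULL` under the `Het`
#'   ablation.
#' @return List with `lambda_m` and `lambda_d` feature matrices.
#' @export
pair_features <- function(SM3, SMtilde, SD3, SDtilde) {
  if (is.null(SMtilde) != is.null(SDtilde)) {
    stop("heterogeneous embeddings must be supplied for both sides or neither")
  }
  if (is.null(SMtilde)) {
    return(list(lambda_m = SM3, lambda_d = SD3))
  }
  if (nrow(SMtilde) != nrow(SM3) || nrow(SDtilde) != nrow(SD3)) {
    stop("row-count mismatch between homogeneous and heterogeneous embeddings")
  }
  list(lambda_m = cbind(SM3, SMtilde), lambda_d = cbind(SD3, SDtilde))
}

#' Pearson correlation of two feature vectors
#'
#' Centered cosine similarity. A vector with zero variance yields a defined
#' correlation of 0 (score 0.5 after the sigmoid) with a warning, so early
#' training epochs with dead ReLU rows cannot produce NaN.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return Correlation in `[-1, 1]`.
#' @export
correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  xc <- x - mean(x)
  yc <- y - mean(y)
  nx <- sqrt(sum(xc^2))
  ny <- sqrt(sum(yc^2))
  if (nx == 0 || ny == 0) {
    warning("zero-variance feature vector; correlation defined as 0")
    return(0)
  }
  sum(xc * yc) / (nx * ny)
}

#' All-pairs correlation with backward cache
#'
#' Rows of `Xm` against rows of `Xd`; zero-variance rows get correlation 0.
#'
#' @keywords internal
corr_all <- function(Xm, Xd, eps = 1e-12) {
  cm <- Xm - rowMeans(Xm)
  cd <- Xd - rowMeans(Xd)
  nm <- sqrt(rowSums(cm^2))
  nd <- sqrt(rowSums(cd^2))
  inm <- ifelse(nm > eps, 1 / nm, 0)
  ind <- ifelse(nd > eps, 1 / nd, 0)
  hm <- cm * inm
  hd <- cd * ind
  list(Z = hm %*% t(hd), hm = hm, hd = hd, inm = inm, ind = ind)
}

#' Reconstruct the score matrix
#'
#' `scores[i, j] = sigmoid(correlation(lambda_m[i, ], lambda_d[j, ]))`.
#' Because correlations lie in `[-1, 1]`, all scores lie in
#' `(sigmoid(-1), sigmoid(1)) ~ (0.269, 0.731)`.
#'
#' @param lambda_m,lambda_d Pair-feature matrices from [pair_features()].
#' @return Microbe-by-disease score matrix.
#' @export
reconstruct <- function(lambda_m, lambda_d) {
  stopifnot(nrow(lambda_m) >= 1L, nrow(lambda_d) >= 1L,
            ncol(lambda_m) == ncol(lambda_d))
  cc <- corr_all(lambda_m, lambda_d)
  out <- sigmoid(cc$Z)
  rownames(out) <- rownames(lambda_m)
  colnames(out) <- rownames(lambda_d)
  out
}

#' Binary cross-entropy over sampled pairs
#'
#' Summed (not averaged, unless `reduction = "mean"`) negative log-likelihood
#' over the union of the positive and negative index sets:
#' `-sum A_ij log(scores_ij) + (1 - A_ij) log(1 - scores_ij)`.
#' Scores are clipped into `[1e-7, 1 - 1e-7]` before the logs as a numerical
#' safeguard (the sigmoid-correlation decoder cannot actually reach 0 or 1).
#'
#' @param A Binary association matrix (labels).
#' @param scores Score matrix of the same shape.
#' @param positives,negatives Two-column index matrices (row, col) of the
#'   sampled positive and negative pairs; must be disjoint.
#' @param reduction `"sum"` (default) or `"mean"`.
#' @return Nonnegative scalar loss (0 for an empty sample).
#' @export
bce_loss <- function(A, scores, positives, negatives, reduction = "sum") {
  reduction <- match.arg(reduction, c("sum", "mean"))
  idx <- rbind(positives, negatives)
  if (is.null(idx) || nrow(idx) == 0L) return(0)
  if (max(idx[, 1L]) > nrow(A) || max(idx[, 2L]) > ncol(A) || min(idx) < 1L) {
    stop("pair index outside the matrix")
  }
  key <- function(m) paste(m[, 1L], m[, 2L])
  if (!is.null(positives) && !is.null(negatives) &&
      nrow(positives) > 0L && nrow(negatives) > 0L &&
      length(intersect(key(positives), key(negatives))) > 0L) {
    stop("positive and negative sets overlap")
  }
  a <- A[idx]
  p <- pmin(pmax(scores[idx], 1e-7), 1 - 1e-7)
  l <- -sum(a * log(p) + (1 - a) * log(1 - p))
  if (reduction == "mean") l <- l / nrow(idx)
  l
}
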