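#' Read a labeled matrix from CSV/TSV
#'
#' Reads a numeric matrix whose first row holds column identifiers and whose
#' first column holds row identifiers. The delimiter is chosen from the file
#' extension: `.csv` is comma-separated, `.tsv` (or `.txt`) tab-separated.
#'
#' Square matrices intended as similarities can be validated on read:
#' symmetry within `1e-8` and, optionally, all values inside `[0, 1]`.
#' Association matrices are validated to contain only 0/1 entries.
#'
#' @param path Path to the file.
#' @param expect_square If `TRUE`, require a square matrix with identical
#'   row and column identifiers and symmetric values (tolerance `1e-8`).
#' @param range_check If `TRUE` (with `expect_square`), require every value
#'   in `[0, 1]`; used for raw input similarities.
#' @param binary If `TRUE`, require every value in `{0, 1}` (association
#'   matrices).
#' @return A numeric matrix with `dimnames` carrying the identifiers.
#' @export
read_matrix <- function(path, expect_square = FALSE, range_check = expect_square,
                        binary = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA, comment.char = "")
  if (ncol(df) < 2L) stop("matrix file must have an ID column plus data: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate row IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- df[, -1L, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1L))
  if (any(bad)) {
    stop("non-numeric cells in ", path, " (columns: ",
         paste(names(vals)[bad], collapse = ", "), ")")
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) {
    stop("duplicate column IDs in ", path)
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("missing value in ", path, " at row '", rownames(m)[idx[1L]],
         "', column '", colnames(m)[idx[2L]], "'")
  }
  if (expect_square) {
    if (nrow(m) != ncol(m)) {
      stop("expected a square matrix in ", path, " but got ",
           nrow(m), "x", ncol(m))
    }
    asym <- abs(m - t(m))
    if (max(asym) > 1e-8) {
      idx <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
      stop("matrix in ", path, " is asymmetric beyond 1e-8 at ('",
           rownames(m)[idx[1L]], "', '", colnames(m)[idx[2L]], "')")
    }
    if (range_check && (min(m) < 0 || max(m) > 1)) {
      idx <- which(m < 0 | m > 1, arr.ind = TRUE)[1L, ]
      stop("similarity value outside [0,1] in ", path, " at ('",
           rownames(m)[idx[1L]], "', '", colnames(m)[idx[2L]], "'): ",
           m[idx[1L], idx[2L]])
    }
  }
  if (binary && !all(m %in% c(0, 1))) {
    idx <- which(!(m %in% c(0, 1)))[1L]
    stop("association matrix in ", path, " has non-binary entry ", m[idx])
  }
  m
}

#' Write a labeled matrix to CSV/TSV
#'
#' Inverse of [read_matrix()]: values round-trip within `1e-12`.
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path; extension selects the delimiter as in
#'   [read_matrix()].
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a score matrix
#'
#' Validates that all scores are finite and strictly inside (0, 1) before
#' delegating to [write_matrix()].
#'
#' @param scores Numeric microbe-by-disease matrix of predicted probabilities.
#' @param path Output path.
#' @export
write_scores <- function(scores, path) {
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (min(scores) <= 0 || max(scores) >= 1) {
    stop("scores must lie strictly inside (0, 1)")
  }
  write_matrix(scores, path)
}

#' Default run configuration
#'
#' Returns the full hyperparameter set with defaults matching the reference
#' configuration: fusion weight `alpha = 0.28`, embedding dimension
#' `layer_size = 128`, `n_hetero_layers = 2` multi-neighbourhood layers over
#' powers `0..k_neighborhood` with `k_neighborhood = 4`, learning rate
#' `1e-3`, weight decay `1e-5` and 2000 training epochs.
#'
#' @param ... Named overrides for any field.
#' @return A validated list of class `"run_config"`.
#' @export
default_config <- function(...) {
  cfg <- list(
    alpha           = 0.28,
    layer_size      = 128L,
    n_hetero_layers = 2L,
    k_neighborhood  = 4L,
    lr              = 1e-3,
    wd              = 1e-5,
    epochs          = 2000L,
    seed            = 1L,
    knn_divisor     = 10L,
    fusion_tol      = 1e-6,
    fusion_max_iter = 1000L,
    neg_strategy    = "random",   # or "kmeans"
    neg_clusters    = 10L,
    ablation        = "full",     # full | SF | Hom | Het | JK | Dec
    threshold       = 0.5,
    jk_mode         = "learnable",  # or "fixed" (uniform 1/l, untrained)
    literal_norm    = FALSE,      # D^{-1/2} G D^{+1/2} as printed, for comparison
    add_self_loops  = TRUE,       # identity added to the bipartite block graph
    renormalize_views = FALSE,    # row-renormalize views between diffusion steps
    loss_reduction  = "sum",      # or "mean"
    uniform_fallback = FALSE      # isolated rows in normalize_full -> uniform row
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
}

#' @keywords internal
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!is.numeric(cfg$alpha) || cfg$alpha < 0 || cfg$alpha > 1) {
    stop("alpha must lie in [0, 1], got ", cfg$alpha)
  }
  int_fields <- c("layer_size", "n_hetero_layers", "knn_divisor",
                  "fusion_max_iter", "neg_clusters")
  for (f in int_fields) {
    cfg[[f]] <- as.integer(cfg[[f]])
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) stop(f, " must be a positive integer")
  }
  cfg$epochs <- as.integer(cfg$epochs)
  if (is.na(cfg$epochs) || cfg$epochs < 0L) {
    stop("epochs must be a nonnegative integer")
  }
  cfg$k_neighborhood <- as.integer(cfg$k_neighborhood)
  if (is.na(cfg$k_neighborhood) || cfg$k_neighborhood < 0L) {
    stop("k_neighborhood must be a nonnegative integer")
  }
  cfg$seed <- as.integer(cfg$seed)
  if (cfg$fusion_tol <= 0) stop("fusion_tol must be > 0")
  if (cfg$lr <= 0) stop("lr must be > 0")
  if (cfg$wd < 0) stop("wd must be >= 0")
  if (cfg$threshold <= 0 || cfg$threshold >= 1) stop("threshold must be in (0, 1)")
  cfg$neg_strategy <- match.arg(cfg$neg_strategy, c("random", "kmeans"))
  cfg$ablation <- match.arg(cfg$ablation, c("full", "SF", "Hom", "Het", "JK", "Dec"))
  cfg$jk_mode <- match.arg(cfg$jk_mode, c("learnable", "fixed"))
  cfg$loss_reduction <- match.arg(cfg$loss_reduction, c("sum", "mean"))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Flat key-value YAML; unspecified fields take the defaults of
#' [default_config()].
#'
#' @param path Path to the YAML file.
#' @return A validated `run_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(default_config, vals)
}

#' @keywords internal
log_msg <- function(level, ...) {
  message(sprintf("[%s] %s", level, paste0(...)))
}
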