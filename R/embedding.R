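#' Normalize binned read counts
#'
#' Library-size normalization followed by a variance-stabilizing log
#' transform: each cell's bin counts are scaled to the median library size
#' (median of per-cell totals) and then transformed as `log2(x + 1)`. The
#' result is scale-invariant per cell, so two cells whose profiles differ
#' only by sequencing depth become identical.
#'
#' @param R n x b nonnegative matrix of binned read counts.
#' @return n x b matrix of normalized, log-transformed counts.
#' @export
normalize_bins <- function(R) {
  R <- as.matrix(R)
  if (any(!is.finite(R)) || any(R < 0)) stop("R must be finite and nonnegative")
  tot <- base::rowSums(R)
  if (any(tot == 0)) {
    bad <- rownames(R)[which(tot == 0)[1]] %||% as.character(which(tot == 0)[1])
    stop("all-zero bin counts for cell ", bad)
  }
  target <- stats::median(tot)
  log2(R * (target / tot) + 1)
}

#' Embed cells into a low-dimensional copy-number space
#'
#' Projects normalized binned read counts onto their first `ndim` principal
#' axes (mean-centered, unscaled), yielding the embedding used as the
#' copy-number proxy throughout inference. The linear projection is the best
#' rank-`ndim` approximation of the centered data in Frobenius norm, so
#' pairwise distances in the embedding reflect copy-number profile
#' similarity. Component signs are fixed deterministically (the loading of
#' largest magnitude is made positive), making the output identical across
#' runs regardless of `seed`; the seed is consumed only by stochastic
#' embedding methods, of which none are currently provided.
#'
#' @param Rnorm n x b matrix of normalized bin counts (see [normalize_bins()]).
#' @param ndim embedding dimension, `2 <= ndim < b`; default 10.
#' @param seed integer seed, kept for interface stability.
#' @param method embedding method; only `"pca"` (principal axes).
#' @return n x ndim matrix with rownames carried over; attribute `"sdev"`
#'   holds the singular values per retained axis.
#' @export
embed_cells <- function(Rnorm, ndim = 10, seed = 1L, method = "pca") {
  method <- match.arg(method)
  Rnorm <- as.matrix(Rnorm)
  b <- ncol(Rnorm)
  if (ndim >= b) stop("embedding dimension must be smaller than the number of bins")
  if (ndim < 2) stop("embedding dimension must be at least 2")
  ndim <- min(ndim, nrow(Rnorm))
  ctr <- base::scale(Rnorm, center = TRUE, scale = FALSE)
  sv <- svd(ctr, nu = ndim, nv = ndim)
  # deterministic sign: largest-|loading| entry of each axis is positive
  for (j in seq_len(ndim)) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) {
      sv$v[, j] <- -v
      sv$u[, j] <- -sv$u[, j]
    }
  }
  E <- sv$u[, seq_len(ndim), drop = FALSE] %*% diag(sv$d[seq_len(ndim)], ndim)
  rownames(E) <- rownames(Rnorm)
  colnames(E) <- paste0("dim", seq_len(ndim))
  attr(E, "sdev") <- sv$d[seq_len(ndim)]
  E
}

#' Compute the default embedding of a read-count object
#'
#' Convenience wrapper: normalizes `data$R` and embeds it. A precomputed
#' embedding can be passed through untouched.
#'
#' @param data a [read_count_data] with binned counts `R`, or `NULL` when
#'   `embedding` is supplied.
#' @param embedding optional precomputed n x l matrix, used verbatim.
#' @param ndim,seed passed to [embed_cells()].
#' @return n x l numeric matrix.
#' @export
cell_embedding <- function(data, embedding = NULL, ndim = 10, seed = 1L) {
  if (!is.null(embedding)) {
    E <- as.matrix(embedding)
    if (!is.null(data) && nrow(E) != length(data$cell_ids))
      stop("embedding must have one row per cell")
    return(E)
  }
  if (is.null(data$R)) stop("no binned counts and no precomputed embedding")
  embed_cells(normalize_bins(data$R), ndim = min(ndim, ncol(data$R) - 1),
              seed = seed)
}
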