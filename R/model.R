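#' Model hyperparameters
#'
#' Collects the hyperparameters of the probabilistic model and its solver.
#' Defaults are the values used for all benchmark runs.
#'
#' @param alpha per-base sequencing error probability, in (0, 1).
#' @param max_copies maximum total number of chromosomal copies `c >= 2` at
#'   any locus; controls the allele-specific copy-number states marginalized
#'   over in the genotype-1 read likelihood.
#' @param threshold detectability threshold `t >= 1`: minimum mean number of
#'   clone cells covering each newly introduced SNV for a clone to be
#'   accepted.
#' @param qc quality-check upper bound in (0, 1) on the median cell
#'   mutational burden of cells outside a new clade.
#' @param restarts number of seeded restarts per elementary tree operation.
#' @param max_iter maximum coordinate-descent iterations per restart.
#' @param min_clone_size minimum number of cells per inferred clone;
#'   `NULL` means `max(10, ceiling(0.01 * n))`, resolved at run time.
#' @param max_candidates cap on the number of candidate trees enumerated
#'   during growth; a deterministic resource bound on instances whose
#'   filters accept many alternative extensions.
#' @param embed_dim dimension of the copy-number embedding.
#' @param seed base integer seed for all randomized steps.
#' @return an object of class `model_params`.
#' @export
model_params <- function(alpha = 0.001, max_copies = 5, threshold = 5,
                         qc = 0.025, restarts = 15, max_iter = 50,
                         min_clone_size = NULL, max_candidates = 64,
                         embed_dim = 10, seed = 1L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  if (max_copies < 2) stop("max_copies must be at least 2")
  if (threshold < 1) stop("threshold must be at least 1")
  if (qc <= 0 || qc >= 1) stop("qc must lie strictly in (0, 1)")
  if (restarts < 1 || max_iter < 1) stop("restarts and max_iter must be >= 1")
  structure(list(alpha = alpha, max_copies = as.integer(max_copies),
                 threshold = threshold, qc = qc,
                 restarts = as.integer(restarts),
                 max_iter = as.integer(max_iter),
                 min_clone_size = min_clone_size,
                 max_candidates = as.integer(max_candidates),
                 embed_dim = as.integer(embed_dim), seed = as.integer(seed)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Allele-specific copy-number states
#'
#' The genotype-1 read likelihood marginalizes the unobserved variant allele
#' copy state over all pairs (variant copies `x`, total copies `y`) with
#' `1 <= y <= c` and `1 <= x <= y`, under a uniform prior within the class.
#' Genotype-0 entries have `x = 0` and emit variant reads only through
#' sequencing error.
#'
#' @param max_copies maximum total copies `c`.
#' @param alpha sequencing error probability used to error-adjust the VAF.
#' @return tibble with columns `x`, `y`, `vaf` (`x/y`), `vaf_adj`
#'   (error-adjusted VAF) and `prior` (uniform, sums to 1).
#' @export
copy_state_set <- function(max_copies, alpha) {
  y <- rep(seq_len(max_copies), times = seq_len(max_copies))
  x <- unlist(lapply(seq_len(max_copies), seq_len))
  vaf <- x / y
  tibble::tibble(x = x, y = y, vaf = vaf,
                 vaf_adj = vaf * (1 - alpha) + (1 - vaf) * alpha,
                 prior = 1 / length(x))
}

#' Per-entry SNV read log-likelihood
#'
#' Log-likelihood of observing `a` variant reads out of `d` total reads at
#' one locus in one cell, conditional on the clonal genotype of that cell at
#' that locus. Genotype 0 emits variant reads at the sequencing error rate:
#' `log Binom(a; d, alpha)`. Genotype 1 marginalizes the binomial success
#' probability over the allele-specific copy states of [copy_state_set()]
#' with the error-adjusted VAF `vaf' = vaf (1 - alpha) + (1 - vaf) alpha`.
#' Entries with `d = 0` carry no information and contribute exactly 0 under
#' either genotype, which keeps posteriors comparable across trees.
#'
#' @param a,d nonnegative integer vectors of variant and total read counts,
#'   `a <= d`.
#' @param genotype 0 or 1.
#' @param params a [model_params].
#' @return numeric vector of log-likelihoods.
#' @export
snv_entry_loglik <- function(a, d, genotype, params = model_params()) {
  if (any(a > d)) stop("variant reads exceed total reads")
  if (any(a < 0) || any(d < 0)) stop("counts must be nonnegative")
  if (!genotype %in% c(0, 1)) stop("genotype must be 0 or 1")
  out <- numeric(length(a))
  pos <- d > 0
  if (genotype == 0) {
    out[pos] <- stats::dbinom(a[pos], d[pos], params$alpha, log = TRUE)
  } else if (any(pos)) {
    st <- copy_state_set(params$max_copies, params$alpha)
    ll <- vapply(seq_len(nrow(st)), function(s) {
      stats::dbinom(a[pos], d[pos], st$vaf_adj[s], log = TRUE) + log(st$prior[s])
    }, numeric(sum(pos)))
    ll <- matrix(ll, nrow = sum(pos))
    out[pos] <- log_sum_exp_rows(ll)
  }
  out
}

log_sum_exp_rows <- function(M) {
  if (nrow(M) == 0L) return(numeric(0))
  mx <- apply(M, 1, max)
  mx + log(base::rowSums(exp(M - mx)))
}

#' Precompute per-entry likelihood structures
#'
#' Builds sparse matrices `S0` and `S1` over the nonzero pattern of `D`
#' holding the genotype-0 and genotype-1 entry log-likelihoods, plus the
#' coverage (`d > 0`) and variant-evidence (`a > 0`) indicator patterns used
#' by the combined feature and the detectability/quality filters. Entry
#' likelihoods are computed once per unique `(a, d)` pair, which at
#' ultra-low coverage is a handful of values.
#'
#' @param data a [read_count_data].
#' @param params a [model_params].
#' @return list with sparse matrices `S0`, `S1`, `Sdiff` (`S1 - S0`) and
#'   pattern matrices `Dpos`, `Apos`.
#' @export
model_precompute <- function(data, params = model_params()) {
  Dt <- as(data$D, "TsparseMatrix")
  i <- Dt@i + 1L; j <- Dt@j + 1L; d <- Dt@x
  a <- data$A[cbind(i, j)]
  key <- paste(a, d)
  uk <- !duplicated(key)
  ua <- a[uk]; ud <- d[uk]
  l0 <- snv_entry_loglik(ua, ud, 0, params)
  l1 <- snv_entry_loglik(ua, ud, 1, params)
  idx <- match(key, key[uk])
  dims <- dim(data$D)
  S0 <- Matrix::sparseMatrix(i = i, j = j, x = l0[idx], dims = dims)
  S1 <- Matrix::sparseMatrix(i = i, j = j, x = l1[idx], dims = dims)
  Dpos <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = dims)
  At <- as(data$A, "TsparseMatrix")
  keep <- At@x > 0
  Apos <- Matrix::sparseMatrix(i = At@i[keep] + 1L, j = At@j[keep] + 1L,
                               x = 1, dims = dims)
  list(S0 = S0, S1 = S1, Sdiff = S1 - S0, Dpos = Dpos, Apos = Apos)
}

#' Clone-level embedding log-likelihood
#'
#' Cells of a clone are modelled as a spherical normal around the clone
#' center in embedding space; this is the term through which copy-number
#' similarity enters the posterior. The value is the sum over cells and
#' dimensions of normal log-densities, monotonically decreasing in the
#' distance of each cell from the center.
#'
#' @param rows matrix of embedding rows of the clone's cells (one per cell).
#' @param center numeric vector, the clone center.
#' @param spread positive scalar standard deviation (pooled across clones).
#' @return scalar log-likelihood.
#' @export
embedding_loglik <- function(rows, center, spread) {
  rows <- rbind(rows)
  if (nrow(rows) == 0L) stop("clone has no cells")
  if (spread <= 0) stop("spread must be positive")
  sum(stats::dnorm(t(rows) - center, sd = spread, log = TRUE))
}

# Pooled MLE spread and per-clone centers for one clustering.
# Returns list(centers = k x l, spread, loglik).
embedding_fit <- function(E, cell_node, k) {
  l <- ncol(E)
  centers <- matrix(0, k, l)
  resid2 <- 0
  for (j in seq_len(k)) {
    rows <- E[cell_node == j, , drop = FALSE]
    if (nrow(rows) == 0L) next
    centers[j, ] <- colMeans(rows)
    resid2 <- resid2 + sum(sweep(rows, 2, centers[j, ])^2)
  }
  N <- nrow(E) * l
  spread <- sqrt(max(resid2 / N, 1e-8))
  # closed form of the summed spherical-normal log-density
  ll <- -0.5 * N * log(2 * pi * spread^2) - resid2 / (2 * spread^2)
  list(centers = centers, spread = spread, loglik = ll)
}

#' Log-posterior of a clonal tree solution
#'
#' Evaluates the (log) posterior of `(T, Y, phi)` given the data, up to a
#' constant: the sum over cells and loci of the entry log-likelihood under
#' the cell's clonal genotype, plus the clone-level embedding log-likelihood
#' with per-clone centers and a pooled spread re-estimated for the given
#' clustering. Priors over tree topologies and cell assignments are flat;
#' the per-SNV attachment prior is uniform over the nodes of the tree at
#' hand, contributing `-m log k` and thereby penalizing solutions that add
#' nodes without likelihood support. The score is additive over clones,
#' which licenses the incremental updates used by the elementary
#' operations.
#'
#' @param tree a [clonal_tree].
#' @param data a [read_count_data].
#' @param params a [model_params].
#' @param embedding optional n x l embedding matrix; computed from `data$R`
#'   when absent, or omitted from the score (with a zero embedding term) when
#'   no binned counts are available.
#' @param precomp optional result of [model_precompute()].
#' @return scalar log-posterior (up to an additive constant).
#' @export
tree_log_posterior <- function(tree, data, params = model_params(),
                               embedding = NULL, precomp = NULL) {
  if (length(tree$cell_node) != length(data$cell_ids) ||
      length(tree$attach) != length(data$snv_ids))
    stop("tree and data dimensions disagree")
  validate_clonal_tree(tree)
  if (is.null(precomp)) precomp <- model_precompute(data, params)
  k <- n_nodes(tree)
  Z <- Matrix::sparseMatrix(i = seq_along(tree$cell_node), j = tree$cell_node,
                            x = 1, dims = c(length(tree$cell_node), k))
  L0 <- as.matrix(Matrix::crossprod(Z, precomp$S0)) # k x m
  Ld <- as.matrix(Matrix::crossprod(Z, precomp$Sdiff))
  M <- anc_or_self(tree) # M[v, j]: v anc-or-self of j
  clade_score <- M %*% Ld # [v, q] = sum over j in clade(v) of Ld[j, q]
  snv_ll <- sum(L0) + sum(clade_score[cbind(tree$attach, seq_along(tree$attach))])
  # per-SNV uniform attachment prior: each SNV attaches to one of the k
  # nodes, so trees with more nodes pay -m log k. This is the only prior
  # term that varies across solutions (tree and cell-assignment priors are
  # flat), and it is what lets a Linear extension outrank a Branching one
  # that merely mimics it with a near-empty second child.
  attach_prior <- -length(tree$attach) * log(k)
  emb_ll <- 0
  if (!is.null(embedding) || !is.null(data$R)) {
    E <- cell_embedding(data, embedding, ndim = params$embed_dim,
                        seed = params$seed)
    emb_ll <- embedding_fit(E, tree$cell_node, k)$loglik
  }
  snv_ll + attach_prior + emb_ll
}

#' Maximum-posterior SNV attachment
#'
#' For a fixed tree topology and cell clustering, re-attaches each SNV to
#' the node maximizing its (marginal) posterior contribution: attaching SNV
#' `q` at node `v` sets genotype 1 exactly on the clade of `v`, so the
#' contribution is the sum of genotype-1 entry likelihoods over cells inside
#' the clade plus genotype-0 likelihoods outside. The resulting genotypes
#' obey infinite sites by construction. Runs in time linear in the number of
#' covered entries. Ties are broken toward the most ancestral candidate
#' (flat attachment prior), so an SNV with no coverage anywhere attaches at
#' the root.
#'
#' @param tree a [clonal_tree]; its `attach` field is replaced.
#' @param data a [read_count_data].
#' @param params a [model_params].
#' @param snvs integer indices of SNVs to (re)attach; default all.
#' @param nodes integer indices of candidate attachment nodes; default all.
#' @param precomp optional [model_precompute()] result.
#' @return the tree with updated SNV attachments.
#' @export
assign_snvs <- function(tree, data, params = model_params(), snvs = NULL,
                        nodes = NULL, precomp = NULL) {
  if (is.null(precomp)) precomp <- model_precompute(data, params)
  if (is.null(snvs)) snvs <- seq_along(tree$attach)
  if (length(snvs) == 0L) return(tree)
  k <- n_nodes(tree)
  if (is.null(nodes)) nodes <- seq_len(k)
  n <- length(tree$cell_node)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = tree$cell_node, x = 1,
                            dims = c(n, k))
  Ld <- as.matrix(Matrix::crossprod(Z, precomp$Sdiff[, snvs, drop = FALSE]))
  M <- anc_or_self(tree)
  scores <- M[nodes, , drop = FALSE] %*% Ld # |nodes| x |snvs|
  # depth-based ancestral tie-break: among equal scores prefer shallower node
  depth <- node_depths(tree)[nodes]
  best <- apply(scores + outer(-1e-12 * depth, rep(1, length(snvs))), 2, which.max)
  tree$attach[snvs] <- nodes[best]
  tree
}

node_depths <- function(tree) {
  k <- n_nodes(tree)
  d <- integer(k)
  for (j in seq_len(k)) {
    v <- tree$parent[j]
    while (v != 0L) { d[j] <- d[j] + 1L; v <- tree$parent[v] }
  }
  d
}
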