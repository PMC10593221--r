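#' Combined copy-number + SNV feature
#'
#' Builds the per-cell feature used for the normalized-cut bipartition of a
#' leaf: the cell's embedding row (standardized per dimension over the cells
#' under consideration) concatenated with one standardized SNV evidence
#' score — the cell mutational burden over the SNV set under reassignment,
#' i.e. the fraction of covered loci of the set carrying at least one
#' variant read. Cells with no covered locus in the set get the cohort mean
#' imputed and are flagged. With an empty SNV set the feature degenerates to
#' the embedding alone.
#'
#' @param embedding n x l embedding matrix (all cells of the dataset).
#' @param A,D sparse count matrices of the dataset.
#' @param cells integer indices of the cells to featurize.
#' @param snv_set integer indices of the SNVs under reassignment.
#' @param precomp optional [model_precompute()] result (pattern reuse).
#' @return |cells| x (l + 1) matrix (or |cells| x l when `snv_set` is
#'   empty); attribute `"missing"` flags cells with no covered locus.
#' @export
combined_feature <- function(embedding, A, D, cells, snv_set,
                             precomp = NULL) {
  if (length(cells) == 0L) stop("cells must be nonempty")
  E <- standardize_cols(embedding[cells, , drop = FALSE])
  if (length(snv_set) == 0L) {
    attr(E, "missing") <- rep(FALSE, length(cells))
    return(E)
  }
  ev <- snv_evidence(A, D, cells, snv_set, precomp)
  miss <- is.na(ev)
  if (all(miss)) {
    ev[] <- 0
  } else {
    ev[miss] <- mean(ev[!miss])
  }
  out <- cbind(E, evidence = standardize_cols(matrix(ev, ncol = 1)))
  attr(out, "missing") <- miss
  out
}

# CMB of each cell over snv_set; NA where no covered locus.
snv_evidence <- function(A, D, cells, snv_set, precomp = NULL) {
  if (is.null(precomp)) {
    Ds <- D[cells, snv_set, drop = FALSE]
    As <- A[cells, snv_set, drop = FALSE]
    cov <- Matrix::rowSums(Ds > 0)
    alt <- Matrix::rowSums(As > 0)
  } else {
    cov <- Matrix::rowSums(precomp$Dpos[cells, snv_set, drop = FALSE])
    alt <- Matrix::rowSums(precomp$Apos[cells, snv_set, drop = FALSE])
  }
  ifelse(cov > 0, alt / pmax(cov, 1), NA_real_)
}

standardize_cols <- function(M) {
  mu <- colMeans(M)
  sdv <- apply(M, 2, stats::sd)
  out <- sweep(M, 2, mu)
  ok <- is.finite(sdv) & sdv > 1e-12
  if (any(ok)) out[, ok] <- sweep(out[, ok, drop = FALSE], 2, sdv[ok], "/")
  if (any(!ok)) out[, !ok] <- 0 # constant columns carry no signal
  out
}

#' Normalized-cut bipartition of cells
#'
#' Builds a fully connected similarity graph over the given feature rows
#' with a Gaussian kernel (bandwidth = the median pairwise feature distance,
#' optionally rescaled), relaxes the normalized-cut objective
#' `Ncut(L, R) = cut(L, R)/assoc(L, V) + cut(L, R)/assoc(R, V)` to the
#' second generalized eigenvector of the graph Laplacian, and thresholds the
#' eigenvector at the sweep position minimizing the exact Ncut. Both sides
#' are always nonempty. When all features coincide the kernel carries no
#' signal; a deterministic half/half split is returned and flagged.
#'
#' @param features numeric matrix, one row per cell (see
#'   [combined_feature()]).
#' @param seed integer seed controlling the sweep-threshold jitter.
#' @param bw_scale multiplicative perturbation of the kernel bandwidth
#'   (restarts use values in `[0.8, 1.2]`).
#' @param jitter standard deviation of the seeded multiplicative noise added
#'   to the sweep Ncut values before taking the argmin; 0 disables it.
#' @param warm_start optional eigenvector from a previous call on the same
#'   cells, used to warm-start the iterative eigensolver.
#' @return list with integer index vectors `left` and `right` (into the rows
#'   of `features`), the exact `ncut` value of the returned split, the
#'   kernel bandwidth `sigma`, the generalized `eigvec`, and `no_signal`.
#' @export
ncut_bipartition <- function(features, seed = 1L, bw_scale = 1,
                             jitter = 0, warm_start = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2L) stop("need at least 2 cells to bipartition")
  core <- .ncut_core(features, bw_scale, warm_start)
  ord <- core$order + 1L
  if (core$no_signal) {
    half <- seq_len(floor(n / 2))
    return(list(left = sort(ord[half]), right = sort(ord[-half]),
                ncut = NA_real_, sigma = core$sigma,
                eigvec = core$eigvec, no_signal = TRUE))
  }
  ncuts <- core$ncut
  if (jitter > 0) {
    noise <- withr::with_seed(seed, stats::runif(length(ncuts), 1 - jitter,
                                                 1 + jitter))
    pick <- which.min(ncuts * noise)
  } else {
    pick <- which.min(ncuts)
  }
  left <- sort(ord[seq_len(pick)])
  right <- sort(ord[-seq_len(pick)])
  list(left = left, right = right, ncut = ncuts[pick], sigma = core$sigma,
       eigvec = core$eigvec, no_signal = FALSE)
}

#' Exact normalized-cut value of a bipartition
#'
#' @param features feature matrix as in [ncut_bipartition()].
#' @param side logical vector, TRUE for cells in the left part.
#' @param sigma kernel bandwidth.
#' @return scalar Ncut value (`Inf` for an empty side).
#' @export
ncut_value <- function(features, side, sigma) {
  .ncut_value(as.matrix(features), as.logical(side), sigma)
}

# ---- elementary operations -------------------------------------------------

# Shared coordinate-descent engine for Linear and Branching.
# Returns the best (split, child SNV partition) over restarts. Works on
# local submatrices restricted to the leaf's cells and reassignable SNVs,
# so each half-step costs one pass over the covered entries. Terminates a
# restart when the cell bipartition revisits any previous state (the
# clustering is discrete, so a revisit means a cycle that cannot improve
# on the best iterate already recorded).
op_coordinate_descent <- function(op, tree, leaf, data, params, embedding,
                                  precomp) {
  cells <- which(tree$cell_node == leaf)
  snvs <- snv_gains(tree, leaf)
  n_c <- length(cells)
  Eloc <- embedding[cells, , drop = FALSE]
  Estd <- standardize_cols(Eloc)
  # column-sliced local views: rows = leaf cells, columns = reassignable SNVs
  S0s <- precomp$S0[, snvs, drop = FALSE][cells, , drop = FALSE]
  S1s <- precomp$S1[, snvs, drop = FALSE][cells, , drop = FALSE]
  Dps <- precomp$Dpos[, snvs, drop = FALSE][cells, , drop = FALSE]
  Aps <- precomp$Apos[, snvs, drop = FALSE][cells, , drop = FALSE]
  s0_all <- Matrix::colSums(S0s)
  s1_all <- Matrix::colSums(S1s)
  evidence_of <- function(cols) {
    cov <- Matrix::rowSums(Dps[, cols, drop = FALSE])
    alt <- Matrix::rowSums(Aps[, cols, drop = FALSE])
    ifelse(cov > 0, alt / pmax(cov, 1), NA_real_)
  }
  best <- list()
  warm <- NULL # eigenvector warm start, carried across restarts (same cells)
  for (r in seq_len(params$restarts) - 1L) {
    rs <- params$seed + r
    if (r == 0L) {
      bw <- 1; jit <- 0
    } else {
      bw <- withr::with_seed(rs, stats::runif(1, 0.8, 1.2))
      jit <- 0.05
    }
    S_desc <- seq_along(snvs) # local indices of SNVs currently below parent
    seen_splits <- character(0)
    iter <- 0L
    converged <- FALSE
    r_best <- NULL
    while (iter < params$max_iter) {
      iter <- iter + 1L
      ev_feat <- if (length(S_desc) > 0L) evidence_of(S_desc) else NULL
      if (is.null(ev_feat)) {
        feats <- Estd
      } else {
        evf <- ev_feat
        miss <- is.na(evf)
        evf[miss] <- if (all(miss)) 0 else mean(evf[!miss])
        feats <- cbind(Estd, standardize_cols(matrix(evf, ncol = 1)))
      }
      cut <- ncut_bipartition(feats, seed = rs, bw_scale = bw, jitter = jit,
                              warm_start = warm)
      warm <- cut$eigvec
      # orientation: the side with higher SNV evidence over the current
      # descendant set is the descendant (left child for Branching)
      ev <- if (length(S_desc) > 0L) ev_feat else evidence_of(seq_along(snvs))
      mL <- mean(ev[cut$left], na.rm = TRUE)
      mR <- mean(ev[cut$right], na.rm = TRUE)
      if (is.nan(mL)) mL <- -Inf
      if (is.nan(mR)) mR <- -Inf
      if (mR > mL) {
        desc_loc <- cut$right; other_loc <- cut$left
      } else {
        desc_loc <- cut$left; other_loc <- cut$right
      }
      asg <- op_assign_snvs(op, n_c, desc_loc, S0s, S1s, s0_all, s1_all)
      score <- asg$snv_ll + op_embedding_ll(Eloc, desc_loc)
      state <- list(desc = cells[desc_loc], other = cells[other_loc],
                    assign = asg$assign, local_post = score)
      if (is.null(r_best) || score > r_best$local_post) r_best <- state
      S_desc <- which(asg$assign == "desc")
      key <- paste(desc_loc, collapse = ",")
      if (key %in% seen_splits) { converged <- TRUE; break }
      seen_splits <- c(seen_splits, key)
    }
    r_best$converged <- converged
    r_best$iterations <- iter
    best[[length(best) + 1L]] <- r_best
  }
  # rank distinct restart states by local posterior (ties: fewer
  # iterations, then lexicographic cell membership); downstream filters may
  # reject the top state, in which case the next-best state is considered
  keys <- vapply(best, function(s) paste(s$desc, collapse = ","), "")
  ord <- order(-vapply(best, `[[`, 1, "local_post"),
               vapply(best, `[[`, 1L, "iterations"), keys)
  best <- best[ord]
  best[!duplicated(keys[ord])]
}

# SNV assignment within one operation, restricted to the new local nodes.
# op = "linear": candidates {parent (all leaf cells), desc (child)}.
# op = "branching": candidates {parent (both children), left = desc,
# right = other}; the parent holds no cells during the operation.
# All inputs are local: desc_loc indexes rows of the S*s submatrices.
op_assign_snvs <- function(op, n_c, desc_loc, S0s, S1s, s0_all, s1_all) {
  ind <- Matrix::sparseMatrix(i = desc_loc, j = rep(1L, length(desc_loc)),
                              x = 1, dims = c(n_c, 1L))
  s1_desc <- as.vector(Matrix::crossprod(ind, S1s))
  s0_desc <- as.vector(Matrix::crossprod(ind, S0s))
  s1_other <- s1_all - s1_desc
  s0_other <- s0_all - s0_desc
  parent_score <- s1_desc + s1_other
  desc_score <- s1_desc + s0_other
  if (op == "linear") {
    assign <- ifelse(desc_score > parent_score + 1e-12, "desc", "parent")
    snv_ll <- sum(pmax(parent_score, desc_score))
  } else {
    other_score <- s0_desc + s1_other
    sc <- cbind(parent = parent_score, desc = desc_score, other = other_score)
    pick <- max.col(sc - 1e-12 * col(sc), ties.method = "first")
    assign <- colnames(sc)[pick]
    snv_ll <- sum(sc[cbind(seq_len(nrow(sc)), pick)])
  }
  list(assign = assign, snv_ll = snv_ll)
}

op_embedding_ll <- function(Eloc, desc_loc) {
  cn <- rep(2L, nrow(Eloc))
  cn[desc_loc] <- 1L
  embedding_fit(Eloc, cn, 2L)$loglik
}

#' Linear elementary operation
#'
#' Replaces a node with a two-node chain (parent -> child): the node's cells
#' are bipartitioned by a normalized cut on the combined feature, the side
#' with higher SNV evidence becomes the descendant child (stepwise SNV
#' acquisition: the child inherits the parent's genotype plus its own
#' gains), and each of the node's reassigned SNVs is attached at the parent
#' or child by maximum posterior. Clustering and attachment alternate until
#' the bipartition repeats or `max_iter` is reached; the best of `restarts`
#' seeded runs (bandwidth and sweep-threshold perturbations) is kept, and
#' within a run the best-scoring iterate (not necessarily the last) is
#' returned. On a leaf this extends the tree downward; on an internal node
#' that still holds cells it subdivides the node — the descendant cell
#' cluster and its gains move to a new intermediate node that inherits the
#' children — which is what allows a chain ancestry to unfold even when
#' earlier cuts did not discover the top edge first.
#'
#' @param tree a [clonal_tree].
#' @param leaf index of a node with at least 2 cells and 1 gained SNV.
#' @param data a [read_count_data].
#' @param params a [model_params].
#' @param embedding optional embedding matrix (computed from `data` if
#'   absent).
#' @param precomp optional [model_precompute()] result.
#' @return an `elementary_result`: list with `tree`, `log_posterior`,
#'   `converged`, `iterations`, `applicable`, `op`, `leaf`, `new_nodes`.
#' @export
linear_op <- function(tree, leaf, data, params = model_params(),
                      embedding = NULL, precomp = NULL) {
  elementary_op("linear", tree, leaf, data, params, embedding, precomp)
}

#' Branching elementary operation
#'
#' Replaces a leaf with a three-node binary subtree: the leaf becomes the
#' (cell-free) parent and its cells are partitioned between two new
#' children, signalling divergence from a common ancestor. Reassigned SNVs
#' are attached at the parent (shared by both children) or at one of the
#' children by maximum posterior. Coordinate descent, restarts and
#' convergence as in [linear_op()].
#'
#' @inheritParams linear_op
#' @return an `elementary_result` (see [linear_op()]).
#' @export
branching_op <- function(tree, leaf, data, params = model_params(),
                         embedding = NULL, precomp = NULL) {
  elementary_op("branching", tree, leaf, data, params, embedding, precomp)
}

elementary_op <- function(op, tree, leaf, data, params, embedding, precomp) {
  if (is.null(precomp)) precomp <- model_precompute(data, params)
  if (!is.null(embedding) || !is.null(data$R)) {
    embedding <- cell_embedding(data, embedding, ndim = params$embed_dim,
                                seed = params$seed)
  } else {
    stop("an embedding (or binned counts) is required by the elementary operations")
  }
  cells <- which(tree$cell_node == leaf)
  snvs <- snv_gains(tree, leaf)
  if (op == "branching" && length(which(tree$parent == leaf)) > 0L)
    stop("the branching operation extends leaves only")
  if (length(cells) < 2L || length(snvs) < 1L) {
    return(structure(list(tree = tree, log_posterior = NA_real_,
                          converged = NA, iterations = 0L,
                          applicable = FALSE, op = op, leaf = leaf,
                          new_nodes = integer(0)),
                     class = "elementary_result"))
  }
  states <- op_coordinate_descent(op, tree, leaf, data, params, embedding,
                                  precomp)
  best <- states[[1L]]
  built <- build_op_tree(op, tree, leaf, snvs, best)
  lp <- tree_log_posterior(built$tree, data, params, embedding, precomp)
  structure(list(tree = built$tree, log_posterior = lp,
                 converged = best$converged, iterations = best$iterations,
                 applicable = TRUE, op = op, leaf = leaf,
                 new_nodes = built$new_nodes, snvs = snvs, states = states),
            class = "elementary_result")
}

# Apply one coordinate-descent state (cell bipartition + local SNV
# assignment) of an elementary operation to a tree. Cell indices in the
# state are global, so a memoised state transfers across candidate trees
# sharing the same (cells, snvs) subproblem.
build_op_tree <- function(op, tree, leaf, snvs, state) {
  k <- n_nodes(tree)
  new_tree <- tree
  if (op == "linear") {
    child <- k + 1L
    new_tree$parent <- c(tree$parent, leaf)
    # edge subdivision: existing children (if any) descend from the new
    # node, which carries the descendant cell cluster and its SNV gains
    kids <- which(tree$parent == leaf)
    new_tree$parent[kids] <- child
    new_tree$node_labels <- c(tree$node_labels, paste0("v", child))
    new_tree$cell_node[state$desc] <- child
    new_tree$attach[snvs[state$assign == "desc"]] <- child
    new_nodes <- c(leaf, child)
  } else {
    left <- k + 1L; right <- k + 2L
    new_tree$parent <- c(tree$parent, leaf, leaf)
    new_tree$node_labels <- c(tree$node_labels, paste0("v", c(left, right)))
    new_tree$cell_node[state$desc] <- left
    new_tree$cell_node[state$other] <- right
    new_tree$attach[snvs[state$assign == "desc"]] <- left
    new_tree$attach[snvs[state$assign == "other"]] <- right
    new_nodes <- c(leaf, left, right)
  }
  list(tree = new_tree, new_nodes = new_nodes)
}

#' Identity elementary operation
#'
#' Leaves the tree unchanged and recomputes its posterior; used during
#' enumeration to close a frontier leaf.
#'
#' @inheritParams linear_op
#' @return an `elementary_result` whose tree is the input.
#' @export
identity_op <- function(tree, leaf, data, params = model_params(),
                        embedding = NULL, precomp = NULL) {
  lp <- tree_log_posterior(tree, data, params, embedding, precomp)
  structure(list(tree = tree, log_posterior = lp, converged = TRUE,
                 iterations = 0L, applicable = TRUE, op = "identity",
                 leaf = leaf, new_nodes = integer(0)),
            class = "elementary_result")
}
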