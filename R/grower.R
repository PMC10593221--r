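#' Initial candidate tree
#'
#' The growing phase starts from a single-node tree: all cells are assigned
#' to the root and every SNV is clonal (genotype 1 at the root). No
#' randomness is consumed.
#'
#' @param data a [read_count_data].
#' @return a [clonal_tree] with one node.
#' @export
init_tree <- function(data) {
  n <- length(data$cell_ids)
  m <- length(data$snv_ids)
  if (n == 0L || m == 0L) stop("need at least one cell and one SNV")
  clonal_tree(parent = 0L, attach = rep(1L, m), cell_node = rep(1L, n),
              cell_ids = data$cell_ids, snv_ids = data$snv_ids)
}

#' Clone detectability
#'
#' A clone is detectable when, on average over its newly introduced SNVs, at
#' least `t` of its cells cover each SNV (have at least one read at the
#' locus). This ties acceptance of a clone to the three quantities that
#' determine whether it is observable at all: sequencing coverage, clone
#' size, and the number of SNVs the clone introduces. Empty cell sets or
#' empty gain sets are never detectable.
#'
#' @param clone_cells integer indices of the clone's cells.
#' @param introduced_snvs integer indices of the SNVs gained at the clone.
#' @param D sparse total read count matrix.
#' @param t detectability threshold (cells per SNV).
#' @return logical scalar.
#' @export
is_detectable <- function(clone_cells, introduced_snvs, D, t) {
  if (length(clone_cells) == 0L || length(introduced_snvs) == 0L) return(FALSE)
  covered <- Matrix::colSums(D[clone_cells, introduced_snvs, drop = FALSE] > 0)
  mean(covered) >= t
}

#' Quality check on newly created clades
#'
#' Cells placed outside a clade should not carry the clade's SNVs: for each
#' checked node with gain set `S`, the median cell mutational burden
#' `CMB(i, S)` over outside cells with at least one covered locus in `S`
#' must not exceed `qc`. A clade that no outside cell covers passes
#' vacuously.
#'
#' @param tree a [clonal_tree].
#' @param data a [read_count_data].
#' @param qc upper bound on the outside-clade median CMB.
#' @param nodes node indices to check; default all non-root nodes with a
#'   nonempty gain set.
#' @param precomp optional [model_precompute()] result.
#' @return logical scalar.
#' @export
quality_check <- function(tree, data, qc, nodes = NULL, precomp = NULL) {
  if (is.null(nodes)) {
    nodes <- setdiff(which(tabulate(tree$attach, n_nodes(tree)) > 0L),
                     root_node(tree))
  }
  for (v in nodes) {
    S <- snv_gains(tree, v)
    if (length(S) == 0L) next
    outside <- setdiff(seq_along(tree$cell_node), clade_cells(tree, v))
    if (length(outside) == 0L) next
    vals <- snv_evidence(data$A, data$D, outside, S, precomp)
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) next # vacuous pass
    if (stats::median(vals) > qc) return(FALSE)
  }
  TRUE
}

#' Grow a clonal tree
#'
#' The full three-phase inference. Starting from the single-root tree, every
#' frontier leaf of every candidate tree is extended by the Linear and
#' Branching elementary operations (Identity closes a leaf); a resulting
#' tree is added to the candidate set only if each modified clone is
#' detectable at threshold `t`, meets the minimum clone size, and the tree
#' passes the outside-clade quality check at `qc`. Enumeration proceeds to
#' a fixpoint (each accepted tree strictly increases the node count, which
#' detectability bounds, so termination is guaranteed). Candidate trees are
#' deduplicated by canonical form, and elementary-op results are reused
#' across candidates that share the same leaf subproblem. Finally the
#' maximum-posterior candidate is post-processed and returned.
#'
#' @param data a [read_count_data].
#' @param params a [model_params].
#' @param embedding optional precomputed n x l embedding; derived from
#'   `data$R` when absent.
#' @param verbose print progress.
#' @return an object of class `clonal_fit`: list with the selected `tree`,
#'   its `log_posterior`, the `params`, a `candidates` tibble (one row per
#'   enumerated tree), an `attempts` tibble logging every attempted
#'   operation with its accept/reject reason, and the `embedding`.
#' @export
grow <- function(data, params = model_params(), embedding = NULL,
                 verbose = FALSE) {
  E <- cell_embedding(data, embedding, ndim = params$embed_dim,
                      seed = params$seed)
  precomp <- model_precompute(data, params)
  n <- length(data$cell_ids)
  min_size <- params$min_clone_size %||% max(10, ceiling(0.01 * n))
  t0 <- init_tree(data)
  candidates <- list(list(tree = t0,
                          log_posterior = tree_log_posterior(
                            t0, data, params, E, precomp)))
  seen <- new.env(parent = emptyenv())
  assign(tree_canonical_key(t0), TRUE, envir = seen)
  memo <- new.env(parent = emptyenv())
  queue <- list(list(tree_idx = 1L, leaf = 1L))
  attempts <- list()
  max_cand <- params$max_candidates %||% 64L
  while (length(queue) > 0L && length(candidates) < max_cand) {
    task <- queue[[1L]]
    queue <- queue[-1L]
    cand <- candidates[[task$tree_idx]]
    leaf <- task$leaf
    cells <- which(cand$tree$cell_node == leaf)
    snvs <- which(cand$tree$attach == leaf)
    if (length(cells) < 2L * min_size || length(snvs) < 1L) next
    is_leaf <- !(leaf %in% cand$tree$parent)
    ops <- if (is_leaf) c("linear", "branching") else "linear"
    for (op in ops) {
      key <- rlang::hash(list(op, cells, snvs))
      entry <- get0(key, envir = memo)
      if (is.null(entry)) {
        res <- switch(op,
                      linear = linear_op(cand$tree, leaf, data, params, E,
                                         precomp),
                      branching = branching_op(cand$tree, leaf, data, params,
                                               E, precomp))
        # memoise the coordinate-descent states, not the built tree, so
        # they transfer across candidates sharing the (cells, snvs)
        # subproblem
        entry <- list(applicable = res$applicable, states = res$states)
        assign(key, entry, envir = memo)
      }
      if (!entry$applicable) {
        attempts[[length(attempts) + 1L]] <- tibble::tibble(
          tree = task$tree_idx, leaf = leaf, op = op,
          log_posterior = NA_real_, accepted = FALSE, reason = "inapplicable")
        next
      }
      # try the ranked restart states until one passes the filters
      accepted <- NULL
      reason <- "accepted"
      for (si in seq_along(entry$states)) {
        built <- build_op_tree(op, cand$tree, leaf, snvs, entry$states[[si]])
        verdict <- accept_result(built$tree, built$new_nodes, data, params,
                                 min_size, precomp)
        if (si == 1L && !verdict$ok) reason <- verdict$reason
        if (verdict$ok) {
          # the posterior is evaluated only for the state that is kept
          lp <- tree_log_posterior(built$tree, data, params, E, precomp)
          accepted <- list(tree = built$tree, log_posterior = lp)
          break
        }
      }
      attempts[[length(attempts) + 1L]] <- tibble::tibble(
        tree = task$tree_idx, leaf = leaf, op = op,
        log_posterior = if (is.null(accepted)) NA_real_ else accepted$log_posterior,
        accepted = !is.null(accepted), reason = reason)
      if (is.null(accepted)) next
      tkey <- tree_canonical_key(accepted$tree)
      if (!is.null(get0(tkey, envir = seen))) next
      assign(tkey, TRUE, envir = seen)
      candidates[[length(candidates) + 1L]] <- accepted
      idx <- length(candidates)
      if (verbose)
        message(sprintf("accepted %s at leaf %d of tree %d -> tree %d (lp %.1f)",
                        op, leaf, task$tree_idx, idx, accepted$log_posterior))
      for (lv in open_nodes(accepted$tree, min_size)) {
        queue[[length(queue) + 1L]] <- list(tree_idx = idx, leaf = lv)
      }
    }
  }
  # ranking phase: candidates are compared by their posterior AFTER
  # post-processing; post-processing every tree is wasteful, so only the
  # top trees by raw posterior are refined (the raw posterior of a
  # candidate is a lower bound on its post-processed posterior)
  raw_lp <- vapply(candidates, `[[`, numeric(1), "log_posterior")
  top <- order(raw_lp, decreasing = TRUE)[seq_len(min(10L, length(raw_lp)))]
  post_lp <- rep(NA_real_, length(candidates))
  post_res <- vector("list", length(candidates))
  for (i in top) {
    post_res[[i]] <- post_process(candidates[[i]]$tree, data, params, E,
                                  precomp)
    post_lp[i] <- post_res[[i]]$log_posterior
  }
  best_idx <- top[which.max(post_lp[top])]
  post <- post_res[[best_idx]]
  # structural refinement of the selected tree: repair mis-nested subtrees
  spr <- spr_refine(post$tree, data, params, E, precomp)
  if (spr$log_posterior > post$log_posterior + 1e-9) {
    again <- post_process(spr$tree, data, params, E, precomp)
    post <- if (again$log_posterior >= spr$log_posterior) again else spr
  }
  cand_tbl <- purrr::map_dfr(seq_along(candidates), function(i) {
    tr <- candidates[[i]]$tree
    tibble::tibble(candidate = i, n_nodes = n_nodes(tr),
                   n_clones = n_clones(tr),
                   log_posterior = raw_lp[i],
                   post_log_posterior = post_lp[i],
                   selected = i == best_idx)
  })
  structure(list(tree = post$tree, log_posterior = post$log_posterior,
                 params = params, candidates = cand_tbl,
                 attempts = if (length(attempts)) dplyr::bind_rows(attempts)
                            else tibble::tibble(),
                 embedding = E,
                 candidate_trees = lapply(candidates, `[[`, "tree")),
            class = "clonal_fit")
}

accept_result <- function(tr, new_nodes, data, params, min_size, precomp) {
  for (v in new_nodes) {
    cells <- which(tr$cell_node == v)
    gains <- which(tr$attach == v)
    if (length(cells) == 0L) next # cell-free internal node is not a clone
    if (length(cells) < min_size)
      return(list(ok = FALSE, reason = "clone below minimum size"))
    if (!is_detectable(cells, gains, data$D, params$threshold))
      return(list(ok = FALSE, reason = "clone not detectable"))
  }
  if (!quality_check(tr, data, params$qc, nodes = new_nodes, precomp = precomp))
    return(list(ok = FALSE, reason = "quality check failed"))
  list(ok = TRUE, reason = "accepted")
}

# nodes whose cell set could still be subdivided (Linear applies to any
# such node; Branching additionally requires it to be a leaf)
open_nodes <- function(tree, min_size) {
  k <- n_nodes(tree)
  cells <- tabulate(tree$cell_node, k)
  gains <- tabulate(tree$attach, k)
  which(cells >= 2L * min_size & gains >= 1L)
}

#' Post-process a grown tree
#'
#' (1) Re-assigns cells to their maximum-posterior node with genotypes held
#' fixed; (2) contracts nodes left with no cells and no introduced SNVs;
#' (3) re-derives genotypes from the attachments (immediate in the
#' attachment encoding). Re-assignment runs as proposal/accept passes: each
#' pass scores every cell under every node (entry likelihood under the
#' node's genotype plus the embedding density), proposes the argmax
#' assignment, and keeps it only if the exact posterior does not decrease.
#' A node currently holding cells is scored around its fitted center with
#' the pooled within-clone spread; a cell-free node (e.g. the shared parent
#' created by a Branching operation) has no fitted center, so cells are
#' scored there under the predictive density — centered at the clade's cell
#' centroid with the between-clone center variance added to the spread.
#' This lets read evidence move trunk-genotype cells up into cell-free
#' internal nodes, after which the node's center is fitted from its new
#' occupants in the next pass. The returned posterior never decreases.
#'
#' @param tree a [clonal_tree].
#' @param data a [read_count_data].
#' @param params a [model_params].
#' @param embedding optional embedding matrix.
#' @param precomp optional [model_precompute()] result.
#' @param max_passes maximum number of re-assignment passes.
#' @return list with elements `tree` and `log_posterior`.
#' @export
post_process <- function(tree, data, params = model_params(),
                         embedding = NULL, precomp = NULL, max_passes = 10) {
  if (is.null(precomp)) precomp <- model_precompute(data, params)
  E <- cell_embedding(data, embedding, ndim = params$embed_dim,
                      seed = params$seed)
  k <- n_nodes(tree)
  Y <- genotypes(tree)
  n <- length(tree$cell_node)
  # per-cell read score under each node's genotype: base (all-0) + Sdiff on 1s
  snv_scores <- as.matrix(precomp$Sdiff %*% Matrix::t(
    Matrix::Matrix(Y, sparse = TRUE))) +
    matrix(Matrix::rowSums(precomp$S0), nrow = n, ncol = k)
  best <- tree
  best_lp <- tree_log_posterior(tree, data, params, E, precomp)
  cur <- tree
  for (pass in seq_len(max_passes)) {
    # half-step 1: re-attach every SNV at its global max-posterior node
    # (coordinate ascent in Y for fixed phi; cannot decrease the SNV term)
    reat <- assign_snvs(cur, data, params, precomp = precomp)
    if (!identical(reat$attach, cur$attach)) {
      lp <- tree_log_posterior(reat, data, params, E, precomp)
      if (lp >= best_lp) {
        cur <- reat
        best <- reat
        best_lp <- lp
        Y <- genotypes(cur)
        snv_scores <- as.matrix(precomp$Sdiff %*% Matrix::t(
          Matrix::Matrix(Y, sparse = TRUE))) +
          matrix(Matrix::rowSums(precomp$S0), nrow = n, ncol = k)
      }
    }
    # half-step 2: re-assign cells under the current genotypes
    ef <- embedding_fit(E, cur$cell_node, k)
    occupied <- sort(unique(cur$cell_node))
    glob <- colMeans(E)
    # between-clone variance of fitted centers (cell-weighted)
    sizes <- tabulate(cur$cell_node, k)
    ctr_dev2 <- sum(sizes[occupied] *
                      base::rowSums(sweep(ef$centers[occupied, , drop = FALSE],
                                          2, glob)^2))
    tau2 <- ctr_dev2 / (n * ncol(E))
    sd_pred <- sqrt(ef$spread^2 + tau2)
    scores <- snv_scores
    for (j in seq_len(k)) {
      if (j %in% occupied) {
        ctr <- ef$centers[j, ]
        sdv <- ef$spread
      } else {
        cc <- clade_cells(cur, j)
        ctr <- if (length(cc) > 0L) colMeans(E[cc, , drop = FALSE]) else glob
        sdv <- sd_pred
      }
      dev <- sweep(E, 2, ctr)
      scores[, j] <- scores[, j] +
        base::rowSums(stats::dnorm(dev, sd = sdv, log = TRUE))
    }
    prop <- max.col(scores, ties.method = "first")
    if (identical(prop, cur$cell_node)) break
    cand <- cur
    cand$cell_node <- prop
    lp <- tree_log_posterior(cand, data, params, E, precomp)
    if (lp < best_lp) break
    cur <- cand
    best <- cand
    best_lp <- lp
  }
  # clone-promotion proposals: the per-cell argmax cannot move a whole
  # cluster out of its own fitted center, yet relocating a node's entire
  # cell set to its parent (re-attaching the node's gains elsewhere) can
  # raise the posterior — the embedding fit follows the cluster, and the
  # attachment prior rewards retiring a node whose gains lack read support.
  # Each proposal is accepted only if the exact posterior increases.
  repeat {
    improved <- FALSE
    k_cur <- n_nodes(cur)
    depths <- node_depths(cur)
    for (v in order(depths, decreasing = TRUE)) {
      if (cur$parent[v] == 0L) next
      if (!any(cur$cell_node == v)) next
      cand <- cur
      cand$cell_node[cand$cell_node == v] <- cand$parent[v]
      gains <- which(cand$attach == v)
      if (length(gains) > 0L) {
        cand <- assign_snvs(cand, data, params, snvs = gains,
                            nodes = setdiff(seq_len(k_cur), v),
                            precomp = precomp)
      }
      # judge the proposal on its contracted form: retiring a node also
      # relaxes the attachment prior
      cand <- contract_empty_nodes(cand)
      lp <- tree_log_posterior(cand, data, params, E, precomp)
      if (lp > best_lp + 1e-9) {
        cur <- cand
        best <- cand
        best_lp <- lp
        improved <- TRUE
        break # node indices changed; restart the sweep
      }
    }
    if (!improved) break
  }
  out <- contract_empty_nodes(best)
  lp <- tree_log_posterior(out, data, params, E, precomp)
  list(tree = out, log_posterior = max(lp, best_lp))
}

# Remove nodes with neither cells nor gained SNVs, reattaching children to
# the grandparent. The root is never removed.
contract_empty_nodes <- function(tree) {
  repeat {
    k <- n_nodes(tree)
    cells <- tabulate(tree$cell_node, k)
    gains <- tabulate(tree$attach, k)
    removable <- which(cells == 0L & gains == 0L & tree$parent != 0L)
    if (length(removable) == 0L) return(tree)
    v <- removable[1L]
    tree$parent[tree$parent == v] <- tree$parent[v]
    keep <- setdiff(seq_len(k), v)
    remap <- integer(k)
    remap[keep] <- seq_along(keep)
    p2 <- tree$parent[keep]
    np <- integer(length(keep))
    nz <- p2 != 0L
    np[nz] <- remap[p2[nz]]
    tree$parent <- np
    tree$attach <- remap[tree$attach]
    tree$cell_node <- remap[tree$cell_node]
    tree$node_labels <- tree$node_labels[keep]
  }
}

#' Subtree-prune-regraft refinement
#'
#' Greedy hill-climb over subtree-prune-regraft (SPR) moves on a grown
#' tree: each non-root subtree is tentatively regrafted below every node
#' outside it, the moved tree's SNVs are re-attached at their
#' maximum-posterior nodes, and the move is kept only if the exact
#' posterior increases. This repairs cross-subtree mis-nestings that the
#' elementary operations cannot reach — e.g. a clade that diverged deep in
#' the tree but was split off at the root as a sibling — which neither
#' cell re-assignment nor SNV re-attachment alone can fix, since they hold
#' the topology fixed. Node count is unchanged, so the attachment prior
#' plays no role; the comparison is purely goodness-of-fit.
#'
#' @param tree a [clonal_tree].
#' @param data a [read_count_data].
#' @param params a [model_params].
#' @param embedding optional embedding matrix.
#' @param precomp optional [model_precompute()] result.
#' @param max_rounds maximum accepted-move rounds.
#' @return list with elements `tree` and `log_posterior`.
#' @export
spr_refine <- function(tree, data, params = model_params(), embedding = NULL,
                       precomp = NULL, max_rounds = 10) {
  if (is.null(precomp)) precomp <- model_precompute(data, params)
  E <- cell_embedding(data, embedding, ndim = params$embed_dim,
                      seed = params$seed)
  eval_cand <- function(tr) {
    tr <- assign_snvs(tr, data, params, precomp = precomp)
    list(tree = tr, lp = tree_log_posterior(tr, data, params, E, precomp))
  }
  cur <- eval_cand(tree)
  for (round in seq_len(max_rounds)) {
    improved <- FALSE
    k <- n_nodes(cur$tree)
    root <- root_node(cur$tree)
    for (u in setdiff(seq_len(k), root)) {
      inside <- clade_nodes(cur$tree, u)
      for (q in setdiff(seq_len(k), c(inside, cur$tree$parent[u]))) {
        cand <- cur$tree
        cand$parent[u] <- q
        got <- eval_cand(cand)
        if (got$lp > cur$lp + 1e-9) {
          cur <- got
          improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  list(tree = cur$tree, log_posterior = cur$lp)
}

#' @export
print.clonal_fit <- function(x, ...) {
  cat(sprintf("<clonal_fit> log-posterior %.2f, %d candidate trees\n",
              x$log_posterior, nrow(x$candidates)))
  print(x$tree)
  invisible(x)
}
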