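#' Relation between a pair of items on a clonal tree
#'
#' Two items (SNVs or cells) placed on a clonal tree are *clustered* if they
#' sit at the same node, *ancestral* if one item's node is a proper ancestor
#' of the other's (an ordered relation), and *incomparable* otherwise
#' (sibling subtrees).
#'
#' @param tree a [clonal_tree].
#' @param pair integer vector of two item indices.
#' @param what `"snv"` (placement = introduction node) or `"cell"`
#'   (placement = assigned node).
#' @return `"clustered"`, `"ancestral"` or `"incomparable"`; for
#'   `"ancestral"`, attribute `"first_is_ancestor"` gives the orientation.
#' @export
pair_relation <- function(tree, pair, what = c("snv", "cell")) {
  what <- match.arg(what)
  place <- if (what == "snv") tree$attach else tree$cell_node
  if (any(pair < 1L) || any(pair > length(place)))
    stop("unplaced item in pair")
  a <- place[pair[1]]; b <- place[pair[2]]
  if (a == b) return("clustered")
  M <- anc_or_self(tree)
  if (M[a, b]) return(structure("ancestral", first_is_ancestor = TRUE))
  if (M[b, a]) return(structure("ancestral", first_is_ancestor = FALSE))
  "incomparable"
}

# Pair-class recall between two placements via the contingency table.
# place_t, place_i: per-item node index in the truth / inferred tree.
# Mt, Mi: anc-or-self matrices of the two trees.
# Ancestral pairs are ordered (orientation must match); clustered and
# incomparable pairs are unordered.
pair_recall_counts <- function(place_t, place_i, Mt, Mi) {
  kt <- nrow(Mt); ki <- nrow(Mi)
  C <- matrix(0, kt, ki)
  tab <- table(factor(place_t, levels = seq_len(kt)),
               factor(place_i, levels = seq_len(ki)))
  C[] <- as.numeric(tab)
  nt <- base::rowSums(C)
  Pt <- Mt * 1; diag(Pt) <- 0 # proper-ancestor indicators
  Pi <- Mi * 1; diag(Pi) <- 0
  It <- 1 - Pt - t(Pt); diag(It) <- 0
  Ii <- 1 - Pi - t(Pi); diag(Ii) <- 0
  Q_anc <- C %*% Pi %*% t(C)
  Q_inc <- C %*% Ii %*% t(C)
  anc_total <- sum(Pt * outer(nt, nt))
  anc_match <- sum(Pt * Q_anc)
  inc_total <- sum(It * outer(nt, nt)) / 2
  inc_match <- sum(It * Q_inc) / 2
  clu_total <- sum(nt * (nt - 1)) / 2
  clu_match <- sum(C * (C - 1)) / 2
  list(apr = if (anc_total > 0) anc_match / anc_total else NA_real_,
       ipr = if (inc_total > 0) inc_match / inc_total else NA_real_,
       cpr = if (clu_total > 0) clu_match / clu_total else NA_real_,
       weights = c(ancestral = anc_total, incomparable = inc_total,
                   clustered = clu_total))
}

weighted_accuracy <- function(rec) {
  w <- rec$weights
  r <- c(rec$apr, rec$ipr, rec$cpr)[match(names(w), c("ancestral",
                                                      "incomparable",
                                                      "clustered"))]
  keep <- w > 0
  sum(w[keep] * r[keep]) / sum(w[keep])
}

#' Pair-recall metrics of an inferred tree against the truth
#'
#' Computes, for SNVs and for cells, the ancestral pair recall (APR: the
#' fraction of truth-ancestral ordered pairs that are ancestral with the
#' same orientation in the inference), incomparable pair recall (IPR) and
#' clustered pair recall (CPR), plus the pair-count-weighted *accuracy*
#' (weights proportional to the number of truth pairs per class; classes
#' with no truth pairs are excluded), and the genotype similarity. Pair
#' counts are accumulated through the truth-by-inferred placement
#' contingency table, so the computation is exact and takes time quadratic
#' in the number of nodes rather than items.
#'
#' @param truth,inferred [clonal_tree]s over the same cells and SNVs (the
#'   truth may also be a `clone_ground_truth`, whose tree and genotypes —
#'   including Dollo losses — are used).
#' @return a one-row tibble (`metrics_report`): `snv_apr`, `snv_ipr`,
#'   `snv_cpr`, `snv_accuracy`, `cell_apr`, `cell_ipr`, `cell_cpr`,
#'   `cell_accuracy`, `genotype_similarity`.
#' @export
recall_metrics <- function(truth, inferred) {
  gs <- genotype_similarity(truth, inferred)
  if (inherits(truth, "clone_ground_truth")) truth <- truth$tree
  if (inherits(inferred, "clonal_fit")) inferred <- inferred$tree
  if (length(truth$attach) != length(inferred$attach) ||
      length(truth$cell_node) != length(inferred$cell_node))
    stop("truth and inference must share the same cells and SNVs")
  Mt <- anc_or_self(truth); Mi <- anc_or_self(inferred)
  snv <- pair_recall_counts(truth$attach, inferred$attach, Mt, Mi)
  cell <- pair_recall_counts(truth$cell_node, inferred$cell_node, Mt, Mi)
  out <- tibble::tibble(
    snv_apr = snv$apr, snv_ipr = snv$ipr, snv_cpr = snv$cpr,
    snv_accuracy = weighted_accuracy(snv),
    cell_apr = cell$apr, cell_ipr = cell$ipr, cell_cpr = cell$cpr,
    cell_accuracy = weighted_accuracy(cell),
    genotype_similarity = gs)
  class(out) <- c("metrics_report", class(out))
  out
}

# Extract (Y matrix, per-cell cluster) from the objects that can carry
# cell-level genotypes.
cell_genotype_spec <- function(x) {
  if (inherits(x, "clone_ground_truth"))
    return(list(Y = x$Y, cluster = x$tree$cell_node))
  if (inherits(x, "clonal_fit")) x <- x$tree
  if (inherits(x, "clonal_tree"))
    return(list(Y = genotypes(x), cluster = x$cell_node))
  if (is.list(x) && !is.null(x$Y) && !is.null(x$cluster))
    return(list(Y = as.matrix(x$Y), cluster = as.integer(x$cluster)))
  stop("cannot extract cell-level genotypes from this object")
}

#' Genotype similarity
#'
#' One minus the normalized Hamming distance between the cell-level genotype
#' matrices of two solutions, where each cell inherits the genotype row of
#' its clone. Symmetric in its arguments.
#'
#' @param truth,inferred objects carrying cell-level genotypes: a
#'   [clonal_tree], `clonal_fit`, `clone_ground_truth`, or a list with
#'   elements `Y` (clusters x SNVs binary matrix) and `cluster` (node index
#'   per cell).
#' @return scalar in `[0, 1]`.
#' @export
genotype_similarity <- function(truth, inferred) {
  a <- cell_genotype_spec(truth)
  b <- cell_genotype_spec(inferred)
  if (length(a$cluster) != length(b$cluster) || ncol(a$Y) != ncol(b$Y))
    stop("genotype matrices have mismatched dimensions")
  n <- length(a$cluster); m <- ncol(a$Y)
  C <- matrix(0, nrow(a$Y), nrow(b$Y))
  tab <- table(factor(a$cluster, levels = seq_len(nrow(a$Y))),
               factor(b$cluster, levels = seq_len(nrow(b$Y))))
  C[] <- as.numeric(tab)
  Ya <- a$Y; Yb <- b$Y
  H <- Ya %*% t(1 - Yb) + (1 - Ya) %*% t(Yb) # pairwise Hamming distances
  1 - sum(C * H) / (n * m)
}

#' Cell mutational burden
#'
#' For each cell, the fraction of the loci of `snv_set` covered in that cell
#' (`d > 0`) that carry at least one variant read (`a > 0`). Cells covering
#' no locus of the set have an undefined burden and return `NA`.
#'
#' @param A,D sparse count matrices.
#' @param snv_set nonempty integer vector of SNV indices.
#' @param cells integer indices of cells; default all.
#' @return numeric vector of burdens (`NA` = undefined).
#' @export
cmb <- function(A, D, snv_set, cells = seq_len(nrow(A))) {
  if (length(snv_set) == 0L) stop("snv_set must be nonempty")
  snv_evidence(A, D, cells, snv_set)
}

#' Per-clade cell mutational burden report
#'
#' For every node with a nonempty gain set, contrasts the CMB over the
#' node's gained SNVs between cells inside the clade (the subtree rooted at
#' the node) and cells outside it. High inside and near-zero outside
#' medians indicate specific SNV placement. Undefined burdens (no covered
#' locus) are excluded.
#'
#' @param tree a [clonal_tree] (or `clonal_fit`).
#' @param data a [read_count_data].
#' @return tibble with one row per (node, side): `node`, `side`
#'   (inside/outside), `n_cells`, `n_defined`, `median`, `q25`, `q75`.
#' @export
cmb_clade_report <- function(tree, data) {
  if (inherits(tree, "clonal_fit")) tree <- tree$tree
  nodes <- which(tabulate(tree$attach, n_nodes(tree)) > 0L)
  purrr::map_dfr(nodes, function(v) {
    S <- snv_gains(tree, v)
    inside <- clade_cells(tree, v)
    outside <- setdiff(seq_along(tree$cell_node), inside)
    one_side <- function(cells, side) {
      vals <- if (length(cells)) cmb(data$A, data$D, S, cells) else numeric(0)
      def <- vals[!is.na(vals)]
      tibble::tibble(node = tree$node_labels[v], side = side,
                     n_cells = length(cells), n_defined = length(def),
                     median = if (length(def)) stats::median(def) else NA_real_,
                     q25 = if (length(def)) unname(stats::quantile(def, 0.25)) else NA_real_,
                     q75 = if (length(def)) unname(stats::quantile(def, 0.75)) else NA_real_)
    }
    dplyr::bind_rows(one_side(inside, "inside"), one_side(outside, "outside"))
  })
}

#' Baseline genotyper: embedding clusters plus pooled-read genotypes
#'
#' The ad hoc two-step practice used as a comparison method: cells are first
#' clustered on the copy-number embedding alone (Gaussian mixture model,
#' cluster count selected by BIC up to `max_clusters`, or fixed via
#' `n_clusters`), then each cluster is genotyped by pooling its reads:
#' `y[j, q] = 1` iff the pooled variant/total read ratio strictly exceeds
#' 0.05. Pools with zero total reads give `y = 0`.
#'
#' @param embedding n x l embedding matrix.
#' @param A,D sparse count matrices.
#' @param n_clusters fixed number of clusters, or `NULL` to select by BIC.
#' @param max_clusters largest cluster count considered when selecting.
#' @param ratio_threshold pooled alternate-read ratio that must be exceeded.
#' @return list with `cluster` (integer per cell), `Y` (clusters x SNVs
#'   binary matrix) and `K` (number of clusters), directly usable in
#'   [genotype_similarity()].
#' @export
baseline_genotyper <- function(embedding, A, D, n_clusters = NULL,
                               max_clusters = 9, ratio_threshold = 0.05) {
  E <- as.matrix(embedding)
  G <- if (is.null(n_clusters)) seq_len(max_clusters) else n_clusters
  # Mclust resolves mclustBIC in the caller's frame; bind it explicitly so
  # the namespace need not be attached
  mclustBIC <- mclust::mclustBIC
  fit <- mclust::Mclust(E, G = G, verbose = FALSE)
  cl <- as.integer(fit$classification)
  K <- max(cl)
  Z <- Matrix::sparseMatrix(i = seq_along(cl), j = cl, x = 1,
                            dims = c(length(cl), K))
  pooled_a <- as.matrix(Matrix::crossprod(Z, A))
  pooled_d <- as.matrix(Matrix::crossprod(Z, D))
  ratio <- ifelse(pooled_d > 0, pooled_a / pmax(pooled_d, 1), 0)
  Y <- (ratio > ratio_threshold) * 1L
  list(cluster = cl, Y = Y, K = K)
}
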