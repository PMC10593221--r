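#' Clonal trees
#'
#' A clonal tree is a rooted tree whose nodes carry binary SNV genotypes
#' obeying the infinite sites model: each SNV is gained exactly once (at the
#' root or on one edge) and never subsequently lost. Under this model the
#' genotype matrix `Y` is fully determined by the *attachment* of each SNV,
#' i.e. the node at which it is introduced: `y[j, q] = 1` iff the attachment
#' node of SNV `q` is an ancestor of (or equal to) node `j`. The object
#' therefore stores, besides the parent vector of the tree, one attachment
#' index per SNV and one node index per cell (the cell clustering `phi`).
#'
#' @param parent integer vector; `parent[j]` is the parent node index of node
#'   `j`, with `0` for the root. Exactly one root is required.
#' @param attach integer vector of length `m`; introduction node per SNV.
#' @param cell_node integer vector of length `n`; assigned node per cell.
#' @param cell_ids,snv_ids character vectors naming cells and SNVs.
#' @param node_labels optional character vector of node labels; defaults to
#'   `v1..vk` with `v1` the root (nodes are relabelled so the root is first).
#'
#' @return An object of class `clonal_tree`.
#' @export
clonal_tree <- function(parent, attach, cell_node, cell_ids = NULL,
                        snv_ids = NULL, node_labels = NULL) {
  parent <- as.integer(parent)
  k <- length(parent)
  if (k < 1L) stop("a clonal tree needs at least one node")
  if (sum(parent == 0L) != 1L) stop("exactly one root (parent = 0) required")
  attach <- as.integer(attach)
  cell_node <- as.integer(cell_node)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_along(cell_node))
  if (is.null(snv_ids)) snv_ids <- paste0("snv", seq_along(attach))
  if (is.null(node_labels)) node_labels <- paste0("v", seq_len(k))
  obj <- structure(
    list(parent = parent, attach = attach, cell_node = cell_node,
         cell_ids = as.character(cell_ids), snv_ids = as.character(snv_ids),
         node_labels = as.character(node_labels)),
    class = "clonal_tree")
  validate_clonal_tree(obj)
  obj
}

#' Validate a clonal tree
#'
#' Checks rootedness, acyclicity, and that every SNV attachment and cell
#' assignment points at an existing node. Because genotypes are derived from
#' attachments, the infinite-sites invariants (no loss along any edge, single
#' gain per SNV) hold by construction; this is additionally asserted on the
#' derived genotype matrix when `deep = TRUE`.
#'
#' @param tree a `clonal_tree`.
#' @param deep also re-check the derived genotype matrix against the
#'   infinite-sites conditions edge by edge.
#' @return `tree`, invisibly; errors on violation.
#' @export
validate_clonal_tree <- function(tree, deep = FALSE) {
  k <- n_nodes(tree)
  p <- tree$parent
  if (any(p < 0L | p > k)) stop("parent indices out of range")
  root <- which(p == 0L)
  # acyclicity: walking up from every node must reach the root
  for (j in seq_len(k)) {
    seen <- logical(k)
    v <- j
    while (v != root) {
      if (seen[v]) stop("cycle detected in tree")
      seen[v] <- TRUE
      v <- p[v]
    }
  }
  if (length(tree$attach) > 0L &&
      (min(tree$attach) < 1L || max(tree$attach) > k))
    stop("SNV attachment points at a nonexistent node")
  if (length(tree$cell_node) > 0L &&
      (min(tree$cell_node) < 1L || max(tree$cell_node) > k))
    stop("cell assigned to a nonexistent node")
  if (anyDuplicated(tree$cell_ids)) stop("duplicate cell ids")
  if (anyDuplicated(tree$snv_ids)) stop("duplicate snv ids")
  if (length(tree$node_labels) != k) stop("node_labels length mismatch")
  if (deep) {
    Y <- genotypes(tree)
    for (j in seq_len(k)) {
      if (j == root) next
      if (any(Y[p[j], ] == 1L & Y[j, ] == 0L))
        stop("infinite sites violated: SNV lost on an edge")
    }
  }
  invisible(tree)
}

#' @export
print.clonal_tree <- function(x, ...) {
  cat(sprintf("<clonal_tree> %d nodes (%d clones), %d cells, %d SNVs\n",
              n_nodes(x), n_clones(x), length(x$cell_node), length(x$attach)))
  gl <- tabulate(x$attach, n_nodes(x))
  cl <- tabulate(x$cell_node, n_nodes(x))
  df <- data.frame(node = x$node_labels,
                   parent = ifelse(x$parent == 0L, "-",
                                   x$node_labels[pmax(x$parent, 1L)]),
                   snvs_gained = gl, cells = cl)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @rdname clonal_tree
#' @export
n_nodes <- function(tree) length(tree$parent)

#' Number of clones (nodes with a nonempty cell set)
#'
#' The number of nodes of a clonal tree can exceed the number of clones: a
#' node that carries SNV gains but no cells (e.g. the shared parent created by
#' a Branching operation) is not counted as a clone.
#'
#' @param tree a `clonal_tree`.
#' @return integer count of nodes with at least one assigned cell.
#' @export
n_clones <- function(tree) {
  sum(tabulate(tree$cell_node, n_nodes(tree)) > 0L)
}

root_node <- function(tree) which(tree$parent == 0L)

#' Ancestor-or-self indicator matrix
#'
#' @param tree a `clonal_tree`.
#' @return k x k logical matrix `M` with `M[v, j]` TRUE iff `v` is `j` or a
#'   proper ancestor of `j`.
#' @keywords internal
anc_or_self <- function(tree) {
  k <- n_nodes(tree)
  M <- diag(TRUE, k)
  p <- tree$parent
  for (j in seq_len(k)) {
    v <- p[j]
    while (v != 0L) {
      M[v, j] <- TRUE
      v <- p[v]
    }
  }
  M
}

#' Clade membership
#'
#' @param tree a `clonal_tree`.
#' @param node node index.
#' @return integer vector of node indices in the subtree rooted at `node`
#'   (including `node` itself).
#' @export
clade_nodes <- function(tree, node) {
  which(anc_or_self(tree)[node, ])
}

#' Cells inside the clade rooted at a node
#' @inheritParams clade_nodes
#' @return integer indices of cells assigned to any node of the clade.
#' @export
clade_cells <- function(tree, node) {
  which(tree$cell_node %in% clade_nodes(tree, node))
}

#' SNVs gained at a node
#'
#' The gain set of node `j` is the set of SNVs introduced on the edge into `j`
#' (or present at the root when `j` is the root).
#'
#' @inheritParams clade_nodes
#' @return integer indices of SNVs attached at `node`.
#' @export
snv_gains <- function(tree, node) which(tree$attach == node)

#' Derive the clonal genotype matrix
#'
#' @param tree a `clonal_tree`.
#' @return k x m integer 0/1 matrix; `[j, q] = 1` iff SNV `q` is present in
#'   the genotype of node `j`.
#' @export
genotypes <- function(tree) {
  M <- anc_or_self(tree)
  # Y[j, q] = M[attach[q], j]
  Y <- t(M[tree$attach, , drop = FALSE]) * 1L
  storage.mode(Y) <- "integer"
  dimnames(Y) <- list(tree$node_labels, tree$snv_ids)
  Y
}

#' Build a clonal tree from an explicit genotype matrix
#'
#' Verifies that `Y` obeys the infinite sites model on the given topology
#' (each SNV present on exactly one clade) and converts it to the attachment
#' encoding.
#'
#' @inheritParams clonal_tree
#' @param Y k x m binary matrix of clonal genotypes.
#' @return a `clonal_tree`.
#' @export
clonal_tree_from_genotypes <- function(parent, Y, cell_node, cell_ids = NULL,
                                       snv_ids = NULL, node_labels = NULL) {
  parent <- as.integer(parent)
  k <- length(parent)
  Y <- as.matrix(Y)
  if (nrow(Y) != k) stop("Y must have one row per node")
  skel <- clonal_tree(parent, attach = rep(which(parent == 0L), ncol(Y)),
                      cell_node = cell_node, cell_ids = cell_ids,
                      snv_ids = snv_ids, node_labels = node_labels)
  M <- anc_or_self(skel)
  attach <- integer(ncol(Y))
  for (q in seq_len(ncol(Y))) {
    on <- which(Y[, q] == 1L)
    if (length(on) == 0L)
      stop(sprintf("SNV %d is absent from every node; every SNV must be gained once", q))
    # candidate attachment: the unique node in `on` whose parent is not in `on`
    cand <- on[!(parent[on] %in% on)]
    if (length(cand) != 1L || !identical(which(M[cand, ]), on))
      stop(sprintf("SNV %d violates the infinite sites model on this topology", q))
    attach[q] <- cand
  }
  skel$attach <- attach
  skel
}

#' Canonical key of a clonal tree solution
#'
#' Hash of the recursive canonical form (per-node sorted gain and cell sets,
#' children ordered by their own canonical keys), used to deduplicate
#' candidate trees that are isomorphic with identical genotypes and cell
#' clustering.
#'
#' @param tree a `clonal_tree`.
#' @return a character scalar.
#' @keywords internal
tree_canonical_key <- function(tree) {
  kids <- split(seq_len(n_nodes(tree)), tree$parent)[-1] # drop root's "0"
  children <- vector("list", n_nodes(tree))
  for (nm in names(kids)) children[[as.integer(nm)]] <- kids[[nm]]
  rec <- function(j) {
    sub <- vapply(children[[j]] %||% integer(0), rec, character(1))
    rlang::hash(list(sort(which(tree$attach == j)),
                     sort(which(tree$cell_node == j)),
                     sort(sub)))
  }
  rec(root_node(tree))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
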