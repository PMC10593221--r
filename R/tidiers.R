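#' Tidy a fitted clonal tree
#'
#' One row per tree node with its parent, the number of SNVs gained on the
#' edge into it, and the number of cells assigned to it.
#'
#' @param x a `clonal_fit` (from [grow()]) or a [clonal_tree].
#' @param ... unused.
#' @return a tibble with columns `node`, `parent`, `depth`, `n_snvs_gained`,
#'   `n_cells`.
#' @export
tidy.clonal_fit <- function(x, ...) tidy(x$tree, ...)

#' @rdname tidy.clonal_fit
#' @export
tidy.clonal_tree <- function(x, ...) {
  k <- n_nodes(x)
  tibble::tibble(
    node = x$node_labels,
    parent = ifelse(x$parent == 0L, NA_character_,
                    x$node_labels[pmax(x$parent, 1L)]),
    depth = node_depths(x),
    n_snvs_gained = tabulate(x$attach, k),
    n_cells = tabulate(x$cell_node, k))
}

#' One-row summary of a clonal tree fit
#'
#' @param x a `clonal_fit`.
#' @param ... unused.
#' @return a tibble with `n_nodes`, `n_clones`, `n_cells`, `n_snvs`,
#'   `log_posterior`, `n_candidates`.
#' @export
glance.clonal_fit <- function(x, ...) {
  tibble::tibble(n_nodes = n_nodes(x$tree), n_clones = n_clones(x$tree),
                 n_cells = length(x$tree$cell_node),
                 n_snvs = length(x$tree$attach),
                 log_posterior = x$log_posterior,
                 n_candidates = nrow(x$candidates))
}

#' Per-cell view of a clonal tree fit
#'
#' @param x a `clonal_fit`.
#' @param ... unused.
#' @return a tibble with one row per cell: `cell`, assigned `node`, and the
#'   first two embedding dimensions (`dim1`, `dim2`) when available.
#' @export
augment.clonal_fit <- function(x, ...) {
  out <- tibble::tibble(cell = x$tree$cell_ids,
                        node = x$tree$node_labels[x$tree$cell_node])
  if (!is.null(x$embedding) && ncol(x$embedding) >= 2) {
    out$dim1 <- x$embedding[, 1]
    out$dim2 <- x$embedding[, 2]
  }
  out
}

# simple layered layout: x = order of leaves below, y = -depth
tree_layout <- function(tree) {
  k <- n_nodes(tree)
  depth <- node_depths(tree)
  M <- anc_or_self(tree)
  leaves <- setdiff(seq_len(k), tree$parent)
  xs <- numeric(k)
  for (j in seq_len(k)) {
    below <- intersect(which(M[j, ]), leaves)
    xs[j] <- mean(match(below, leaves))
  }
  tibble::tibble(node = seq_len(k), x = xs, y = -depth)
}

#' Plot a clonal tree
#'
#' Draws the tree with nodes scaled by clone size and labelled with the
#' number of SNVs gained and cells assigned.
#'
#' @param object a `clonal_fit` or [clonal_tree].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.clonal_fit <- function(object, ...) autoplot(object$tree, ...)

#' @rdname autoplot.clonal_fit
#' @export
autoplot.clonal_tree <- function(object, ...) {
  tree <- object
  lay <- tree_layout(tree)
  info <- tidy(tree)
  df <- dplyr::bind_cols(lay[c("x", "y")], info)
  seg <- dplyr::filter(
    dplyr::mutate(df,
                  xend = lay$x[ifelse(tree$parent == 0L, NA, tree$parent)],
                  yend = lay$y[ifelse(tree$parent == 0L, NA, tree$parent)]),
    !is.na(.data$xend))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(xend = .data$xend, yend = .data$yend),
                          color = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_cells), color = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%s\n+%d SNVs\n%d cells", .data$node,
                      .data$n_snvs_gained, .data$n_cells)),
      vjust = -0.4, size = 3) +
    ggplot2::scale_size_area(max_size = 10, guide = "none") +
    ggplot2::theme_void() +
    ggplot2::expand_limits(y = c(min(df$y) - 0.5, 0.7))
}

#' Plot within- versus outside-clade cell mutational burden
#'
#' Boxplot of per-cell CMB for each clade, contrasting cells inside the
#' clade with cells outside it; the package's specificity diagnostic.
#'
#' @param tree a `clonal_fit` or [clonal_tree].
#' @param data a [read_count_data].
#' @return a ggplot object.
#' @export
plot_cmb <- function(tree, data) {
  if (inherits(tree, "clonal_fit")) tree <- tree$tree
  nodes <- which(tabulate(tree$attach, n_nodes(tree)) > 0L)
  df <- purrr::map_dfr(nodes, function(v) {
    S <- snv_gains(tree, v)
    inside <- clade_cells(tree, v)
    all_cells <- seq_along(tree$cell_node)
    vals <- cmb(data$A, data$D, S, all_cells)
    tibble::tibble(node = tree$node_labels[v],
                   side = ifelse(all_cells %in% inside, "inside", "outside"),
                   cmb = vals)
  })
  df <- dplyr::filter(df, !is.na(.data$cmb))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node, y = .data$cmb,
                                   fill = .data$side)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, position = "dodge") +
    ggplot2::labs(x = "clade", y = "cell mutational burden", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
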