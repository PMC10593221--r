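#' Read sparse SNV read counts from a long TSV
#'
#' The canonical on-disk format for variant/total read counts is a long
#' (triplet) TSV with header columns `cell`, `snv`, `variant_reads`,
#' `total_reads`: one row per covered `(cell, snv)` pair. Pairs absent from
#' the file have `a = d = 0` (no coverage). Cell and SNV ordering follows
#' first appearance in the file.
#'
#' @param path path to the TSV file.
#' @return a [read_count_data] (without binned counts).
#' @export
read_snv_counts <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    cell = readr::col_character(), snv = readr::col_character(),
    variant_reads = readr::col_double(), total_reads = readr::col_double()),
    progress = FALSE)
  req <- c("cell", "snv", "variant_reads", "total_reads")
  if (!all(req %in% names(df)))
    stop("counts file must have columns: ", paste(req, collapse = ", "))
  if (nrow(df) == 0L) stop("no records in ", path)
  prob <- readr::problems(df)
  if (nrow(prob) > 0L)
    stop(sprintf("malformed row at line %d of %s", prob$row[1] + 1L, path))
  if (any(!is.finite(df$variant_reads)) || any(!is.finite(df$total_reads)))
    stop("malformed counts: NA or non-finite values")
  if (any(df$variant_reads != round(df$variant_reads)) ||
      any(df$total_reads != round(df$total_reads)))
    stop("counts must be integers")
  if (any(df$variant_reads < 0) || any(df$total_reads < 0))
    stop("counts must be nonnegative")
  bad <- which(df$variant_reads > df$total_reads)
  if (length(bad) > 0L)
    stop(sprintf("variant reads exceed total reads at (%s, %s)",
                 df$cell[bad[1]], df$snv[bad[1]]))
  if (anyDuplicated(df[c("cell", "snv")]))
    stop("duplicate (cell, snv) rows")
  cell_ids <- unique(df$cell)
  snv_ids <- unique(df$snv)
  i <- match(df$cell, cell_ids)
  j <- match(df$snv, snv_ids)
  dims <- c(length(cell_ids), length(snv_ids))
  A <- Matrix::sparseMatrix(i = i, j = j, x = df$variant_reads, dims = dims)
  D <- Matrix::sparseMatrix(i = i, j = j, x = df$total_reads, dims = dims)
  read_count_data(A, D, cell_ids = cell_ids, snv_ids = snv_ids)
}

#' Write sparse SNV read counts to a long TSV
#'
#' @param data a [read_count_data].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snv_counts <- function(data, path) {
  readr::write_tsv(tidy(data), path, progress = FALSE)
  invisible(path)
}

#' Read binned read counts from a CSV/TSV table
#'
#' Expects a rectangular numeric table whose first column holds cell ids and
#' whose remaining columns are genomic bins. When `data` is supplied, rows
#' are reconciled against `data$cell_ids` by id (not by position) and the
#' returned object carries the bins in that order.
#'
#' @param path path to the table (delimiter inferred from the extension:
#'   `.csv` is comma-separated, anything else tab-separated).
#' @param data optional [read_count_data] whose cell ids the table must cover.
#' @return if `data` is `NULL`, a list with `R` (matrix) and `bin_ids`;
#'   otherwise `data` with `R` and `bin_ids` filled in.
#' @export
read_binned_counts <- function(path, data = NULL) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  df <- reader(path, col_types = readr::cols(), progress = FALSE)
  if (ncol(df) < 2L) stop("binned counts table needs a cell column plus bins")
  cells <- as.character(df[[1]])
  R <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(R)) stop("bin columns must be numeric")
  if (any(!is.finite(R))) stop("binned counts contain NA or non-finite values")
  if (any(R < 0)) stop("negative bin count")
  rownames(R) <- cells
  if (is.null(data)) return(list(R = R, bin_ids = colnames(R)))
  missing <- setdiff(data$cell_ids, cells)
  if (length(missing) > 0L)
    stop("binned counts missing cells: ", paste(missing, collapse = ", "))
  R <- R[data$cell_ids, , drop = FALSE]
  read_count_data(data$A, data$D, R = R, cell_ids = data$cell_ids,
                  snv_ids = data$snv_ids, bin_ids = colnames(R))
}

#' Read a precomputed cell embedding from CSV
#'
#' Format: first column `cell`, remaining columns the embedding dimensions.
#'
#' @param path path to the CSV.
#' @param data optional [read_count_data] used to order rows by cell id.
#' @return numeric matrix with rownames set to cell ids.
#' @export
read_embedding_csv <- function(path, data = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  E <- as.matrix(df[, -1, drop = FALSE])
  rownames(E) <- as.character(df[[1]])
  if (any(!is.finite(E))) stop("embedding contains non-finite values")
  if (!is.null(data)) {
    missing <- setdiff(data$cell_ids, rownames(E))
    if (length(missing) > 0L)
      stop("embedding missing cells: ", paste(missing, collapse = ", "))
    E <- E[data$cell_ids, , drop = FALSE]
  }
  E
}

#' Write a clonal tree solution to a directory
#'
#' Serializes a solution as four text files: `edges.tsv` (parent, child node
#' labels), `genotypes.tsv` (k x m 0/1 clonal genotype matrix with node and
#' SNV headers), `clustering.tsv` (cell, node), and `tree.dot` (Graphviz,
#' nodes annotated with the number of SNVs gained and cells assigned).
#'
#' @param tree a [clonal_tree] (or a `clonal_fit`, whose tree is used).
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_clonal_solution <- function(tree, out_dir) {
  if (inherits(tree, "clonal_fit")) tree <- tree$tree
  validate_clonal_tree(tree)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lab <- tree$node_labels
  nonroot <- which(tree$parent != 0L)
  edges <- tibble::tibble(parent = lab[tree$parent[nonroot]],
                          child = lab[nonroot])
  readr::write_tsv(edges, file.path(out_dir, "edges.tsv"), progress = FALSE)
  Y <- genotypes(tree)
  gen <- tibble::as_tibble(as.data.frame(Y), rownames = NA)
  gen <- dplyr::bind_cols(tibble::tibble(node = lab), gen)
  readr::write_tsv(gen, file.path(out_dir, "genotypes.tsv"), progress = FALSE)
  clus <- tibble::tibble(cell = tree$cell_ids, node = lab[tree$cell_node])
  readr::write_tsv(clus, file.path(out_dir, "clustering.tsv"), progress = FALSE)
  gains <- tabulate(tree$attach, n_nodes(tree))
  cells <- tabulate(tree$cell_node, n_nodes(tree))
  dot <- c("digraph clonal_tree {",
           sprintf("  \"%s\" [label=\"%s\\n%d SNVs\\n%d cells\"];",
                   lab, lab, gains, cells),
           sprintf("  \"%s\" -> \"%s\";", edges$parent, edges$child),
           "}")
  writeLines(dot, file.path(out_dir, "tree.dot"))
  invisible(out_dir)
}

#' Read a clonal tree solution written by [write_clonal_solution()]
#'
#' @param dir directory containing `edges.tsv`, `genotypes.tsv`,
#'   `clustering.tsv`.
#' @return a [clonal_tree].
#' @export
read_clonal_solution <- function(dir) {
  edges <- readr::read_tsv(file.path(dir, "edges.tsv"),
                           col_types = "cc", progress = FALSE)
  gen <- readr::read_tsv(file.path(dir, "genotypes.tsv"),
                         col_types = readr::cols(), progress = FALSE)
  clus <- readr::read_tsv(file.path(dir, "clustering.tsv"),
                          col_types = "cc", progress = FALSE)
  lab <- gen$node
  Y <- as.matrix(gen[, -1, drop = FALSE])
  parent <- rep(0L, length(lab))
  parent[match(edges$child, lab)] <- match(edges$parent, lab)
  if (any(!(clus$node %in% lab)))
    stop("cell assigned to a nonexistent node")
  clonal_tree_from_genotypes(parent, Y, cell_node = match(clus$node, lab),
                             cell_ids = clus$cell, snv_ids = colnames(Y),
                             node_labels = lab)
}

#' Read model parameters from a YAML/JSON config file
#'
#' Recognized keys match the arguments of [model_params()]; unknown keys are
#' an error.
#'
#' @param path path to a YAML (or JSON) file.
#' @return a [model_params] object.
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  known <- names(formals(model_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(model_params, cfg)
}
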