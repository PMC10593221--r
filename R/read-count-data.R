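#' Read count data for clonal tree inference
#'
#' Bundles the three observed matrices of an ultra-low coverage scDNA-seq
#' experiment: sparse variant read counts `A` and total read counts `D`
#' (cells x SNV loci), and optionally dense binned read counts `R`
#' (cells x genomic bins), the proxy for copy number. At 0.01x coverage more
#' than 99% of the entries of `D` are zero, so `A` and `D` are held as
#' `dgCMatrix`. An absent `(cell, snv)` entry means "no coverage" (`d = 0`),
#' not missing-at-random.
#'
#' @param A,D sparse or dense n x m nonnegative integer matrices of variant
#'   and total read counts; `0 <= A <= D` entrywise.
#' @param R optional dense n x b nonnegative matrix of binned read counts,
#'   rows aligned with `cell_ids`.
#' @param cell_ids,snv_ids,bin_ids identifier vectors; defaults are taken
#'   from dimnames where available.
#' @return An object of class `read_count_data` with elements `A`, `D`, `R`,
#'   `cell_ids`, `snv_ids`, `bin_ids`.
#' @export
read_count_data <- function(A, D, R = NULL, cell_ids = NULL, snv_ids = NULL,
                            bin_ids = NULL) {
  A <- as(as(A, "CsparseMatrix"), "dMatrix")
  D <- as(as(D, "CsparseMatrix"), "dMatrix")
  if (!identical(dim(A), dim(D))) stop("A and D must have identical dimensions")
  cell_ids <- as.character(cell_ids %||% rownames(A) %||% paste0("cell", seq_len(nrow(A))))
  snv_ids <- as.character(snv_ids %||% colnames(A) %||% paste0("snv", seq_len(ncol(A))))
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (anyDuplicated(snv_ids)) stop("duplicate snv ids")
  if (length(cell_ids) != nrow(A) || length(snv_ids) != ncol(A))
    stop("id lengths do not match matrix dimensions")
  check_counts <- function(M, nm) {
    x <- M@x
    if (any(!is.finite(x))) stop(nm, " contains non-finite counts")
    if (any(x < 0)) stop(nm, " contains negative counts")
    if (any(x != round(x))) stop(nm, " contains non-integer counts")
  }
  check_counts(A, "A"); check_counts(D, "D")
  if (any((A - D)@x > 0)) {
    bad <- which(as.matrix(A > D), arr.ind = TRUE)[1, ]
    stop(sprintf("variant reads exceed total reads at (%s, %s)",
                 cell_ids[bad[1]], snv_ids[bad[2]]))
  }
  if (!is.null(R)) {
    R <- as.matrix(R)
    if (nrow(R) != length(cell_ids))
      stop("R must have exactly one row per cell")
    if (any(!is.finite(R))) stop("R contains non-finite values")
    if (any(R < 0)) stop("R contains negative bin counts")
    bin_ids <- as.character(bin_ids %||% colnames(R) %||% paste0("bin", seq_len(ncol(R))))
    dimnames(R) <- list(cell_ids, bin_ids)
  } else {
    bin_ids <- NULL
  }
  dimnames(A) <- dimnames(D) <- list(cell_ids, snv_ids)
  structure(list(A = A, D = D, R = R, cell_ids = cell_ids, snv_ids = snv_ids,
                 bin_ids = bin_ids),
            class = "read_count_data")
}

#' @export
print.read_count_data <- function(x, ...) {
  cat(sprintf("<read_count_data> %d cells x %d SNVs (%.2f%% of D nonzero)%s\n",
              length(x$cell_ids), length(x$snv_ids),
              100 * length(x$D@x) / max(1, prod(dim(x$D))),
              if (is.null(x$R)) "" else sprintf(", %d bins", length(x$bin_ids))))
  invisible(x)
}

#' @export
dim.read_count_data <- function(x) dim(x$A)

#' Tidy the SNV counts of a read-count object
#'
#' @param x a `read_count_data`.
#' @param ... unused.
#' @return A long tibble with columns `cell`, `snv`, `variant_reads`,
#'   `total_reads`, one row per covered entry (`total_reads > 0`).
#' @export
tidy.read_count_data <- function(x, ...) {
  Dt <- as(x$D, "TsparseMatrix")
  ord <- order(Dt@i, Dt@j)
  i <- Dt@i[ord] + 1L
  j <- Dt@j[ord] + 1L
  a <- x$A[cbind(i, j)]
  tibble::tibble(cell = x$cell_ids[i], snv = x$snv_ids[j],
                 variant_reads = as.integer(a),
                 total_reads = as.integer(Dt@x[ord]))
}
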