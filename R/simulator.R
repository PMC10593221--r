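#' Simulation configuration
#'
#' Parameters of the matched simulator: a random clonal tree with `k` nodes,
#' `n` cells, `m` SNVs and `b` genomic bins, sequenced at mean coverage `g`
#' with per-base error `alpha`. Defaults mirror the benchmark study design:
#' 1000 cells, 5000 SNVs, 0.05x coverage, copy-number aberrations on, a 30%
#' truncal SNV share, and clone proportions drawn from a Dirichlet with a 2%
#' minimum clone fraction.
#'
#' @param k number of tree nodes (clones).
#' @param n number of cells.
#' @param m number of SNV loci.
#' @param g mean sequencing coverage per SNV locus in a diploid region,
#'   in (0, 1].
#' @param alpha per-base sequencing error probability.
#' @param b number of genomic bins.
#' @param cna_mode logical; when `TRUE`, each non-root edge acquires 1-3
#'   segmental copy-number events. When `FALSE` every locus stays
#'   heterozygous diploid in all clones.
#' @param evolution `"infinite_sites"` (no losses) or `"dollo"` (each SNV is
#'   additionally lost on at most one descendant edge with probability
#'   `dollo_loss_prob`).
#' @param max_copies cap on total copies per allele pair.
#' @param truncal_fraction fraction of SNVs placed at the root.
#' @param dirichlet_conc symmetric Dirichlet concentration for clone
#'   proportions.
#' @param min_clone_frac minimum clone proportion; proportions are redrawn
#'   until satisfied.
#' @param events_per_edge integer range (length 2) of CNA events per
#'   non-root edge.
#' @param event_len_frac numeric range (length 2) of event lengths as a
#'   fraction of the genome (in bins).
#' @param bin_factor expected reads per bin, per haploid copy, per unit
#'   coverage: with 500 kb bins and 100 bp reads a bin collects about 5000
#'   reads per copy at 1x, so the default is 5000.
#' @param dollo_loss_prob per-SNV loss probability under `"dollo"`.
#' @param seed integer seed; the full ground truth and read counts are
#'   reproducible from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(k = 5, n = 1000, m = 5000, g = 0.05, alpha = 0.001,
                       b = 1000, cna_mode = TRUE,
                       evolution = c("infinite_sites", "dollo"),
                       max_copies = 5, truncal_fraction = 0.3,
                       dirichlet_conc = 2, min_clone_frac = 0.02,
                       events_per_edge = c(1, 3),
                       event_len_frac = c(0.025, 0.15),
                       bin_factor = 5000, dollo_loss_prob = 0.05,
                       seed = 1L) {
  evolution <- match.arg(evolution)
  stopifnot(k >= 1, n >= 1, m >= 1, b >= 2, g > 0, g <= 1,
            alpha >= 0, alpha < 1, max_copies >= 2,
            truncal_fraction >= 0, truncal_fraction <= 1)
  if (k > n || k > m) stop("infeasible config: k must not exceed n or m")
  if (k * min_clone_frac > 1) stop("min_clone_frac too large for k clones")
  structure(list(k = as.integer(k), n = as.integer(n), m = as.integer(m),
                 g = g, alpha = alpha, b = as.integer(b),
                 cna_mode = cna_mode, evolution = evolution,
                 max_copies = as.integer(max_copies),
                 truncal_fraction = truncal_fraction,
                 dirichlet_conc = dirichlet_conc,
                 min_clone_frac = min_clone_frac,
                 events_per_edge = as.integer(events_per_edge),
                 event_len_frac = event_len_frac,
                 bin_factor = bin_factor,
                 dollo_loss_prob = dollo_loss_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

rdirichlet1 <- function(k, conc) {
  x <- stats::rgamma(k, shape = conc)
  x / sum(x)
}

# uniform labelled tree via a Pruefer sequence, rooted at node 1
random_rooted_tree <- function(k) {
  if (k == 1L) return(0L)
  if (k == 2L) return(c(0L, 1L))
  prufer <- sample.int(k, k - 2L, replace = TRUE)
  degree <- rep(1L, k) + tabulate(prufer, k)
  edges <- matrix(0L, k - 1L, 2L)
  ptr <- 1L
  for (i in seq_len(k - 2L)) {
    leaf <- which(degree == 1L)[1L]
    edges[i, ] <- c(leaf, prufer[i])
    degree[leaf] <- 0L
    degree[prufer[i]] <- degree[prufer[i]] - 1L
  }
  last <- which(degree == 1L)
  edges[k - 1L, ] <- last
  # orient away from root 1 by BFS
  adj <- vector("list", k)
  for (i in seq_len(k - 1L)) {
    a <- edges[i, 1L]; bnd <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], bnd)
    adj[[bnd]] <- c(adj[[bnd]], a)
  }
  parent <- rep(0L, k)
  visited <- logical(k)
  queue <- 1L
  visited[1L] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!visited[w]) {
        parent[w] <- v
        visited[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  parent
}

#' Simulate a ground-truth clonal tree
#'
#' Draws a uniform random labelled rooted tree on `k` nodes, assigns a
#' truncal share of the SNVs to the root and spreads the rest uniformly over
#' the non-root nodes, draws clone proportions from a symmetric Dirichlet
#' (redrawn until every clone holds at least `min_clone_frac` of cells), and
#' (with `cna_mode`) lets every non-root edge acquire 1-3 segmental
#' allele-specific copy-number events (single-allele gain or loss over a
#' contiguous bin range, capped at `max_copies` total). Each SNV is placed
#' in a random bin on a random allele, so its variant copy number in a clone
#' follows that allele's copy state. Under the Dollo mode each SNV is
#' additionally lost, with small probability, on one random edge below its
#' gain node.
#'
#' @param config a [sim_config].
#' @return an object of class `clone_ground_truth`: list with `tree` (a
#'   [clonal_tree]; attachments and cell assignments are the simulated
#'   truth), `Y` (k x m cell-free clonal genotypes, equal to the tree's
#'   genotypes minus Dollo losses), allele-specific bin `profiles` (list of
#'   two k x b matrices), per-SNV per-node variant and total copy matrices
#'   `x_copies`, `y_copies`, `snv_bin`, `snv_allele`, and the `config`.
#' @export
simulate_ground_truth <- function(config) {
  withr::with_seed(config$seed, simulate_ground_truth_(config))
}

simulate_ground_truth_ <- function(cfg) {
  k <- cfg$k; m <- cfg$m; n <- cfg$n; b <- cfg$b
  parent <- random_rooted_tree(k)
  # SNV attachments: truncal share at the root, rest uniform over non-root
  n_truncal <- round(cfg$truncal_fraction * m)
  attach <- integer(m)
  truncal <- if (n_truncal > 0) sample.int(m, n_truncal) else integer(0)
  attach[truncal] <- 1L
  rest <- setdiff(seq_len(m), truncal)
  if (k > 1L) {
    attach[rest] <- sample(2:k, length(rest), replace = TRUE)
  } else {
    attach[rest] <- 1L
  }
  # clone proportions with a minimum clone fraction
  repeat {
    props <- rdirichlet1(k, cfg$dirichlet_conc)
    if (min(props) >= cfg$min_clone_frac) break
  }
  repeat {
    sizes <- as.integer(stats::rmultinom(1, n, props))
    if (all(sizes > 0L)) break
  }
  cell_node <- sample(rep.int(seq_len(k), sizes))
  tree <- clonal_tree(parent, attach, cell_node,
                      cell_ids = sprintf("cell%04d", seq_len(n)),
                      snv_ids = sprintf("snv%05d", seq_len(m)))
  # allele-specific copy-number profiles per node
  prof1 <- matrix(1L, k, b) # allele 1 copies
  prof2 <- matrix(1L, k, b)
  if (cfg$cna_mode && k > 1L) {
    ord <- order(node_depths(tree)) # parents before children
    for (j in ord) {
      if (parent[j] == 0L) next
      prof1[j, ] <- prof1[parent[j], ]
      prof2[j, ] <- prof2[parent[j], ]
      n_ev <- sample(cfg$events_per_edge[1]:cfg$events_per_edge[2], 1L)
      for (e in seq_len(n_ev)) {
        len <- max(1L, round(stats::runif(1, cfg$event_len_frac[1],
                                          cfg$event_len_frac[2]) * b))
        start <- sample.int(b - len + 1L, 1L)
        rng <- start:(start + len - 1L)
        allele <- sample(1:2, 1L)
        type <- sample(c(-1L, 1L), 1L)
        # an allele at zero copies cannot be amplified back into existence
        if (allele == 1L) {
          cur <- prof1[j, rng]
          newv <- pmin(pmax(cur + type, 0L), cfg$max_copies - prof2[j, rng])
          newv <- pmax(newv, 0L)
          if (type > 0L) newv[cur == 0L] <- 0L
          prof1[j, rng] <- newv
        } else {
          cur <- prof2[j, rng]
          newv <- pmin(pmax(cur + type, 0L), cfg$max_copies - prof1[j, rng])
          newv <- pmax(newv, 0L)
          if (type > 0L) newv[cur == 0L] <- 0L
          prof2[j, rng] <- newv
        }
      }
    }
  }
  snv_bin <- sample.int(b, m, replace = TRUE)
  snv_allele <- sample(1:2, m, replace = TRUE)
  Y <- genotypes(tree)
  loss_edges <- rep(NA_integer_, m)
  if (cfg$evolution == "dollo" && k > 1L) {
    M <- anc_or_self(tree)
    for (q in seq_len(m)) {
      if (stats::runif(1) > cfg$dollo_loss_prob) next
      below <- setdiff(which(M[attach[q], ]), attach[q])
      if (length(below) == 0L) next
      v <- below[sample.int(length(below), 1L)]
      Y[which(M[v, ]), q] <- 0L
      loss_edges[q] <- v
    }
  }
  # per-SNV copy states per node
  x_copies <- matrix(0L, k, m)
  y_copies <- matrix(0L, k, m)
  for (j in seq_len(k)) {
    tot <- prof1[j, snv_bin] + prof2[j, snv_bin]
    y_copies[j, ] <- tot
    carrier <- ifelse(snv_allele == 1L, prof1[j, snv_bin], prof2[j, snv_bin])
    x_copies[j, ] <- ifelse(Y[j, ] == 1L, carrier, 0L)
  }
  structure(list(tree = tree, Y = Y, profiles = list(prof1, prof2),
                 x_copies = x_copies, y_copies = y_copies,
                 snv_bin = snv_bin, snv_allele = snv_allele,
                 loss_edges = loss_edges, config = cfg),
            class = "clone_ground_truth")
}

#' @export
print.clone_ground_truth <- function(x, ...) {
  cat(sprintf("<clone_ground_truth> k=%d nodes, %d cells, %d SNVs (%s%s)\n",
              n_nodes(x$tree), length(x$tree$cell_node),
              length(x$tree$attach), x$config$evolution,
              if (x$config$cna_mode) ", CNAs on" else ", CNAs off"))
  invisible(x)
}

#' Simulate read counts from a ground truth
#'
#' Total reads at SNV locus `q` in a cell of clone `j` are
#' `d ~ Poisson(g * y[j, q] / 2)`, proportional to the locus's total copy
#' number; variant reads are `a ~ Binom(d, vaf')` with
#' `vaf' = (x/y)(1 - alpha) + (1 - x/y) alpha` for genotype-1 clones and
#' `vaf' = alpha` otherwise. Binned counts are
#' `r ~ Poisson(g * bin_factor * total_copies / 2)`. Sampling exploits
#' sparsity: the number of covered entries per (clone, copy-state) block is
#' drawn first, then positions and zero-truncated Poisson depths.
#'
#' @param gt a `clone_ground_truth` from [simulate_ground_truth()].
#' @param config optional [sim_config]; defaults to `gt$config`.
#' @return a [read_count_data] with `A`, `D` and binned counts `R`.
#' @export
simulate_reads <- function(gt, config = NULL) {
  cfg <- config %||% gt$config
  withr::with_seed(cfg$seed + 500000L, simulate_reads_(gt, cfg))
}

simulate_reads_ <- function(gt, cfg) {
  k <- n_nodes(gt$tree); n <- cfg$n; m <- cfg$m
  alpha <- cfg$alpha
  ii <- integer(0); jj <- integer(0); dd <- integer(0); aa <- integer(0)
  for (j in seq_len(k)) {
    cells_j <- which(gt$tree$cell_node == j)
    nj <- length(cells_j)
    if (nj == 0L) next
    key <- paste(gt$x_copies[j, ], gt$y_copies[j, ])
    for (g_key in unique(key)) {
      qs <- which(key == g_key)
      x <- gt$x_copies[j, qs[1]]
      y <- gt$y_copies[j, qs[1]]
      if (y == 0L) next # homozygous deletion: no reads
      lambda <- cfg$g * y / 2
      p_cov <- 1 - exp(-lambda)
      N <- as.numeric(nj) * length(qs)
      nnz <- stats::rbinom(1L, N, p_cov)
      if (nnz == 0L) next
      pos <- sample(N, nnz) - 1
      ci <- cells_j[(pos %% nj) + 1L]
      qi <- qs[(pos %/% nj) + 1L]
      # zero-truncated Poisson depths
      u <- stats::runif(nnz, exp(-lambda), 1)
      d <- stats::qpois(u, lambda)
      d <- pmax(d, 1L)
      vaf <- x / y
      vafp <- vaf * (1 - alpha) + (1 - vaf) * alpha
      a <- stats::rbinom(nnz, d, vafp)
      ii <- c(ii, ci); jj <- c(jj, qi); dd <- c(dd, d); aa <- c(aa, a)
    }
  }
  keep_a <- aa > 0
  A <- Matrix::sparseMatrix(i = ii[keep_a], j = jj[keep_a], x = aa[keep_a],
                            dims = c(n, m))
  D <- Matrix::sparseMatrix(i = ii, j = jj, x = dd, dims = c(n, m))
  # binned counts
  tot <- gt$profiles[[1]] + gt$profiles[[2]] # k x b total copies
  R <- matrix(0L, n, cfg$b)
  for (j in seq_len(k)) {
    cells_j <- which(gt$tree$cell_node == j)
    if (length(cells_j) == 0L) next
    lam <- cfg$g * cfg$bin_factor * tot[j, ] / 2
    R[cells_j, ] <- stats::rpois(length(cells_j) * cfg$b,
                                 rep(lam, each = length(cells_j)))
  }
  read_count_data(A, D, R = R, cell_ids = gt$tree$cell_ids,
                  snv_ids = gt$tree$snv_ids,
                  bin_ids = paste0("bin", seq_len(cfg$b)))
}

#' Simulate a full instance (ground truth plus reads)
#'
#' @param config a [sim_config].
#' @return list with `truth` (a `clone_ground_truth`) and `data`
#'   (a [read_count_data]).
#' @export
simulate_instance <- function(config) {
  truth <- simulate_ground_truth(config)
  list(truth = truth, data = simulate_reads(truth, config))
}
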