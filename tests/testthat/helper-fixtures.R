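# Hand-built toy read-count data: counts given as dense matrices.
toy_data <- function(A, D, R = NULL, cell_ids = NULL, snv_ids = NULL) {
  read_count_data(Matrix::Matrix(A, sparse = TRUE),
                  Matrix::Matrix(D, sparse = TRUE),
                  R = R, cell_ids = cell_ids, snv_ids = snv_ids)
}

# A small planted two-clone chain instance (root clone + descendant clone)
# with strong signal, for operation-level tests.
small_chain_instance <- function(seed = 42, n = 300, m = 800, g = 0.1,
                                 k = 2, b = 200) {
  simulate_instance(sim_config(k = k, n = n, m = m, g = g, b = b,
                               seed = seed))
}

# Random clonal tree over given items, used by metric oracles.
random_placement_tree <- function(k, n_cells, m_snvs, seed) {
  withr::with_seed(seed, {
    parent <- if (k == 1) 0L else c(0L, sapply(2:k, function(j) sample.int(j - 1L, 1L)))
    clonal_tree(parent,
                attach = sample.int(k, m_snvs, replace = TRUE),
                cell_node = sample.int(k, n_cells, replace = TRUE))
  })
}

# Brute-force pair-recall oracle: enumerates every ordered/unordered pair
# with pair_relation(); independent of the contingency-table implementation.
oracle_recall <- function(truth, inferred, what) {
  n_items <- if (what == "snv") length(truth$attach) else length(truth$cell_node)
  rel <- function(tree, i, j) {
    r <- pair_relation(tree, c(i, j), what)
    if (r == "ancestral" && !attr(r, "first_is_ancestor")) "descendant" else as.character(r)
  }
  anc_tot <- 0; anc_hit <- 0; inc_tot <- 0; inc_hit <- 0
  clu_tot <- 0; clu_hit <- 0
  for (i in seq_len(n_items)) for (j in seq_len(n_items)) {
    if (i == j) next
    rt <- rel(truth, i, j)
    ri <- rel(inferred, i, j)
    if (rt == "ancestral") { # ordered
      anc_tot <- anc_tot + 1
      if (ri == "ancestral") anc_hit <- anc_hit + 1
    }
    if (i < j) { # unordered classes
      if (rt == "clustered") { clu_tot <- clu_tot + 1; if (ri == "clustered") clu_hit <- clu_hit + 1 }
      if (rt == "incomparable") { inc_tot <- inc_tot + 1; if (ri == "incomparable") inc_hit <- inc_hit + 1 }
    }
  }
  w <- c(anc_tot, inc_tot, clu_tot)
  r <- c(ifelse(anc_tot > 0, anc_hit / anc_tot, NA),
         ifelse(inc_tot > 0, inc_hit / inc_tot, NA),
         ifelse(clu_tot > 0, clu_hit / clu_tot, NA))
  list(apr = r[1], ipr = r[2], cpr = r[3],
       accuracy = sum(w[w > 0] * r[w > 0]) / sum(w[w > 0]))
}

# Exhaustive minimum Ncut over all bipartitions (n <= 14), sharing the
# kernel definition but not the spectral solver.
oracle_min_ncut <- function(features, sigma) {
  n <- nrow(features)
  d2 <- as.matrix(stats::dist(features))^2
  W <- exp(-d2 / (2 * sigma^2))
  deg <- rowSums(W)
  tot <- sum(deg)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    side <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    aL <- sum(deg[side]); aR <- tot - aL
    cut <- sum(W[side, !side])
    val <- cut / aL + cut / aR
    if (val < best) best <- val
  }
  best
}
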