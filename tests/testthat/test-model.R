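test_that("entry log-likelihoods match closed forms and the state-sum oracle", {
  p <- model_params(alpha = 0.001, max_copies = 2)
  # no coverage carries no information under either genotype
  expect_equal(snv_entry_loglik(0, 0, 0, p), 0)
  expect_equal(snv_entry_loglik(0, 0, 1, p), 0)
  # a single variant read under genotype 0 is a sequencing error
  expect_equal(snv_entry_loglik(1, 1, 0, p), log(0.001))
  # genotype 1 marginalizes over allele-specific copy states: brute force
  states <- list(c(1, 1), c(1, 2), c(2, 2))
  vaf <- vapply(states, function(s) s[1] / s[2], 1)
  vafp <- vaf * (1 - p$alpha) + (1 - vaf) * p$alpha
  for (obs in list(c(1, 2), c(0, 3), c(2, 2))) {
    manual <- log(mean(dbinom(obs[1], obs[2], vafp)))
    expect_equal(snv_entry_loglik(obs[1], obs[2], 1, p), manual,
                 tolerance = 1e-12)
  }
  expect_error(snv_entry_loglik(3, 2, 0, p), "exceed")
  expect_error(model_params(alpha = 0), "alpha")
})

test_that("copy state set enumerates x in 1..y up to max copies", {
  st <- copy_state_set(3, 0.001)
  expect_equal(nrow(st), 6L) # (1,1),(1,2),(2,2),(1,3),(2,3),(3,3)
  expect_true(all(st$x >= 1 & st$x <= st$y))
  expect_equal(sum(st$prior), 1)
})

test_that("embedding log-likelihood equals the direct normal density sum", {
  withr::with_seed(3, {
    rows <- matrix(rnorm(10), 5, 2)
    ctr <- c(0.3, -0.2)
  })
  manual <- sum(dnorm(rows[, 1], ctr[1], 0.7, log = TRUE)) +
    sum(dnorm(rows[, 2], ctr[2], 0.7, log = TRUE))
  expect_equal(embedding_loglik(rows, ctr, 0.7), manual, tolerance = 1e-10)
  # symmetric cells contribute equally
  sym <- rbind(c(1, 0), c(-1, 0))
  expect_equal(embedding_loglik(sym[1, , drop = FALSE], c(0, 0), 1),
               embedding_loglik(sym[2, , drop = FALSE], c(0, 0), 1))
  expect_error(embedding_loglik(rows[0, , drop = FALSE], ctr, 1), "no cells")
  expect_error(embedding_loglik(rows, ctr, 0), "positive")
})

test_that("tree log-posterior matches a brute-force evaluation on a toy", {
  # 4 cells, 3 SNVs, 2-node chain; counts chosen by hand
  A <- rbind(c(1, 0, 0), c(1, 0, 1), c(1, 1, 0), c(0, 1, 1))
  D <- rbind(c(2, 0, 1), c(1, 1, 1), c(2, 2, 0), c(0, 2, 1))
  d <- toy_data(A, D)
  p <- model_params(alpha = 0.01, max_copies = 2)
  tr <- clonal_tree(parent = c(0L, 1L), attach = c(1L, 2L, 2L),
                    cell_node = c(1L, 1L, 2L, 2L))
  Y <- genotypes(tr)
  manual <- 0
  for (i in 1:4) for (q in 1:3) {
    manual <- manual +
      snv_entry_loglik(A[i, q], D[i, q], Y[tr$cell_node[i], q], p)
  }
  manual <- manual - 3 * log(2) # uniform attachment prior over 2 nodes
  expect_equal(tree_log_posterior(tr, d, p), manual, tolerance = 1e-9)
  # with all d = 0 the read term vanishes exactly
  d0 <- toy_data(matrix(0, 2, 2), matrix(0, 2, 2))
  tr0 <- init_tree(d0)
  expect_equal(tree_log_posterior(tr0, d0, p), 0)
})

test_that("claiming absence of a fully-supported SNV lowers the posterior", {
  A <- rbind(c(1), c(1))
  D <- rbind(c(1), c(1))
  d <- toy_data(A, D)
  p <- model_params(alpha = 0.01, max_copies = 2)
  present <- clonal_tree(parent = 0L, attach = 1L, cell_node = c(1L, 1L))
  tr2 <- clonal_tree(parent = c(0L, 1L), attach = 2L, cell_node = c(2L, 2L))
  absent_root <- clonal_tree(parent = c(0L, 1L), attach = 2L,
                             cell_node = c(1L, 1L))
  expect_gt(tree_log_posterior(tr2, d, p),
            tree_log_posterior(absent_root, d, p))
})

test_that("SNV assignment finds the argmax attachment", {
  # branching tree: root (1) with children 2 and 3
  parent <- c(0L, 1L, 1L)
  # SNV 1: reads only in left-child cells -> left child
  # SNV 2: reads in cells of both children -> root (clonal)
  # SNV 3: zero coverage anywhere -> root by the ancestral tie-break
  A <- rbind(c(2, 1, 0), c(1, 0, 0), c(0, 1, 0), c(0, 1, 0))
  D <- rbind(c(2, 1, 0), c(2, 1, 0), c(1, 1, 0), c(0, 1, 0))
  d <- toy_data(A, D)
  p <- model_params(alpha = 0.001)
  tr <- clonal_tree(parent, attach = rep(1L, 3), cell_node = c(2L, 2L, 3L, 3L))
  out <- assign_snvs(tr, d, p)
  expect_equal(out$attach, c(2L, 1L, 1L))
  # exhaustive check: the chosen attachment maximizes the posterior
  pre <- clonegrower:::model_precompute(d, p)
  for (q in 1:3) {
    scores <- sapply(1:3, function(v) {
      cand <- tr; cand$attach[] <- out$attach; cand$attach[q] <- v
      tree_log_posterior(cand, d, p, precomp = pre)
    })
    expect_equal(max(scores), scores[out$attach[q]], tolerance = 1e-9)
  }
})

test_that("assign_snvs never decreases the posterior on random toys", {
  worst <- 0
  for (rep in 1:100) {
    withr::with_seed(500 + rep, {
      k <- sample(2:4, 1)
      n <- sample(4:8, 1)
      m <- sample(3:6, 1)
      parent <- if (k == 1) 0L else c(0L, sapply(2:k, function(j) sample.int(j - 1, 1)))
      D <- matrix(rpois(n * m, 0.8), n, m)
      A <- matrix(rbinom(n * m, D, 0.4), n, m)
      tr <- clonal_tree(parent, attach = sample.int(k, m, replace = TRUE),
                        cell_node = sample.int(k, n, replace = TRUE))
    })
    d <- toy_data(A, D)
    p <- model_params(alpha = 0.005, max_copies = 3)
    pre <- clonegrower:::model_precompute(d, p)
    before <- tree_log_posterior(tr, d, p, precomp = pre)
    after <- tree_log_posterior(assign_snvs(tr, d, p, precomp = pre), d, p,
                                precomp = pre)
    worst <- min(worst, after - before)
  }
  expect_gte(worst, -1e-9)
})

test_that("posterior is invariant to cell order within clones", {
  inst <- small_chain_instance(seed = 9, n = 60, m = 100, g = 0.2, b = 50)
  d <- inst$data
  p <- model_params()
  tr <- inst$truth$tree
  lp1 <- tree_log_posterior(tr, d, p)
  # permute cells within each clone (data rows move with their labels)
  perm <- order(tr$cell_node, withr::with_seed(1, runif(length(tr$cell_node))))
  d2 <- read_count_data(d$A[perm, ], d$D[perm, ], R = d$R[perm, ],
                        cell_ids = d$cell_ids[perm], snv_ids = d$snv_ids)
  tr2 <- tr
  tr2$cell_node <- tr$cell_node[perm]
  tr2$cell_ids <- tr$cell_ids[perm]
  expect_equal(tree_log_posterior(tr2, d2, p), lp1, tolerance = 1e-8)
})
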