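test_that("combined feature applies the missing-data and identity conventions", {
  E <- matrix(c(0, 0, 1, 1, 0, 0, 1, 1), 4, 2)
  A <- rbind(c(1, 0), c(1, 0), c(0, 0), c(0, 0))
  D <- rbind(c(1, 1), c(1, 1), c(1, 1), c(0, 0))
  d <- toy_data(A, D)
  f <- combined_feature(E, d$A, d$D, cells = 1:4, snv_set = 1:2)
  expect_equal(ncol(f), 3L) # l + 1
  # cells 1 and 2 share embedding rows and counts -> identical features
  expect_equal(f[1, ], f[2, ])
  # cell 4 covers nothing: flagged, imputed at the cohort mean
  expect_true(attr(f, "missing")[4])
  expect_false(any(attr(f, "missing")[1:3]))
  # empty SNV set degenerates to embedding-only features
  f0 <- combined_feature(E, d$A, d$D, cells = 1:4, snv_set = integer(0))
  expect_equal(ncol(f0), 2L)
})

test_that("normalized cut isolates effectively disconnected components", {
  # unbalanced groups so the median-distance bandwidth reflects the
  # within-group scale, making the between-group similarity vanish
  withr::with_seed(21, {
    X <- rbind(matrix(rnorm(14 * 2, 0, 1), 14, 2),
               matrix(rnorm(4 * 2, 40, 1), 4, 2))
  })
  cut <- ncut_bipartition(X, seed = 1)
  small <- if (length(cut$left) < length(cut$right)) cut$left else cut$right
  expect_equal(sort(small), 15:18)
  expect_lt(cut$ncut, 1e-4)
})

test_that("normalized cut is deterministic and respects duplicated cells", {
  withr::with_seed(8, X <- matrix(rnorm(24), 12, 2))
  c1 <- ncut_bipartition(X, seed = 3)
  c2 <- ncut_bipartition(X, seed = 3)
  expect_identical(c1, c2)
  # duplicating every row keeps duplicates co-assigned
  Xd <- rbind(X, X)
  cd <- ncut_bipartition(Xd, seed = 3)
  for (i in 1:12) {
    expect_equal(i %in% cd$left, (i + 12) %in% cd$left)
  }
  # identical features flag the no-signal degenerate case
  cs <- ncut_bipartition(matrix(1, 6, 2), seed = 1)
  expect_true(cs$no_signal)
  expect_equal(sort(c(cs$left, cs$right)), 1:6)
  expect_true(length(cs$left) > 0 && length(cs$right) > 0)
})

test_that("sweep cut is near the exhaustive Ncut optimum on small instances", {
  hits <- 0
  trials <- 20
  for (i in seq_len(trials)) {
    withr::with_seed(3000 + i, X <- matrix(rnorm(10 * 3), 10, 3))
    cut <- ncut_bipartition(X, seed = 1)
    best <- oracle_min_ncut(X, cut$sigma)
    if (cut$ncut <= best * 1.05 + 1e-12) hits <- hits + 1
  }
  expect_gte(hits / trials, 0.95)
})

test_that("identity operation is idempotent and preserves the posterior", {
  inst <- small_chain_instance(seed = 13, n = 80, m = 120, g = 0.2, b = 60)
  p <- model_params()
  tr <- init_tree(inst$data)
  r1 <- identity_op(tr, 1L, inst$data, p)
  expect_identical(r1$tree, tr)
  expect_equal(r1$log_posterior,
               tree_log_posterior(tr, inst$data, p), tolerance = 1e-9)
  r2 <- identity_op(r1$tree, 1L, inst$data, p)
  expect_identical(r2$tree, r1$tree)
  expect_equal(r2$log_posterior, r1$log_posterior)
})

test_that("linear operation recovers a planted two-clone chain", {
  inst <- small_chain_instance(seed = 42, n = 300, m = 800, g = 0.1, b = 200)
  p <- model_params(restarts = 5, seed = 7)
  res <- linear_op(init_tree(inst$data), 1L, inst$data, p)
  expect_true(res$applicable)
  expect_equal(n_nodes(res$tree), 2L)
  truth <- inst$truth$tree$cell_node
  pred <- res$tree$cell_node
  acc <- max(mean((pred == 1L) == (truth == 1L)),
             mean((pred == 1L) == (truth == 2L)))
  expect_gt(acc, 0.9)
  # descendant-orientation: the child carries the clone with extra gains
  child_truth <- names(which.max(table(truth[pred == 2L])))
  expect_equal(child_truth, "2")
  # planted SNV gains largely recovered at the child
  gains_true <- which(inst$truth$tree$attach == 2L)
  gains_inf <- which(res$tree$attach == 2L)
  expect_gt(length(intersect(gains_true, gains_inf)) / length(gains_true), 0.8)
})

test_that("branching operation separates a planted three-clone star", {
  inst <- simulate_instance(sim_config(k = 3, n = 300, m = 900, g = 0.1,
                                       b = 200, seed = 77))
  # force a star: use instances where the truth is root with two children
  tr_true <- inst$truth$tree
  p <- model_params(restarts = 5, seed = 3)
  res <- branching_op(init_tree(inst$data), 1L, inst$data, p)
  expect_true(res$applicable)
  expect_equal(n_nodes(res$tree), 3L)
  expect_equal(sum(res$tree$cell_node == 1L), 0L) # parent holds no cells
  # mirror symmetry: swapping the children leaves the posterior unchanged
  swap <- res$tree
  swap$cell_node <- c(1L, 3L, 2L)[swap$cell_node]
  swap$attach <- c(1L, 3L, 2L)[swap$attach]
  expect_equal(tree_log_posterior(swap, inst$data, p),
               res$log_posterior, tolerance = 1e-8)
})

test_that("elementary results keep ascent within the restart trace", {
  inst <- small_chain_instance(seed = 50, n = 150, m = 300, g = 0.1, b = 100)
  p <- model_params(restarts = 3, max_iter = 10, seed = 5)
  res <- linear_op(init_tree(inst$data), 1L, inst$data, p)
  # rerunning with a single iteration cannot beat the converged result
  p1 <- model_params(restarts = 3, max_iter = 1, seed = 5)
  res1 <- linear_op(init_tree(inst$data), 1L, inst$data, p1)
  expect_gte(res$log_posterior, res1$log_posterior - 1e-9)
})

test_that("operations signal inapplicable leaves instead of failing", {
  d <- toy_data(A = rbind(1), D = rbind(1))
  d$R <- matrix(1, 1, 3)
  tr <- init_tree(d)
  res <- linear_op(tr, 1L, d, model_params(),
                   embedding = matrix(0, 1, 2))
  expect_false(res$applicable)
  expect_identical(res$tree, tr)
})
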