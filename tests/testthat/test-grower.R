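test_that("initialization assigns all cells and SNVs to the root", {
  d <- toy_data(A = matrix(0, 5, 3), D = matrix(1, 5, 3))
  tr <- init_tree(d)
  expect_equal(n_nodes(tr), 1L)
  expect_equal(unname(genotypes(tr)[1, ]), rep(1L, 3))
  expect_equal(sum(tr$cell_node == 1L), 5L)
  expect_true(is.finite(tree_log_posterior(tr, d, model_params())))
  # no randomness consumed
  withr::with_seed(1, r1 <- runif(1))
  withr::with_seed(1, { init_tree(d); r2 <- runif(1) })
  expect_identical(r1, r2)
  expect_error(init_tree(list(cell_ids = character(0), snv_ids = character(0))),
               "at least one")
})

test_that("detectability follows the mean-covering-cells rule", {
  # 100 cells, 10 SNVs each covered in exactly 5 cells of the clone
  D <- matrix(0, 100, 10)
  for (q in 1:10) D[((q - 1) * 5 + 1):(q * 5), q] <- 1
  Ds <- Matrix::Matrix(D, sparse = TRUE)
  expect_true(is_detectable(1:100, 1:10, Ds, t = 5))
  expect_false(is_detectable(1:100, 1:10, Ds, t = 7))
  # empty gain set or zero coverage is never detectable
  expect_false(is_detectable(1:100, integer(0), Ds, t = 1))
  expect_false(is_detectable(integer(0), 1:10, Ds, t = 1))
  expect_false(is_detectable(1:100, 1:10, Matrix::Matrix(0, 100, 10, sparse = TRUE), t = 1))
})

test_that("quality check bounds the outside-clade mutational burden", {
  # chain root -> child; child gains SNVs 1:2
  tr <- clonal_tree(parent = c(0L, 1L), attach = c(2L, 2L, 1L),
                    cell_node = c(1L, 1L, 2L, 2L))
  # outside cells (1, 2) have no variant reads on the gain set -> pass
  A <- rbind(c(0, 0, 1), c(0, 0, 0), c(1, 1, 0), c(1, 0, 1))
  D <- rbind(c(1, 1, 1), c(1, 0, 1), c(1, 1, 1), c(1, 1, 1))
  expect_true(quality_check(tr, toy_data(A, D), qc = 0.025))
  # half the outside burden present -> fail
  A2 <- rbind(c(1, 0, 1), c(1, 0, 0), c(1, 1, 0), c(1, 0, 1))
  expect_false(quality_check(tr, toy_data(A2, D), qc = 0.05))
  # no outside cell covers the gain set -> vacuous pass
  D3 <- rbind(c(0, 0, 1), c(0, 0, 1), c(1, 1, 1), c(1, 1, 1))
  A3 <- rbind(c(0, 0, 1), c(0, 0, 0), c(1, 1, 0), c(1, 0, 1))
  expect_true(quality_check(tr, toy_data(A3, D3), qc = 0.025))
})

test_that("a single simulated clone yields the one-node tree", {
  inst <- simulate_instance(sim_config(k = 1, n = 120, m = 300, g = 0.1,
                                       b = 80, seed = 31))
  fit <- grow(inst$data, model_params(seed = 2))
  expect_equal(n_nodes(fit$tree), 1L)
  expect_equal(n_clones(fit$tree), 1L)
})

test_that("a two-clone chain is recovered with accurate cells and gains", {
  inst <- small_chain_instance(seed = 42, n = 300, m = 800, g = 0.1, b = 200)
  fit <- grow(inst$data, model_params(restarts = 5, seed = 7))
  expect_equal(n_clones(fit$tree), 2L)
  m <- recall_metrics(inst$truth, fit)
  expect_gt(m$cell_accuracy, 0.9)
  expect_gt(m$genotype_similarity, 0.9)
})

test_that("growth is reproducible given the seed", {
  inst <- small_chain_instance(seed = 15, n = 200, m = 400, g = 0.1, b = 100)
  f1 <- grow(inst$data, model_params(restarts = 3, seed = 5))
  f2 <- grow(inst$data, model_params(restarts = 3, seed = 5))
  expect_identical(f1$tree, f2$tree)
  expect_identical(f1$log_posterior, f2$log_posterior)
  expect_identical(f1$candidates, f2$candidates)
})

test_that("every enumerated candidate satisfies the clonal tree invariants", {
  inst <- simulate_instance(sim_config(k = 3, n = 250, m = 600, g = 0.1,
                                       b = 150, seed = 23))
  fit <- grow(inst$data, model_params(restarts = 3, seed = 9))
  for (tr in fit$candidate_trees) {
    expect_silent(validate_clonal_tree(tr, deep = TRUE))
    # cells partition over nodes
    expect_equal(length(tr$cell_node), 250L)
    expect_true(all(tr$cell_node >= 1 & tr$cell_node <= n_nodes(tr)))
  }
  expect_silent(validate_clonal_tree(fit$tree, deep = TRUE))
})

test_that("post-processing never lowers the posterior and contracts dead nodes", {
  inst <- small_chain_instance(seed = 33, n = 200, m = 400, g = 0.1, b = 100)
  p <- model_params(restarts = 3, seed = 4)
  res <- branching_op(init_tree(inst$data), 1L, inst$data, p)
  lp0 <- res$log_posterior
  pp <- post_process(res$tree, inst$data, p)
  expect_gte(pp$log_posterior, lp0 - 1e-6)
  expect_silent(validate_clonal_tree(pp$tree, deep = TRUE))
  # a gain-free, cell-free intermediate node is contracted away
  tr <- clonal_tree(parent = c(0L, 1L, 2L), attach = c(1L, 3L),
                    cell_node = rep(c(1L, 3L), each = 2))
  out <- clonegrower:::contract_empty_nodes(tr)
  expect_equal(n_nodes(out), 2L)
  expect_equal(out$parent, c(0L, 1L))
})

test_that("raising the detectability threshold cannot add clones", {
  for (s in c(61, 62)) {
    inst <- simulate_instance(sim_config(k = 3, n = 300, m = 800, g = 0.1,
                                         b = 150, seed = s))
    k5 <- n_clones(grow(inst$data, model_params(threshold = 5, restarts = 3,
                                                seed = 2))$tree)
    k11 <- n_clones(grow(inst$data, model_params(threshold = 11, restarts = 3,
                                                 seed = 2))$tree)
    expect_lte(k11, k5)
  }
})
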