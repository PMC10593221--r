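test_that("pair relations classify clustered, ancestral and incomparable pairs", {
  # root (1) -> {2, 3}; SNVs: 1,2 at root, 3 at node 2, 4 at node 3
  tr <- clonal_tree(parent = c(0L, 1L, 1L), attach = c(1L, 1L, 2L, 3L),
                    cell_node = c(1L, 2L, 3L))
  expect_equal(as.character(pair_relation(tr, c(1, 2), "snv")), "clustered")
  r <- pair_relation(tr, c(1, 3), "snv")
  expect_equal(as.character(r), "ancestral")
  expect_true(attr(r, "first_is_ancestor"))
  expect_equal(as.character(pair_relation(tr, c(3, 4), "snv")), "incomparable")
  expect_equal(as.character(pair_relation(tr, c(2, 3), "cell")), "incomparable")
  expect_error(pair_relation(tr, c(1, 9), "snv"), "unplaced")
})

test_that("recall metrics are exact against the brute-force pair oracle", {
  for (rep in 1:6) {
    truth <- random_placement_tree(k = 4, n_cells = 15, m_snvs = 20,
                                   seed = 100 + rep)
    inferred <- random_placement_tree(k = 5, n_cells = 15, m_snvs = 20,
                                      seed = 200 + rep)
    got <- recall_metrics(truth, inferred)
    for (what in c("snv", "cell")) {
      oracle <- oracle_recall(truth, inferred, what)
      pre <- paste0(what, "_")
      expect_equal(got[[paste0(pre, "apr")]], oracle$apr, tolerance = 1e-12)
      expect_equal(got[[paste0(pre, "ipr")]], oracle$ipr, tolerance = 1e-12)
      expect_equal(got[[paste0(pre, "cpr")]], oracle$cpr, tolerance = 1e-12)
      expect_equal(got[[paste0(pre, "accuracy")]], oracle$accuracy,
                   tolerance = 1e-12)
    }
  }
})

test_that("perfect inference scores 1 and trivial clustering trades APR for CPR", {
  truth <- random_placement_tree(k = 4, n_cells = 20, m_snvs = 25, seed = 7)
  m <- recall_metrics(truth, truth)
  expect_equal(m$snv_apr, 1)
  expect_equal(m$snv_accuracy, 1)
  expect_equal(m$cell_accuracy, 1)
  expect_equal(m$genotype_similarity, 1)
  # everything in one cluster: CPR = 1, APR = IPR = 0
  one <- clonal_tree(parent = 0L,
                     attach = rep(1L, length(truth$attach)),
                     cell_node = rep(1L, length(truth$cell_node)))
  m1 <- recall_metrics(truth, one)
  expect_equal(m1$snv_cpr, 1)
  expect_equal(m1$snv_apr, 0)
  expect_equal(m1$snv_ipr, 0)
})

test_that("accuracy interpolates its component recalls by pair counts", {
  truth <- random_placement_tree(k = 3, n_cells = 18, m_snvs = 12, seed = 31)
  inferred <- random_placement_tree(k = 3, n_cells = 18, m_snvs = 12, seed = 32)
  m <- recall_metrics(truth, inferred)
  comps <- c(m$snv_apr, m$snv_ipr, m$snv_cpr)
  comps <- comps[!is.na(comps)]
  expect_gte(m$snv_accuracy, min(comps) - 1e-12)
  expect_lte(m$snv_accuracy, max(comps) + 1e-12)
})

test_that("ordered pair classes partition all ordered pairs", {
  tr <- random_placement_tree(k = 5, n_cells = 30, m_snvs = 10, seed = 9)
  n <- 30
  counts <- table(vapply(utils::combn(n, 2, simplify = FALSE), function(pr)
    as.character(pair_relation(tr, pr, "cell")), ""))
  expect_equal(sum(counts), choose(n, 2))
})

test_that("genotype similarity is the cell-level Hamming complement", {
  # four cells; one differs at half of its 10 loci
  Yt <- rbind(rep(1L, 10), c(rep(1L, 5), rep(0L, 5)))
  truth <- list(Y = Yt, cluster = c(1L, 1L, 1L, 2L))
  inferred <- list(Y = Yt[1, , drop = FALSE], cluster = rep(1L, 4))
  expect_equal(genotype_similarity(truth, inferred), 1 - 5 / 40)
  expect_equal(genotype_similarity(inferred, truth), 1 - 5 / 40) # symmetry
  # identical and complementary matrices
  expect_equal(genotype_similarity(truth, truth), 1)
  comp <- list(Y = 1L - Yt, cluster = truth$cluster)
  expect_equal(genotype_similarity(truth, comp), 0)
  expect_error(genotype_similarity(truth, list(Y = Yt[, 1:3], cluster = truth$cluster)),
               "mismatch")
})

test_that("cell mutational burden follows its definition and conventions", {
  A <- rbind(c(1, 0, 2), c(0, 0, 0), c(0, 0, 0))
  D <- rbind(c(1, 1, 2), c(0, 0, 0), c(1, 2, 0))
  d <- toy_data(A, D)
  v <- unname(cmb(d$A, d$D, snv_set = 1:3))
  expect_equal(v[1], 2 / 3)
  expect_true(is.na(v[2])) # no covered locus -> undefined
  expect_equal(v[3], 0)
  expect_error(cmb(d$A, d$D, snv_set = integer(0)), "nonempty")
})

test_that("clade CMB report separates inside from outside cells", {
  inst <- simulate_instance(sim_config(k = 3, n = 200, m = 500, g = 0.2,
                                       b = 100, alpha = 0, seed = 17))
  rep_tbl <- cmb_clade_report(inst$truth$tree, inst$data)
  expect_true(all(c("node", "side", "median") %in% names(rep_tbl)))
  out <- dplyr::filter(rep_tbl, side == "outside", n_defined > 0)
  # error-free reads: cells outside a clade carry none of its SNVs
  expect_true(all(out$median == 0))
  ins <- dplyr::filter(rep_tbl, side == "inside", node != "v1")
  expect_true(all(ins$median > 0))
  # root clade: all cells inside, outside set empty
  root_out <- dplyr::filter(rep_tbl, side == "outside", node == "v1")
  expect_equal(root_out$n_cells, 0L)
  # medians agree with direct recomputation
  v2 <- dplyr::filter(rep_tbl, side == "inside", node == "v2")
  S <- snv_gains(inst$truth$tree, 2L)
  direct <- cmb(inst$data$A, inst$data$D, S, clade_cells(inst$truth$tree, 2L))
  expect_equal(v2$median, stats::median(direct, na.rm = TRUE))
})

test_that("baseline genotyper thresholds pooled ratios strictly", {
  # one cluster forced; pooled ratios: s1 = 1/20 (not > 0.05 -> 0),
  # s2 = 3/50 = 0.06 (> 0.05 -> 1), s3 = 0/0 (undefined -> 0)
  A <- rbind(c(1, 2, 0), c(0, 1, 0))
  D <- rbind(c(10, 30, 0), c(10, 20, 0))
  E <- matrix(rnorm(4), 2, 2)
  out <- baseline_genotyper(E, Matrix::Matrix(A, sparse = TRUE),
                            Matrix::Matrix(D, sparse = TRUE), n_clusters = 1)
  expect_equal(unname(out$Y[1, ]), c(0L, 1L, 0L))
})

test_that("baseline genotyper calls clonal SNVs at realistic coverage", {
  inst <- simulate_instance(sim_config(k = 2, n = 400, m = 300, g = 0.1,
                                       b = 100, seed = 71))
  E <- cell_embedding(inst$data, ndim = 5)
  out <- baseline_genotyper(E, inst$data$A, inst$data$D, n_clusters = 2)
  truncal <- which(inst$truth$tree$attach == 1L)
  expect_gt(mean(out$Y[, truncal] == 1L), 0.95)
})
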