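test_that("canonical correlations reduce to correlations for singletons", {
  for (r in c(-0.7, 0, 0.4, 0.95)) {
    F <- matrix(c(1, r, r, 1), 2)
    expect_equal(canonical_correlations(F, 1, 2)[1], abs(r),
                 tolerance = 1e-10)
  }
  # block-diagonal FIM: orthogonal blocks, all correlations zero
  F <- as.matrix(Matrix::bdiag(random_spd(2, 1), random_spd(2, 2)))
  expect_equal(canonical_correlations(F, 1:2, 3:4), c(0, 0),
               tolerance = 1e-10)
  # rank-1 FIM: perfectly confounded pair
  v <- c(1, 2)
  F1 <- tcrossprod(v)
  expect_equal(canonical_correlations(F1, 1, 2)[1], 1, tolerance = 1e-10)
  expect_error(canonical_correlations(F1, 1, 1), "overlap")
})

test_that("functional redundancy follows the canonical-correlation formula", {
  F <- matrix(c(1, 0.8, 0.8, 1), 2)
  expect_equal(functional_redundancy(F, 1, 2), -0.5 * log(0.36),
               tolerance = 1e-10)
  Fd <- diag(2)
  expect_equal(functional_redundancy(Fd, 1, 2), 0)
  F1 <- tcrossprod(c(1, 3))
  expect_identical(functional_redundancy(F1, 1, 2), Inf)
  # symmetry and invariance to within-set ordering
  F4 <- random_spd(4, 5)
  expect_equal(functional_redundancy(F4, c(1, 2), c(3, 4)),
               functional_redundancy(F4, c(4, 3), c(2, 1)),
               tolerance = 1e-10)
})

test_that("redundancy equals Gaussian block mutual information", {
  # For theta ~ N(0, C) with C = F^{-1}, the canonical correlations of the
  # precision blocks match those of the covariance blocks, so the formula
  # must reproduce the closed-form Gaussian mutual information.
  for (seed in 1:6) {
    F <- random_spd(4, seed)
    C <- solve(F)
    A <- 1:2; B <- 3:4
    expect_rel_equal(functional_redundancy(F, A, B),
                     gaussian_block_mi(C, A, B), rtol = 1e-6)
  }
})

test_that("the (delta, zeta) filter removes flat and confounded directions", {
  F <- diag(c(1, 0.5, 0))
  flt <- identifiability_filter(F, delta = 0.01, zeta = 1e-6)
  expect_equal(flt$removed$parameter, "3")
  expect_equal(flt$removed$reason, "zeta")
  expect_setequal(flt$identifiable, c("1", "2"))

  F1 <- tcrossprod(c(1, 2)) # product-confounded pair
  flt1 <- identifiability_filter(F1, delta = 1e-6, zeta = 1e-8)
  expect_equal(sort(flt1$removed$reason), c("delta", "delta"))
  expect_length(flt1$identifiable, 0)
})

test_that("clustering merges the most redundant pair first", {
  # parameters 1,2 correlated at 0.9; parameter 3 independent
  F <- as.matrix(Matrix::bdiag(matrix(c(1, 0.9, 0.9, 1), 2), 1))
  rownames(F) <- colnames(F) <- c("p1", "p2", "p3")
  tree <- cluster_parameters(F, delta = 1e-6, zeta = 1e-6)
  expect_equal(sort(c(tree$merges$set_a[[1]], tree$merges$set_b[[1]])),
               c("p1", "p2"))
  expect_equal(tree$merges$height[1], -0.5 * log(1 - 0.81),
               tolerance = 1e-10)
  # the independent parameter never merges (zero redundancy stops the loop)
  expect_equal(nrow(tree$merges), 1)
  expect_equal(tree$n_clusters, 2)
  expect_setequal(tree$leaves, c("p1", "p2", "p3"))
})

test_that("confounded pairs are removed before any merge", {
  F <- as.matrix(Matrix::bdiag(tcrossprod(c(1, 2)),
                               matrix(c(1, 0.5, 0.5, 1), 2)))
  rownames(F) <- colnames(F) <- paste0("p", 1:4)
  tree <- cluster_parameters(F, delta = 1e-6, zeta = 1e-8)
  expect_setequal(tree$removed$parameter, c("p1", "p2"))
  expect_true(all(tree$removed$step == 0))
  expect_setequal(tree$leaves, c("p3", "p4"))
  expect_setequal(
    c(tree$merges$set_a[[1]], tree$merges$set_b[[1]]), c("p3", "p4"))
  # removed and clustered partition the parameter set
  td <- tidy(tree)
  expect_setequal(td$parameter, paste0("p", 1:4))
  expect_equal(sum(!td$identifiable), 2)
})

test_that("cluster assignment is robust to 1 percent parameter jitter", {
  base <- make_linear_chain(4, 2, 1)
  ref <- NULL
  for (rep in 1:3) {
    set.seed(rep)
    jit <- base
    for (key in names(jit$params)) {
      jit <- set_param(jit, key, jit$params[[key]] * (1 + 0.01 * runif(1, -1, 1)))
    }
    fim <- fisher_information(jit, horizon = 40)
    tree <- cluster_parameters(fim, delta = 1e-6, zeta = 1e-6)
    memb <- tidy(tree) |> dplyr::arrange(parameter)
    if (is.null(ref)) ref <- memb else {
      expect_equal(memb$cluster, ref$cluster)
      expect_equal(memb$identifiable, ref$identifiable)
    }
  }
})

test_that("dendrogram export produces a valid tree with all leaves", {
  F <- random_spd(5, 9)
  # soften into a correlated but full-rank matrix
  F <- F + diag(5)
  rownames(F) <- colnames(F) <- paste0("q", 1:5)
  tree <- cluster_parameters(F, delta = 1e-9, zeta = 1e-9)
  if (nrow(tree$merges) == length(tree$leaves) - 1) {
    hc <- as_hclust(tree)
    expect_s3_class(hc, "hclust")
    expect_setequal(hc$labels, tree$leaves)
    path <- tempfile(fileext = ".nwk")
    write_newick(tree, path)
    tr <- ape::read.tree(path)
    expect_setequal(tr$tip.label, tree$leaves)
    ct <- cut_redundancy_tree(tree, k = 2)
    expect_equal(length(unique(ct$cluster)), 2)
  }
})
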