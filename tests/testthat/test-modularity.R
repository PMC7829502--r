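two_cliques <- function() {
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- 1
  A[3, 4] <- A[4, 3] <- 1
  A
}

test_that("multilayer assembly zeroes negative weights and sums strengths", {
  L <- matrix(c(0, 0.5, 0.5, 0), 2)
  L2 <- matrix(c(0, -0.3, -0.3, 0), 2)
  mg <- build_multilayer(list(L, L + 0.2))
  expect_equal(mg$layers[[1]][1, 2], 0.5)
  expect_error(build_multilayer(list(L, L2)), "layer 2 has no positive")
  mg2 <- build_multilayer(list(two_cliques()))
  expect_equal(mg2$strength[, 1], rep(1, 4))
  expect_equal(mg2$two_m, 4)
  # omega = 0: coupling contributes nothing to mu
  mg3 <- build_multilayer(list(two_cliques(), two_cliques()))
  expect_equal(two_mu(mg3, modularity_params(1, 0)), 8)
  expect_equal(two_mu(mg3, modularity_params(1, 1)), 8 + 2 * 4 * 1)
})

test_that("modularity of the two-clique layer matches hand evaluation", {
  mg <- build_multilayer(list(two_cliques()))
  p <- modularity_params(1, 0)
  labs <- matrix(c(1, 1, 2, 2), 4, 1)
  expect_equal(modularity_q(mg, labs, p), 0.5)
  # label-permutation invariance
  expect_equal(modularity_q(mg, matrix(c(7, 7, 3, 3), 4, 1), p), 0.5)
  # agreement with the independent entry-by-entry oracle
  supra <- oracle_supra(list(two_cliques()), 1, 0)
  expect_equal(modularity_q(mg, labs, p), oracle_q(supra, c(1, 1, 2, 2)))
})

test_that("identical layers with omega 0 reduce to summed single-layer q", {
  A <- two_cliques()
  p0 <- modularity_params(1, 0)
  mg2 <- build_multilayer(list(A, A))
  labs <- matrix(1, 4, 2)   # everything in one module
  supra <- oracle_supra(list(A, A), 1, 0)
  expect_equal(modularity_q(mg2, labs, p0), oracle_q(supra, rep(1, 8)))
  # and for the planted split as well
  labs2 <- matrix(c(1, 1, 2, 2), 4, 2)
  expect_equal(modularity_q(mg2, labs2, p0),
               oracle_q(supra, rep(c(1, 1, 2, 2), 2)))
})

test_that("the optimizer recovers planted toy structure", {
  # single node-layer copy: one module, deterministically
  mg1 <- build_multilayer(list(matrix(c(0, 1, 1, 0), 2)))
  part1 <- louvain_run(mg1, modularity_params(1, 1, seed = 1))
  expect_equal(length(unique(as.vector(part1$labels))), 1L)
  # two-clique layer: {12|34} is the exhaustive optimum
  mg <- build_multilayer(list(two_cliques()))
  p <- modularity_params(1, 0, n_runs = 5, seed = 2)
  best <- max(partition_ensemble(mg, p)$q)
  expect_equal(best, 0.5)
  expect_equal(best, oracle_max_q(list(two_cliques()), 1, 0))
  # 3 nodes x 2 identical layers, omega 1: labels align across layers
  A3 <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3)
  A3[3, 1] <- A3[1, 3] <- 0.2
  mg3 <- build_multilayer(list(A3, A3))
  part3 <- louvain_run(mg3, modularity_params(1, 1, seed = 3))
  expect_equal(part3$labels[, 1], part3$labels[, 2])
})

test_that("optimizer q always agrees with the independent evaluator", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:4, 1); T <- sample(1:3, 1)
    layers <- random_layers(n, T)
    gamma <- runif(1, 0.6, 1.4); omega <- runif(1, 0, 1.5)
    mg <- build_multilayer(layers)
    p <- modularity_params(gamma, omega)
    part <- louvain_run(mg, p, seed = rep)
    expect_equal(part$q, modularity_q(mg, part$labels, p),
                 tolerance = 1e-12)
  }
})

test_that("omega 0 decouples layers; huge omega freezes labels", {
  A <- two_cliques()
  B <- matrix(0, 4, 4); B[1, 3] <- B[3, 1] <- 1; B[2, 4] <- B[4, 2] <- 1
  mg <- build_multilayer(list(A, B))
  p0 <- modularity_params(1, 0, n_runs = 10, seed = 4)
  part <- partition_ensemble(mg, p0)
  best <- part$partitions[[which.max(part$q)]]
  # per-layer structure equals independently optimized single layers
  for (s in 1:2) {
    mgs <- build_multilayer(list(list(A, B)[[s]]))
    qs <- max(partition_ensemble(mgs, p0)$q)
    ps <- modularity_params(1, 0)
    expect_equal(modularity_q(mgs, best$labels[, s, drop = FALSE], ps), qs)
  }
  phuge <- modularity_params(1, 100, n_runs = 5, seed = 5)
  parth <- louvain_run(mg, phuge, seed = 6)
  expect_equal(parth$labels[, 1], parth$labels[, 2])
})

test_that("ensembles are deterministic given the master seed", {
  set.seed(99)
  mg <- build_multilayer(random_layers(5, 3))
  p <- modularity_params(1, 1, n_runs = 8, seed = 77)
  e1 <- partition_ensemble(mg, p)
  e2 <- partition_ensemble(mg, p)
  expect_identical(lapply(e1$partitions, `[[`, "labels"),
                   lapply(e2$partitions, `[[`, "labels"))
  expect_identical(e1$q, e2$q)
  expect_length(e1$partitions, 8L)
})
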