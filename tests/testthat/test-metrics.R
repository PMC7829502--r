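test_that("connection stability counts co-assignment fractions", {
  # everyone in one module always: all ones
  labs <- matrix(1, 4, 6)
  expect_equal(connection_stability(list(labs)), matrix(1, 4, 4))
  # a pair never co-assigned: 0
  labs <- rbind(rep(1, 6), rep(2, 6))
  cs <- connection_stability(list(labs))
  expect_equal(cs[1, 2], 0)
  expect_equal(diag(cs), c(1, 1))
  # co-assigned in 73 of 146 layers in every run: 0.5
  labs <- rbind(rep(1, 146), c(rep(1, 73), rep(2, 73)))
  cs <- connection_stability(list(labs, labs, labs))
  expect_equal(cs[1, 2], 0.5)
  expect_equal(cs, t(cs))
})

test_that("flexibility implements the transition-count definition", {
  expect_equal(flexibility(list(matrix(1, 3, 5))), rep(0, 3))
  alt <- matrix(rep(c(1, 2), 73), 1, 146)
  expect_equal(flexibility(list(alt)), 1)
  one <- matrix(c(rep(1, 100), rep(2, 46)), 1, 146)
  expect_equal(flexibility(list(one)), 1 / 145)
  expect_error(flexibility(list(matrix(1, 2, 1))), "at least 2 layers")
})

test_that("switch events are classified by the source-and-destination rule", {
  ev <- change_events(toy_labels_cohesive_disjoint())
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$kind[ev$node %in% c(1, 2)], rep("cohesive", 2))
  expect_equal(ev$kind[ev$node == 3], "disjoint")
  # same source, different destinations: both disjoint
  labs <- rbind(c(1, 2), c(1, 3), c(1, 1))
  ev2 <- change_events(labs)
  expect_equal(ev2$kind, c("disjoint", "disjoint"))
  # no changes at all
  expect_equal(nrow(change_events(matrix(2, 3, 4))), 0L)
})

test_that("disjointness and cohesion match the per-transition counts", {
  labs <- toy_labels_cohesive_disjoint()   # T = 3
  dc <- disjointness_cohesion(list(labs))
  expect_equal(dc$disjointness, c(0, 0, 1 / 2))
  expect_equal(dc$cohesion_strength, c(1 / 2, 1 / 2, 0))
  # a node that never changes has zero everything
  labs2 <- rbind(labs, rep(9, 3))
  dc2 <- disjointness_cohesion(list(labs2))
  expect_equal(dc2$disjointness[4], 0)
  expect_equal(dc2$cohesion_strength[4], 0)
})

test_that("flexibility * (T-1) = disjoint + cohesive counts, per run", {
  set.seed(8)
  for (rep in 1:25) {
    n <- sample(3:8, 1); T <- sample(3:10, 1)
    labs <- matrix(sample.int(3, n * T, replace = TRUE), n, T)
    fl <- flexibility(list(labs))
    dc <- disjointness_cohesion(list(labs))
    expect_equal(fl * (T - 1),
                 dc$disjoint_count + dc$cohesive_count)
    expect_true(all(dc$disjointness <= fl + 1e-12))
  }
})

test_that("metrics are invariant under consistent module relabeling", {
  set.seed(9)
  labs <- matrix(sample.int(4, 5 * 6, replace = TRUE), 5, 6)
  perm <- sample(10)   # injective relabeling applied to all layers
  labs2 <- matrix(perm[labs], 5, 6)
  expect_equal(connection_stability(list(labs2)),
               connection_stability(list(labs)))
  expect_equal(flexibility(list(labs2)), flexibility(list(labs)))
  d1 <- disjointness_cohesion(list(labs))
  d2 <- disjointness_cohesion(list(labs2))
  expect_equal(d2$disjointness, d1$disjointness)
  expect_equal(d2$cohesion_strength, d1$cohesion_strength)
  # connection stability (within-layer) also survives per-layer relabeling
  labs3 <- labs
  for (s in 1:6) {
    pl <- sample(10)
    labs3[, s] <- pl[labs[, s]]
  }
  expect_equal(connection_stability(list(labs3)),
               connection_stability(list(labs)))
})

test_that("network aggregation averages members and within pairs", {
  atl1 <- synthetic_atlas(c(ALL = 4L))
  labs <- matrix(sample.int(3, 4 * 5, replace = TRUE), 4, 5)
  mt <- metric_table(list(labs), atl1)
  expect_equal(mt$network_means$disjointness, mean(mt$disjointness))
  expect_equal(mt$network_means$flexibility, mean(mt$flexibility))
  # all-ones stability: every network mean 1
  mt2 <- metric_table(list(matrix(1, 4, 5)), atl1)
  expect_equal(mt2$network_means$connection_stability, 1)
  # 3-node network with pair values {1, 0, 0.5} averages to 0.5
  mt3 <- mt
  mt3$connection_stability <- rbind(c(1, 1, 0, 0), c(1, 1, 0.5, 0),
                                    c(0, 0.5, 1, 0), c(0, 0, 0, 1))
  atl3 <- synthetic_atlas(c(A = 3L, B = 1L))
  agg <- suppressWarnings(network_aggregate(mt3, atl3))
  expect_equal(agg$connection_stability[1], 0.5)
  expect_true(is.na(agg$connection_stability[2]))
  expect_warning(network_aggregate(mt3, atl3), "single node")
})

test_that("planted switches are recovered from high-SNR synthetic data", {
  sched <- list(
    list(epoch = 3L, nodes = 5L, mode = "disjoint", to = 3L),
    list(epoch = 5L, nodes = c(11L, 12L, 13L), mode = "cohesive", to = 4L))
  des <- planted_design(n_epochs = 6L, epoch_length = 30L,
                        within_corr = 0.85, between_corr = 0.05,
                        switch_schedule = sched)
  gs <- generate_subject(des, seed = 21)
  expect_equal(gs$truth$disjoint_count[5], 1L)
  expect_equal(gs$truth$cohesive_count[11:13], rep(1L, 3))
  mt <- subject_metrics(gs$subject, window_spec(30, 30),
                        modularity_params(1, 1, n_runs = 10, seed = 13))
  # the planted disjoint switcher has the highest estimated disjointness
  expect_equal(which.max(mt$disjointness), 5L)
  # planted cohesive movers carry the top cohesion strengths
  expect_true(all(rank(mt$cohesion_strength)[11:13] > 34))
})
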