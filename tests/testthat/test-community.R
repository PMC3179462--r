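two_triangles <- backbone_graph(
  6, rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))

test_that("modularity matches hand-tallied values", {
  g <- two_triangles
  expect_equal(modularity_q(g, rep(1, 6)), 0)
  expect_equal(modularity_q(g, rep(1:2, each = 3)), 0.5)
  expect_error(modularity_q(backbone_graph(3, NULL), c(1, 1, 2)),
               "edgeless")
  expect_error(module_partition(g, c(1, 1)), "cover all nodes")
})

test_that("modularity agrees with the node-pair formulation", {
  set.seed(41)
  for (rep in 1:30) {
    g <- random_small_graph(n = sample(5:9, 1))
    mem <- sample(1:3, g$n_nodes, replace = TRUE)
    expect_equal(modularity_q(g, mem), oracle_modularity(g, mem))
  }
})

test_that("random assignments have the closed-form near-zero mean Q", {
  set.seed(42)
  n <- 60
  m <- 3
  g <- random_small_graph(n = n, p = 0.3, min_edges = 100)
  qs <- replicate(300, modularity_q(g, sample(1:m, n, replace = TRUE)))
  # E[Q] = -(1 - 1/m) * sum(k_i^2) / (2L)^2 for uniform random labels
  k <- node_degrees(g)
  expected <- -(1 - 1 / m) * sum(k^2) / (2 * nrow(g$edges))^2
  se <- sd(qs) / sqrt(length(qs))
  expect_lt(abs(mean(qs) - expected), 3 * se)
  expect_lt(abs(mean(qs)), 0.03)  # vanishing with graph size
})

test_that("greedy detection recovers obvious community structure", {
  part <- detect_communities(two_triangles)
  expect_equal(part$n_modules, 2)
  expect_equal(part$q, 0.5)
  expect_equal(part$membership[1:3], rep(part$membership[1], 3))
  expect_equal(part$membership[4:6], rep(part$membership[4], 3))
  expect_error(detect_communities(backbone_graph(3, NULL)), "edgeless")
})

test_that("reported Q equals recomputed Q of the returned partition", {
  set.seed(43)
  for (rep in 1:20) {
    g <- random_small_graph(n = sample(6:12, 1), min_edges = 3)
    part <- detect_communities(g)
    expect_equal(part$q, modularity_q(g, part$membership))
  }
})

test_that("greedy Q never exceeds the exhaustive-search maximum", {
  set.seed(44)
  for (rep in 1:15) {
    g <- random_small_graph(n = sample(5:8, 1), min_edges = 2)
    expect_lte(detect_communities(g)$q,
               oracle_best_partition_q(g) + 1e-12)
  }
})

test_that("greedy detection tracks igraph's fast-greedy quality", {
  skip_if_not_installed("igraph")
  set.seed(45)
  for (rep in 1:5) {
    g <- random_small_graph(n = 20, p = 0.25, min_edges = 15)
    ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
    ig <- igraph::add_vertices(ig, g$n_nodes - igraph::vcount(ig))
    q_ig <- max(igraph::cluster_fast_greedy(ig)$modularity)
    expect_gte(detect_communities(g)$q, q_ig - 0.05)
  }
})

test_that("planted partitions are recovered with high adjusted Rand index", {
  skip_if_not_installed("mclust")
  n <- 80
  atlas <- region_atlas(paste0("R", 1:n, rep(c("-L", "-R"), n / 2)),
                        rep(c("L", "R"), n / 2))
  mem <- rep(1:4, each = 20)
  aris <- vapply(1:20, function(s) {
    cfg <- cohort_config(atlas = atlas, modules_truth = mem,
                         p_in = 0.8, p_out = 0.02,
                         propensity_sdlog = 0,
                         n_subjects_per_group = 2, n_male = 1, seed = s)
    pb <- plant_backbone(cfg)
    det <- detect_communities(pb$graph)
    mclust::adjustedRandIndex(det$membership, mem)
  }, numeric(1))
  expect_gte(mean(aris), 0.9)
  # and the optimiser should score at least close to the truth's Q
  cfg <- cohort_config(atlas = atlas, modules_truth = mem,
                       p_in = 0.8, p_out = 0.02, propensity_sdlog = 0,
                       n_subjects_per_group = 2, n_male = 1, seed = 3)
  pb <- plant_backbone(cfg)
  expect_gte(detect_communities(pb$graph)$q,
             modularity_q(pb$graph, mem) - 0.02)
})

test_that("node roles follow the z and P definitions", {
  # all edges inside the module: P = 0
  part <- module_partition(two_triangles, rep(1:2, each = 3))
  roles <- node_roles(two_triangles, part)
  expect_equal(roles$p, rep(0, 6))
  expect_equal(roles$z, rep(0, 6))  # uniform kappa within each module
  expect_equal(roles$role, rep("A", 6))
  expect_equal(roles$kappa, rep(2, 6))

  # degree-4 node split 2/2 across two modules: P = 0.5
  g <- backbone_graph(5, rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  roles2 <- node_roles(g, c(1, 1, 1, 2, 2))
  expect_equal(roles2$p[1], 0.5)
  # kappa sums to degree across modules
  expect_true(all(roles2$kappa <= roles2$degree))
})

test_that("participation is invariant to module relabelling", {
  set.seed(46)
  g <- random_small_graph(n = 12, p = 0.4, min_edges = 10)
  mem <- sample(1:3, 12, replace = TRUE)
  r1 <- node_roles(g, mem)
  relabel <- c(3, 1, 2)[mem]
  r2 <- node_roles(g, relabel)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$z, r2$z)
})

test_that("isolated nodes get degenerate role A with P = 0", {
  g <- backbone_graph(4, rbind(c(1, 2), c(2, 3), c(1, 3)))
  roles <- node_roles(g, c(1, 1, 1, 2))
  expect_equal(roles$role[4], "A")
  expect_equal(roles$p[4], 0)
  expect_true(roles$degenerate[4])
})

test_that("backbone modularity beats rewired nulls on modular cohorts", {
  cohort <- sample_cohort(cohort_config(n_subjects_per_group = 8,
                                        n_male = 4, seed = 47))
  snr <- compute_snr(cohort, "1yr")
  qs <- nonrandom_modularity_sweep(snr, c(0.10, 0.21), n_null = 8,
                                   seed = 2)
  expect_true(all(qs$q_brain > qs$q_rand_mean))
})

test_that("structureless SBM shows no excess modularity over nulls", {
  n <- 40
  atlas <- region_atlas(paste0("R", 1:n, rep(c("-L", "-R"), n / 2)),
                        rep(c("L", "R"), n / 2))
  # p_in must exceed p_out by construction; make the gap negligible
  cfg <- cohort_config(atlas = atlas, modules_truth = rep(1:4, each = 10),
                       p_in = 0.3, p_out = 0.2999999,
                       propensity_sdlog = 0,
                       noise_edge_rate = 0,
                       n_subjects_per_group = 6, n_male = 3, seed = 48)
  cohort <- sample_cohort(cfg)
  qs <- nonrandom_modularity_sweep(compute_snr(cohort), 0.21,
                                   n_null = 15, seed = 3)
  expect_lt(abs(qs$q_brain - qs$q_rand_mean), 2 * qs$q_rand_sd + 0.02)
})
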