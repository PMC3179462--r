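# tiny cohort with hand-set counts for one pair
make_pair_cohort <- function(counts_12, n = 4, lengths_12 = NULL) {
  atlas <- region_atlas(paste0(c("A", "B", "C", "D")[1:n],
                               rep(c("-L", "-R"), length.out = n)),
                        rep(c("L", "R"), length.out = n))
  s <- length(counts_12)
  arr <- array(0, dim = c(s, n, n))
  arr[, 1, 2] <- counts_12
  arr[, 2, 1] <- counts_12
  lens <- NULL
  if (!is.null(lengths_12)) {
    lens <- array(0, dim = c(s, n, n))
    lens[, 1, 2] <- lengths_12 * (counts_12 > 0)
    lens[, 2, 1] <- lengths_12 * (counts_12 > 0)
  }
  fiber_cohort(arr, tibble::tibble(subject_id = paste0("s", 1:s),
                                   age_group = "g", sex = "F"),
               atlas, lengths = lens)
}

test_that("SNR is mean over SD with the documented sentinels", {
  snr <- compute_snr(make_pair_cohort(c(4, 6, 5)))
  expect_equal(snr$mean[1, 2], 5)
  expect_equal(snr$sd[1, 2], 1)          # sample SD, n - 1
  expect_equal(snr$snr[1, 2], 5)
  expect_equal(compute_snr(make_pair_cohort(c(5, 5, 5)))$snr[1, 2], Inf)
  expect_equal(compute_snr(make_pair_cohort(c(0, 0, 0)))$snr[1, 2], 0)
  expect_error(compute_snr(make_pair_cohort(7)), "at least 2 subjects")
})

test_that("SNR is invariant to rescaling a pair's counts", {
  set.seed(31)
  base <- rnbinom(20, mu = 30, size = 5) + 1
  for (c_ in c(2, 5, 10)) {
    s1 <- compute_snr(make_pair_cohort(base))
    s2 <- compute_snr(make_pair_cohort(base * c_))
    expect_equal(s1$snr[1, 2], s2$snr[1, 2])
  }
})

test_that("thresholding keeps the top pairs with deterministic ties", {
  cohort <- sample_cohort(cohort_config(n_subjects_per_group = 5,
                                        n_male = 2, seed = 8))
  snr <- compute_snr(cohort, "2yr")
  g <- threshold_to_cost(snr, 0.21)
  expect_equal(nrow(g$edges), 631)       # round(0.21 * 3003)
  expect_equal(attr(g, "realized_cost"), 631 / 3003)

  full <- threshold_to_cost(snr, 1)
  expect_equal(network_cost(full), 1)

  expect_error(threshold_to_cost(snr, 1e-5), "zero edges")
  expect_error(threshold_to_cost(snr, 0), "in \\(0, 1\\]")
})

test_that("thresholding is invariant to region order", {
  set.seed(32)
  n <- 8
  atlas <- region_atlas(paste0("R", 1:n, rep(c("-L", "-R"), 4)),
                        rep(c("L", "R"), 4))
  arr <- array(0, dim = c(4, n, n))
  for (s in 1:4) {
    m <- matrix(rpois(n * n, 6), n)
    m <- m + t(m)
    diag(m) <- 0
    arr[s, , ] <- m
  }
  cohort <- fiber_cohort(arr, tibble::tibble(subject_id = paste0("s", 1:4),
                                             age_group = "g", sex = "F"),
                         atlas)
  g1 <- threshold_to_cost(compute_snr(cohort), 3 / choose(n, 2))
  perm <- sample(n)
  arr2 <- arr[, perm, perm, drop = FALSE]
  cohort2 <- fiber_cohort(arr2, cohort$subjects,
                          region_atlas(atlas$label[perm],
                                       atlas$hemisphere[perm]))
  g2 <- threshold_to_cost(compute_snr(cohort2), 3 / choose(n, 2))
  lab1 <- apply(g1$edges, 1, function(e) {
    paste(sort(g1$labels[e]), collapse = "|")
  })
  lab2 <- apply(g2$edges, 1, function(e) {
    paste(sort(g2$labels[e]), collapse = "|")
  })
  expect_setequal(lab1, lab2)
})

test_that("edge sets nest across increasing costs and hit cost targets", {
  cohort <- sample_cohort(cohort_config(n_subjects_per_group = 5,
                                        n_male = 2, seed = 9))
  snr <- compute_snr(cohort, "1yr")
  costs <- c(0.05, 0.10, 0.21, 0.40)
  graphs <- lapply(costs, threshold_to_cost, snr = snr)
  for (i in seq_len(length(costs) - 1)) {
    e_small <- paste(graphs[[i]]$edges[, 1], graphs[[i]]$edges[, 2])
    e_big <- paste(graphs[[i + 1]]$edges[, 1], graphs[[i + 1]]$edges[, 2])
    expect_true(all(e_small %in% e_big))
  }
  k <- 3003
  for (i in seq_along(costs)) {
    expect_lte(abs(attr(graphs[[i]], "realized_cost") - costs[i]), 1 / k)
  }
})

test_that("cost sweep reports nondecreasing component sizes", {
  cohort <- sample_cohort(cohort_config(n_subjects_per_group = 5,
                                        n_male = 2, seed = 10))
  snr <- compute_snr(cohort, "1yr")
  sw <- cost_sweep(snr, c(0.02, 0.05, 0.1, 0.21, 1))
  expect_true(all(diff(sw$largest_component) >= 0))
  expect_equal(sw$largest_component[nrow(sw)], 78)
})

test_that("two isolated cliques stay disconnected below cross-pair saturation", {
  n <- 10
  atlas <- region_atlas(paste0("R", 1:n, rep(c("-L", "-R"), 5)),
                        rep(c("L", "R"), 5))
  mem <- rep(1:2, each = 5)
  arr <- array(0, dim = c(3, n, n))
  for (s in 1:3) {
    m <- matrix(0, n, n)
    within <- outer(mem, mem, "==")
    diag(within) <- FALSE
    m[within] <- 20 + (s - 1)  # consistent within-clique counts
    arr[s, , ] <- m
  }
  cohort <- fiber_cohort(arr, tibble::tibble(subject_id = paste0("s", 1:3),
                                             age_group = "g", sex = "F"),
                         atlas)
  snr <- compute_snr(cohort)
  # exactly the within-clique pairs have nonzero SNR: 2 * C(5,2) = 20
  g <- threshold_to_cost(snr, 20 / choose(n, 2))
  expect_equal(nrow(g$edges), 20)
  expect_equal(largest_component_size(g), 5)
})

test_that("length summaries pool per-edge means and the empirical CDF", {
  cohort <- make_pair_cohort(c(3, 4, 5), lengths_12 = c(50, 50, 50))
  g <- backbone_graph(4, rbind(c(1, 2)))
  ls <- length_summary(cohort, g)
  expect_equal(ls$mean_length, 50)
  expect_equal(ls$ecdf(49.9), 0)
  expect_equal(ls$ecdf(50), 1)

  # four edges with known mean lengths 20, 40, 60, 80
  n <- 4
  atlas <- region_atlas(c("A-L", "A-R", "B-L", "B-R"))
  arr <- array(0, dim = c(2, n, n))
  lens <- array(0, dim = c(2, n, n))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3))
  lmeans <- c(20, 40, 60, 80)
  for (p in 1:4) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    arr[, i, j] <- arr[, j, i] <- c(5, 6)
    lens[, i, j] <- lens[, j, i] <- lmeans[p]
  }
  cohort2 <- fiber_cohort(arr, tibble::tibble(subject_id = c("s1", "s2"),
                                              age_group = "g", sex = "F"),
                          atlas, lengths = lens)
  ls2 <- length_summary(cohort2, backbone_graph(n, pairs))
  expect_equal(ls2$mean_length, 50)
  expect_equal(ls2$ecdf(60), 0.75)

  # backbone edge without any length data is dropped with a warning
  g_extra <- backbone_graph(n, rbind(pairs, c(3, 4)))
  expect_warning(ls3 <- length_summary(cohort2, g_extra), "excluded")
  expect_equal(ls3$mean_length, 50)
})

test_that("planted group length shift is recovered within 3 SE", {
  cfg <- cohort_config(
    n_subjects_per_group = 39,
    groups = tibble::tibble(group = c("g1", "g2"),
                            count_factor = c(1, 1),
                            length_mean_mm = c(40, 60)),
    seed = 33)
  cohort <- sample_cohort(cfg)
  g <- threshold_to_cost(compute_snr(cohort), 0.19)
  m1 <- length_summary(cohort, g, "g1")
  m2 <- length_summary(cohort, g, "g2")
  # SE of the difference of pooled means, from the per-edge spread
  v1 <- var(m1$edges$mean_length, na.rm = TRUE) /
    sum(!is.na(m1$edges$mean_length))
  v2 <- var(m2$edges$mean_length, na.rm = TRUE) /
    sum(!is.na(m2$edges$mean_length))
  diff <- m2$mean_length - m1$mean_length
  expect_lt(abs(diff - 20), 3 * sqrt(v1 + v2))
})
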