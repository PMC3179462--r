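test_that("graph construction enforces simple undirected structure", {
  expect_error(backbone_graph(3, rbind(c(1, 1))), "self-loops")
  expect_error(backbone_graph(3, rbind(c(1, 2), c(2, 1))), "duplicate")
  expect_error(backbone_graph(3, rbind(c(1, 4))), "node indices")
  g <- backbone_graph(5, rbind(c(3, 1), c(2, 5)))
  expect_equal(g$edges, rbind(c(1L, 3L), c(2L, 5L)))
  expect_equal(sum(node_degrees(g)), 2 * nrow(g$edges))
})

test_that("shortest paths match hand-enumerated small cases", {
  k4 <- backbone_graph(4, t(combn(4, 2)))
  ps <- shortest_path_stats(k4)
  expect_true(all(ps$dist[upper.tri(ps$dist)] == 1))
  expect_true(all(ps$sigma[upper.tri(ps$sigma)] == 1))

  path3 <- backbone_graph(3, rbind(c(1, 2), c(2, 3)))
  ps <- shortest_path_stats(path3, through = TRUE)
  expect_equal(ps$dist[1, 3], 2)
  expect_equal(ps$sigma[1, 3], 1)
  expect_equal(ps$sigma_through[1, 3, 2], 1)
  expect_equal(ps$sigma_through[1, 2, 3], 0)

  disjoint <- backbone_graph(4, rbind(c(1, 2), c(3, 4)))
  ps <- shortest_path_stats(disjoint)
  expect_equal(ps$dist[1, 3], Inf)
  expect_equal(ps$sigma[1, 3], 0)
})

test_that("BFS distances and path counts agree with brute force", {
  set.seed(11)
  for (rep in 1:40) {
    g <- random_small_graph(n = sample(4:8, 1), min_edges = 0)
    ps <- shortest_path_stats(g)
    expect_equal(ps$dist, oracle_fw_dist(oracle_adj(g)))
    # sigma by explicit path enumeration
    for (j in 1:2) {
      for (k in (g$n_nodes - 1):g$n_nodes) {
        if (j == k) next
        paths <- oracle_all_shortest_paths(oracle_adj(g), j, k)
        expect_equal(ps$sigma[j, k], length(paths))
      }
    }
  }
})

test_that("path counts satisfy the predecessor-sum recursion", {
  set.seed(12)
  for (rep in 1:20) {
    g <- random_small_graph(n = sample(5:8, 1))
    a <- oracle_adj(g)
    ps <- shortest_path_stats(g)
    for (s in seq_len(g$n_nodes)) {
      for (v in seq_len(g$n_nodes)) {
        if (v == s || !is.finite(ps$dist[s, v])) next
        preds <- which(a[v, ] > 0 & ps$dist[s, ] == ps$dist[s, v] - 1)
        expect_equal(ps$sigma[s, v], sum(ps$sigma[s, preds]))
      }
    }
  }
})

test_that("largest component size handles complete, split and edgeless graphs", {
  k78 <- backbone_graph(78, t(combn(78, 2)))
  expect_equal(largest_component_size(k78), 78)
  tri_iso <- backbone_graph(4, rbind(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(largest_component_size(tri_iso), 3)
  expect_equal(largest_component_size(backbone_graph(5, NULL)), 1)
})

test_that("cohort write-read round-trips exactly", {
  cfg <- cohort_config(n_subjects_per_group = 3, n_male = 2, seed = 5)
  cohort <- sample_cohort(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cohort(cohort, dir)
  back <- read_cohort(setNames(paths$counts, cohort$subjects$subject_id),
                      paths$atlas, paths$metadata,
                      length_files = paths$lengths)
  expect_equal(back$counts, cohort$counts)
  expect_equal(back$lengths, cohort$lengths, tolerance = 1e-12)
  expect_equal(back$subjects$subject_id, cohort$subjects$subject_id)
  expect_equal(back$atlas$label, cohort$atlas$label)
})

test_that("cohort reading rejects malformed inputs", {
  dir <- withr::local_tempdir()
  atlas <- region_atlas(c("A-L", "A-R", "B-L", "B-R"))
  readr::write_tsv(tibble::as_tibble(atlas), file.path(dir, "atlas.tsv"))
  meta <- file.path(dir, "meta.csv")
  writeLines("subject_id,age_group,sex\ns1,g1,M", meta)
  write_mat <- function(m, name) {
    p <- file.path(dir, name)
    write.table(m, p, sep = "\t", row.names = FALSE, col.names = FALSE)
    p
  }
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 7
  p_ok <- write_mat(m, "s1.tsv")
  got <- read_cohort(c(s1 = p_ok), file.path(dir, "atlas.tsv"), meta)
  expect_equal(sum(got$counts > 0), 2)
  expect_equal(got$counts[1, 1, 2], 7)

  p_rect <- write_mat(matrix(0, 3, 4), "bad_shape.tsv")
  expect_error(
    read_cohort(c(s1 = p_rect), file.path(dir, "atlas.tsv"), meta),
    "shape mismatch")

  asym <- m
  asym[1, 2] <- 3
  p_asym <- write_mat(asym, "asym.tsv")
  expect_error(
    read_cohort(c(s1 = p_asym), file.path(dir, "atlas.tsv"), meta),
    "not symmetric")

  neg <- matrix(0, 4, 4)
  neg[1, 2] <- neg[2, 1] <- -2
  p_neg <- write_mat(neg, "neg.tsv")
  expect_error(
    read_cohort(c(s1 = p_neg), file.path(dir, "atlas.tsv"), meta),
    "nonnegative")

  writeLines("subject_id,age_group,sex\nzz,g1,M", meta)
  expect_error(
    read_cohort(c(s1 = p_ok), file.path(dir, "atlas.tsv"), meta),
    "unknown subject id")
})

test_that("Pajek export follows the 1-based quoted-label format", {
  g <- backbone_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3)),
                      labels = c("A", "B", "C"))
  path <- withr::local_tempfile(fileext = ".net")
  write_pajek(g, path, partition = c(1, 1, 2))
  got <- oracle_parse_pajek(path)
  expect_equal(got$n, 3)
  expect_equal(got$labels, c("A", "B", "C"))
  expect_equal(got$edges, rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)))
  clu <- readLines(sub("\\.net$", ".clu", path))
  expect_equal(clu, c("*Vertices 3", "1", "1", "2"))

  empty <- backbone_graph(2, NULL)
  write_pajek(empty, path)
  lines <- readLines(path)
  expect_equal(lines[length(lines)], "*Edges")
})

test_that("Pajek round-trip preserves the edge set on random graphs", {
  set.seed(13)
  for (rep in 1:10) {
    g <- random_small_graph(n = sample(5:9, 1), min_edges = 0)
    path <- withr::local_tempfile(fileext = ".net")
    write_pajek(g, path)
    got <- oracle_parse_pajek(path)
    if (nrow(g$edges) == 0) {
      expect_null(got$edges)
    } else {
      expect_equal(got$edges, g$edges)
    }
  }
})
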