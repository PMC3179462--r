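# Brute-force reference implementations, kept deliberately independent
# of the package's algorithms: Floyd-Warshall distances, explicit
# shortest-path enumeration, exhaustive partition search. Only usable at
# tiny n; that is the point.

oracle_adj <- function(g) {
  a <- matrix(0, g$n_nodes, g$n_nodes)
  if (nrow(g$edges) > 0) {
    for (r in seq_len(nrow(g$edges))) {
      a[g$edges[r, 1], g$edges[r, 2]] <- 1
      a[g$edges[r, 2], g$edges[r, 1]] <- 1
    }
  }
  a
}

oracle_fw_dist <- function(a) {
  n <- nrow(a)
  d <- ifelse(a > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# all shortest paths between j and k as lists of node sequences
oracle_all_shortest_paths <- function(a, j, k, d = oracle_fw_dist(a)) {
  if (!is.finite(d[j, k])) return(list())
  grow <- function(path) {
    v <- path[length(path)]
    if (v == k) return(list(path))
    nxt <- which(a[v, ] > 0 & d[, k] == d[v, k] - 1)
    unlist(lapply(nxt, function(w) grow(c(path, w))), recursive = FALSE)
  }
  grow(j)
}

oracle_global_efficiency <- function(g) {
  d <- oracle_fw_dist(oracle_adj(g))
  n <- nrow(d)
  tot <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
    }
  }
  tot / (n * (n - 1))
}

oracle_local_efficiency <- function(g) {
  a <- oracle_adj(g)
  n <- nrow(a)
  effs <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- a[nb, nb, drop = FALSE]
    d <- oracle_fw_dist(sub)
    m <- length(nb)
    tot <- 0
    for (x in seq_len(m)) {
      for (y in seq_len(m)) {
        if (x != y && is.finite(d[x, y])) tot <- tot + 1 / d[x, y]
      }
    }
    tot / (m * (m - 1))
  }, numeric(1))
  mean(effs)
}

oracle_betweenness <- function(g) {
  a <- oracle_adj(g)
  n <- nrow(a)
  d <- oracle_fw_dist(a)
  b <- numeric(n)
  for (j in seq_len(n - 1)) {
    for (k in seq((j + 1), n)) {
      paths <- oracle_all_shortest_paths(a, j, k, d)
      if (length(paths) == 0) next
      inner <- unlist(lapply(paths, function(p) setdiff(p, c(j, k))))
      if (length(inner) > 0) {
        cnt <- table(inner)
        idx <- as.integer(names(cnt))
        b[idx] <- b[idx] + as.numeric(cnt) / length(paths)
      }
    }
  }
  b / ((n - 1) * (n - 2) / 2)
}

oracle_vulnerability <- function(g) {
  e0 <- oracle_global_efficiency(g)
  vapply(seq_len(g$n_nodes), function(i) {
    a <- oracle_adj(g)[-i, -i, drop = FALSE]
    sub <- graph_from_adjacency(a)
    (e0 - oracle_global_efficiency(sub)) / e0
  }, numeric(1))
}

# modularity via the node-pair formulation
# Q = (1/2L) * sum_ij (A_ij - k_i k_j / 2L) [c_i == c_j]
oracle_modularity <- function(g, membership) {
  a <- oracle_adj(g)
  k <- rowSums(a)
  l2 <- sum(a)  # 2L
  same <- outer(membership, membership, "==")
  sum((a - outer(k, k) / l2) * same) / l2
}

# maximum modularity by exhaustive search over all set partitions
# (restricted-growth enumeration); feasible for n <= 8
oracle_best_partition_q <- function(g) {
  n <- g$n_nodes
  best <- -Inf
  recurse <- function(mem, next_id) {
    i <- length(mem) + 1
    if (i > n) {
      q <- oracle_modularity(g, mem)
      if (q > best) best <<- q
      return(invisible(NULL))
    }
    for (b in seq_len(next_id)) {
      recurse(c(mem, b), max(next_id, b + 1))
    }
  }
  recurse(integer(0), 1)
  best
}

# naive Pajek parser, independent of write_pajek's formatting choices
oracle_parse_pajek <- function(path) {
  lines <- readLines(path)
  nv <- as.integer(sub("\\*Vertices\\s+", "", lines[1],
                       ignore.case = TRUE))
  eidx <- grep("^\\*Edges", lines, ignore.case = TRUE)
  labels <- sub('^\\s*\\d+\\s+"(.*)"\\s*$', "\\1",
                lines[seq(2, eidx - 1)])
  edges <- do.call(rbind, lapply(
    lines[seq_len(length(lines)) > eidx],
    function(l) as.integer(strsplit(trimws(l), "\\s+")[[1]][1:2])))
  list(n = nv, labels = labels, edges = edges)
}

# random Erdos-Renyi test graph with at least min_edges edges
random_small_graph <- function(n = NULL, p = NULL, min_edges = 1) {
  repeat {
    nn <- n %||% sample(4:7, 1)
    pp <- p %||% runif(1, 0.3, 0.8)
    a <- matrix(0, nn, nn)
    a[upper.tri(a)] <- as.numeric(runif(nn * (nn - 1) / 2) < pp)
    a <- a + t(a)
    if (sum(a) / 2 >= min_edges) return(graph_from_adjacency(a))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Jaccard similarity of two graphs' edge sets
edge_jaccard <- function(g1, g2) {
  e1 <- paste(g1$edges[, 1], g1$edges[, 2])
  e2 <- paste(g2$edges[, 1], g2$edges[, 2])
  length(intersect(e1, e2)) / length(union(e1, e2))
}
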