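#' Backbone graphs
#'
#' The unweighted, undirected, simple graph all network metrics consume.
#' Nodes are the regions of an atlas (1-based indices); edges are the
#' region pairs retained by consistency thresholding. Self-loops and
#' duplicate edges are rejected at construction.
#'
#' @param n_nodes Number of nodes `N >= 2`.
#' @param edges Two-column matrix (or data frame) of node-index pairs;
#'   may be empty. Order within a pair is irrelevant.
#' @param labels Optional character vector of `n_nodes` node labels.
#'
#' @return An object of class `backbone_graph`: a list with elements
#'   `n_nodes`, `edges` (two-column integer matrix, each row `i < j`,
#'   sorted), and `labels`.
#' @examples
#' g <- backbone_graph(3, rbind(c(1, 2), c(2, 3)))
#' node_degrees(g)
#' @export
backbone_graph <- function(n_nodes, edges, labels = NULL) {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 2) {
    stop("a backbone graph needs at least 2 nodes", call. = FALSE)
  }
  edges <- if (is.null(edges) || length(edges) == 0) {
    matrix(integer(0), ncol = 2)
  } else {
    as.matrix(edges)
  }
  if (ncol(edges) != 2) stop("edges must have two columns", call. = FALSE)
  storage.mode(edges) <- "integer"
  if (nrow(edges) > 0) {
    if (anyNA(edges) || any(edges < 1) || any(edges > n_nodes)) {
      stop("edge endpoints must be node indices in 1..n_nodes",
           call. = FALSE)
    }
    if (any(edges[, 1] == edges[, 2])) {
      stop("self-loops are not allowed", call. = FALSE)
    }
    edges <- cbind(pmin(edges[, 1], edges[, 2]),
                   pmax(edges[, 1], edges[, 2]))
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
    if (anyDuplicated(edges)) {
      stop("duplicate edges are not allowed", call. = FALSE)
    }
  }
  if (!is.null(labels) && length(labels) != n_nodes) {
    stop("labels must have length n_nodes", call. = FALSE)
  }
  dimnames(edges) <- NULL
  structure(list(n_nodes = n_nodes, edges = edges,
                 labels = if (!is.null(labels)) as.character(labels)),
            class = "backbone_graph")
}

#' @export
print.backbone_graph <- function(x, ...) {
  cat(sprintf("<backbone_graph: %d nodes, %d edges, cost %.4f>\n",
              x$n_nodes, nrow(x$edges), network_cost(x)))
  invisible(x)
}

#' Build a backbone graph from an adjacency matrix
#'
#' @param adj Square symmetric matrix; nonzero entries are edges.
#' @param labels Optional node labels (defaults to matrix dimnames).
#' @return A [backbone_graph()].
#' @export
graph_from_adjacency <- function(adj, labels = rownames(adj)) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj)) stop("adjacency must be square", call. = FALSE)
  if (!isSymmetric(unname(adj))) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  idx <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
  backbone_graph(nrow(adj), idx, labels = labels)
}

#' Adjacency matrix of a backbone graph
#'
#' @param g A [backbone_graph()].
#' @return An `n_nodes` x `n_nodes` 0/1 integer matrix.
#' @export
adjacency_matrix <- function(g) {
  stopifnot(inherits(g, "backbone_graph"))
  a <- matrix(0L, g$n_nodes, g$n_nodes)
  if (nrow(g$edges) > 0) {
    a[g$edges] <- 1L
    a[g$edges[, c(2, 1), drop = FALSE]] <- 1L
  }
  if (!is.null(g$labels)) dimnames(a) <- list(g$labels, g$labels)
  a
}

#' Node degrees
#'
#' @param g A [backbone_graph()].
#' @return Integer vector of per-node degrees.
#' @export
node_degrees <- function(g) {
  stopifnot(inherits(g, "backbone_graph"))
  tabulate(g$edges, nbins = g$n_nodes)
}

# adjacency list: integer neighbor vectors, one per node
adj_list <- function(g) {
  nb <- vector("list", g$n_nodes)
  for (v in seq_len(g$n_nodes)) nb[[v]] <- integer(0)
  if (nrow(g$edges) > 0) {
    ends <- c(g$edges[, 1], g$edges[, 2])
    other <- c(g$edges[, 2], g$edges[, 1])
    nb <- split(other, factor(ends, levels = seq_len(g$n_nodes)))
  }
  unname(nb)
}

# all-pairs hop distances by frontier expansion on the adjacency matrix;
# Inf marks disconnected pairs
dist_matrix <- function(g) {
  n <- g$n_nodes
  a <- adjacency_matrix(g)
  dimnames(a) <- NULL
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  reached <- diag(n) > 0
  frontier <- reached
  step <- 0
  while (any(frontier)) {
    step <- step + 1
    nxt <- (frontier %*% a > 0) & !reached
    if (!any(nxt)) break
    d[nxt] <- step
    reached <- reached | nxt
    frontier <- nxt
  }
  d
}

#' Shortest-path statistics
#'
#' Breadth-first search from every source gives, for each ordered pair,
#' the hop distance `d_ij` and the number of distinct shortest paths
#' `sigma_ij`. Disconnected pairs have `d = Inf` and `sigma = 0`.
#' When `through = TRUE` the per-intermediate path counts
#' `sigma_jk(i)` (number of j-k shortest paths passing through node i)
#' are also returned, via the Bellman identity
#' `sigma_jk(i) = sigma_ji * sigma_ik` when `d_ji + d_ik = d_jk`.
#'
#' @param g A [backbone_graph()].
#' @param through Also return the `sigma_through` array (N x N x N,
#'   `[j, k, i]`)? Off by default; cubic memory.
#' @return A list of class `path_stats` with matrices `dist`, `sigma`
#'   and optionally the array `sigma_through`.
#' @export
shortest_path_stats <- function(g, through = FALSE) {
  n <- g$n_nodes
  nb <- adj_list(g)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dv <- rep(-1L, n)
    sg <- numeric(n)
    dv[s] <- 0L
    sg[s] <- 1
    queue <- integer(n)
    queue[1] <- s
    head <- 1L
    tail <- 1L
    while (head <= tail) {
      v <- queue[head]
      head <- head + 1L
      for (w in nb[[v]]) {
        if (dv[w] < 0L) {
          dv[w] <- dv[v] + 1L
          tail <- tail + 1L
          queue[tail] <- w
        }
        if (dv[w] == dv[v] + 1L) sg[w] <- sg[w] + sg[v]
      }
    }
    dist[s, dv >= 0L] <- dv[dv >= 0L]
    sigma[s, ] <- sg
  }
  sigma[!is.finite(dist)] <- 0
  sigma[cbind(seq_len(n), seq_len(n))] <- 1
  out <- list(dist = dist, sigma = sigma)
  if (through) {
    st <- array(0, dim = c(n, n, n))
    for (i in seq_len(n)) {
      on_path <- outer(dist[, i], dist[i, ], "+") == dist
      on_path[!is.finite(dist)] <- FALSE
      contrib <- outer(sigma[, i], sigma[i, ]) * on_path
      contrib[i, ] <- 0
      contrib[, i] <- 0
      diag(contrib) <- 0
      st[, , i] <- contrib
    }
    out$sigma_through <- st
  }
  class(out) <- "path_stats"
  out
}

# connected-component membership by repeated BFS
component_membership <- function(g) {
  n <- g$n_nodes
  nb <- adj_list(g)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      fresh <- nb[[v]][comp[nb[[v]]] == 0L]
      comp[fresh] <- cur
      queue <- c(queue, fresh)
    }
  }
  comp
}

#' Size of the largest connected component
#'
#' A backbone is fully connected (no isolated nodes) exactly when this
#' equals the node count.
#'
#' @param g A [backbone_graph()].
#' @return Integer: number of nodes in the biggest connected node set.
#' @examples
#' largest_component_size(backbone_graph(4, rbind(c(1, 2), c(2, 3))))
#' @export
largest_component_size <- function(g) {
  max(tabulate(component_membership(g)))
}

#' Export a graph (and optional partition) in Pajek format
#'
#' Writes a standard `.net` file (`*Vertices N` with 1-based ids and
#' quoted labels, then `*Edges` with endpoint pairs). If a module
#' partition is supplied, a companion `.clu` file with one module id per
#' node is written next to it.
#'
#' @param g A [backbone_graph()].
#' @param path Output path for the `.net` file.
#' @param partition Optional [module_partition()] or integer membership
#'   vector; written as `<path minus .net>.clu`.
#' @return Invisibly, the path(s) written.
#' @export
write_pajek <- function(g, path, partition = NULL) {
  stopifnot(inherits(g, "backbone_graph"))
  labels <- g$labels %||% paste0("v", seq_len(g$n_nodes))
  lines <- c(
    sprintf("*Vertices %d", g$n_nodes),
    sprintf("%d \"%s\"", seq_len(g$n_nodes), labels),
    "*Edges"
  )
  if (nrow(g$edges) > 0) {
    lines <- c(lines, sprintf("%d %d", g$edges[, 1], g$edges[, 2]))
  }
  writeLines(lines, path)
  written <- path
  if (!is.null(partition)) {
    membership <- if (inherits(partition, "module_partition")) {
      partition$membership
    } else {
      as.integer(partition)
    }
    if (length(membership) != g$n_nodes) {
      stop("partition must cover all nodes", call. = FALSE)
    }
    clu <- paste0(sub("\\.net$", "", path), ".clu")
    writeLines(c(sprintf("*Vertices %d", g$n_nodes),
                 as.character(membership)), clu)
    written <- c(written, clu)
  }
  invisible(written)
}
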