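# distances / efficiency on a raw adjacency matrix (frontier BFS);
# shared by the graph-level metrics and the neighbourhood subgraphs
dist_from_adj <- function(a) {
  n <- nrow(a)
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

eff_from_adj <- function(a) {
  n <- nrow(a)
  if (n < 2) return(0)
  d <- dist_from_adj(a)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs,
#' `E_glob = (1 / (N (N - 1))) * sum_{i != j} 1 / d_ij`, with
#' disconnected pairs contributing 0. Gauges the capacity for parallel,
#' integrated information transfer; 1 for a complete graph, 0 for an
#' edgeless one.
#'
#' @param g A [backbone_graph()] with at least 2 nodes.
#' @return A number in `[0, 1]`.
#' @examples
#' global_efficiency(backbone_graph(3, rbind(c(1, 2), c(2, 3)))) # 5/6
#' @export
global_efficiency <- function(g) {
  stopifnot(inherits(g, "backbone_graph"))
  if (g$n_nodes < 2) stop("global efficiency needs N >= 2", call. = FALSE)
  a <- adjacency_matrix(g)
  dimnames(a) <- NULL
  eff_from_adj(a)
}

#' Local efficiency
#'
#' Mean, over all nodes, of the global efficiency of each node's
#' neighbour-induced subgraph (the node itself excluded, and the
#' subgraph's own node count used in the normalisation). Nodes of degree
#' 0 or 1 have a sub-2-node subgraph and contribute 0. Gauges clustered,
#' fault-tolerant processing in each node's immediate neighbourhood.
#'
#' @param g A [backbone_graph()].
#' @return A number in `[0, 1]`.
#' @export
local_efficiency <- function(g) {
  stopifnot(inherits(g, "backbone_graph"))
  a <- adjacency_matrix(g)
  dimnames(a) <- NULL
  mean(vapply(seq_len(g$n_nodes), function(i) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2) return(0)
    eff_from_adj(a[nb, nb, drop = FALSE])
  }, numeric(1)))
}

#' Network cost
#'
#' Fraction of possible edges present: `|E| / (N (N - 1) / 2)`.
#'
#' @param g A [backbone_graph()].
#' @return A number in `[0, 1]`.
#' @export
network_cost <- function(g) {
  stopifnot(inherits(g, "backbone_graph"))
  nrow(g$edges) / (g$n_nodes * (g$n_nodes - 1) / 2)
}

#' Betweenness centrality
#'
#' For each node i, the sum over unordered pairs `{j, k}` (both distinct
#' from i) of the fraction of j-k shortest paths passing through i,
#' normalised by `(N - 1)(N - 2) / 2` so the hub of a star attains the
#' greatest possible value of 1. Disconnected pairs contribute 0.
#' Computed with Brandes' dependency accumulation.
#'
#' @param g A [backbone_graph()] with at least 3 nodes.
#' @return Numeric vector of per-node normalised betweenness in `[0, 1]`.
#' @examples
#' star <- backbone_graph(4, cbind(1, 2:4))
#' betweenness_centrality(star) # hub 1, leaves 0
#' @export
betweenness_centrality <- function(g) {
  stopifnot(inherits(g, "backbone_graph"))
  n <- g$n_nodes
  if (n < 3) stop("betweenness needs N >= 3", call. = FALSE)
  nb <- adj_list(g)
  b <- numeric(n)
  for (s in seq_len(n)) {
    dv <- rep(-1L, n)
    sg <- numeric(n)
    dv[s] <- 0L
    sg[s] <- 1
    preds <- vector("list", n)
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
        if (dv[w] == dv[v] + 1L) {
          sg[w] <- sg[w] + sg[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in queue[tail:1]) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sg[v] / sg[w] * (1 + delta[w])
      }
      if (w != s) b[w] <- b[w] + delta[w]
    }
  }
  # each unordered pair counted from both endpoints
  b / 2 / ((n - 1) * (n - 2) / 2)
}

#' Node vulnerability
#'
#' Relative drop in global efficiency when a node and its edges are
#' removed: `V_i = (E_glob - E_glob^{-i}) / E_glob`, where the damaged
#' graph's efficiency is computed on its own `N - 1` nodes. Negative
#' values are possible (removing a peripheral node can raise the
#' normalised efficiency).
#'
#' @param g A [backbone_graph()] with at least 3 nodes and `E_glob > 0`.
#' @return Numeric vector of per-node vulnerability.
#' @export
vulnerability <- function(g) {
  stopifnot(inherits(g, "backbone_graph"))
  n <- g$n_nodes
  if (n < 3) stop("vulnerability needs N >= 3", call. = FALSE)
  a <- adjacency_matrix(g)
  dimnames(a) <- NULL
  e0 <- eff_from_adj(a)
  if (e0 <= 0) stop("vulnerability undefined when E_glob = 0", call. = FALSE)
  vapply(seq_len(n), function(i) {
    (e0 - eff_from_adj(a[-i, -i, drop = FALSE])) / e0
  }, numeric(1))
}

#' Graph-level efficiency report
#'
#' One-row summary of a backbone graph: global and local efficiency,
#' cost, size and connectedness.
#'
#' @param g A [backbone_graph()].
#' @return A one-row tibble with columns `n_nodes`, `n_edges`, `cost`,
#'   `e_glob`, `e_loc`, `largest_component`.
#' @export
efficiency_report <- function(g) {
  tibble::tibble(
    n_nodes = g$n_nodes,
    n_edges = nrow(g$edges),
    cost = network_cost(g),
    e_glob = global_efficiency(g),
    e_loc = local_efficiency(g),
    largest_component = largest_component_size(g)
  )
}

#' Per-node metric table
#'
#' Degree, nodal efficiency (mean inverse distance to every other node),
#' normalised betweenness and vulnerability for each node of a backbone.
#'
#' @param g A [backbone_graph()] with at least 3 nodes.
#' @return A tibble with one row per node: `node`, `label`, `degree`,
#'   `nodal_efficiency`, `betweenness`, `vulnerability`.
#' @export
node_metrics <- function(g) {
  stopifnot(inherits(g, "backbone_graph"))
  n <- g$n_nodes
  d <- dist_matrix(g)
  inv <- 1 / d
  diag(inv) <- 0
  tibble::tibble(
    node = seq_len(n),
    label = g$labels %||% paste0("v", seq_len(n)),
    degree = node_degrees(g),
    nodal_efficiency = rowSums(inv) / (n - 1),
    betweenness = betweenness_centrality(g),
    vulnerability = vulnerability(g)
  )
}
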