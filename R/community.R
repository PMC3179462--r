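#' Module partitions
#'
#' A partition of a graph's nodes into modules, together with the edge
#' tallies that enter the modularity: for each module s, `l_s` (edges
#' with both ends in s) and `d_s` (summed member degrees), and the total
#' edge count `L`. Its modularity is
#' `Q = sum_s [ l_s / L - (d_s / (2 L))^2 ]` — the excess of
#' within-module edge fraction over its degree-based random expectation.
#'
#' @param g A [backbone_graph()] with at least one edge.
#' @param membership Vector assigning each node a module id (any
#'   values; renumbered 1..M preserving first appearance).
#' @return An object of class `module_partition`: list with
#'   `membership` (integer vector), `n_modules`, `modules` (tibble:
#'   `module`, `n_nodes`, `l_s`, `d_s`), `n_edges` and `q`.
#' @examples
#' g <- backbone_graph(6, rbind(c(1, 2), c(2, 3), c(1, 3),
#'                              c(4, 5), c(5, 6), c(4, 6)))
#' module_partition(g, c(1, 1, 1, 2, 2, 2))$q # 0.5
#' @export
module_partition <- function(g, membership) {
  stopifnot(inherits(g, "backbone_graph"))
  if (length(membership) != g$n_nodes || anyNA(membership)) {
    stop("membership must cover all nodes", call. = FALSE)
  }
  l_tot <- nrow(g$edges)
  if (l_tot == 0) stop("modularity undefined for an edgeless graph",
                       call. = FALSE)
  mem <- as.integer(factor(membership, levels = unique(membership)))
  m <- max(mem)
  same <- mem[g$edges[, 1]] == mem[g$edges[, 2]]
  l_s <- tabulate(mem[g$edges[, 1]][same], nbins = m)
  deg <- node_degrees(g)
  d_s <- vapply(seq_len(m), function(s) sum(deg[mem == s]), numeric(1))
  q <- sum(l_s / l_tot - (d_s / (2 * l_tot))^2)
  structure(list(membership = mem, n_modules = m,
                 modules = tibble::tibble(
                   module = seq_len(m),
                   n_nodes = tabulate(mem, nbins = m),
                   l_s = l_s, d_s = d_s),
                 n_edges = l_tot, q = q,
                 labels = g$labels),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition: %d modules over %d nodes, Q = %.4f>\n",
              x$n_modules, length(x$membership), x$q))
  invisible(x)
}

#' Modularity of a given partition
#'
#' @param g A [backbone_graph()].
#' @param membership Module assignment over all nodes (or a
#'   [module_partition()]).
#' @return The modularity Q.
#' @export
modularity_q <- function(g, membership) {
  if (inherits(membership, "module_partition")) {
    membership <- membership$membership
  }
  module_partition(g, membership)$q
}

#' Fast-greedy community detection
#'
#' Agglomerative modularity optimisation (Clauset–Newman–Moore): every
#' node starts as its own community; at each step the pair of
#' edge-connected communities whose merge yields the largest modularity
#' gain is merged (ties broken by the lowest community-id pair, ids
#' being the smallest member node); the best partition seen along the
#' merge sequence is returned. Separate components are never merged, so
#' isolated nodes stay singleton modules.
#'
#' @param g A [backbone_graph()] with at least one edge.
#' @return A [module_partition()].
#' @examples
#' g <- backbone_graph(6, rbind(c(1, 2), c(2, 3), c(1, 3),
#'                              c(4, 5), c(5, 6), c(4, 6)))
#' detect_communities(g)
#' @export
detect_communities <- function(g) {
  stopifnot(inherits(g, "backbone_graph"))
  n <- g$n_nodes
  l_tot <- nrow(g$edges)
  if (l_tot == 0) stop("cannot detect communities in an edgeless graph",
                       call. = FALSE)
  # w[i, j]: 2x within-community edges on the diagonal, between-community
  # edge counts off it; b = w / (2L) is the standard CNM bookkeeping
  w <- matrix(0, n, n)
  a <- adjacency_matrix(g)
  dimnames(a) <- NULL
  w[a > 0] <- 1
  active <- rep(TRUE, n)
  comm_id <- seq_len(n)          # smallest member node of each community
  node_comm <- seq_len(n)        # current community (row index) per node
  q_cur <- sum(-(rowSums(w) / (2 * l_tot))^2)
  best_q <- q_cur
  best_mem <- node_comm
  repeat {
    idx <- which(active)
    if (length(idx) < 2) break
    wa <- w[idx, idx, drop = FALSE]
    arow <- rowSums(wa) / (2 * l_tot)
    dq <- 2 * (wa / (2 * l_tot) - outer(arow, arow))
    dq[wa == 0] <- -Inf
    dq[lower.tri(dq, diag = TRUE)] <- -Inf
    if (!any(is.finite(dq))) break  # only disconnected communities left
    mx <- max(dq)
    cand <- which(dq == mx, arr.ind = TRUE)
    ids <- cbind(pmin(comm_id[idx[cand[, 1]]], comm_id[idx[cand[, 2]]]),
                 pmax(comm_id[idx[cand[, 1]]], comm_id[idx[cand[, 2]]]))
    pick <- order(ids[, 1], ids[, 2])[1]
    i <- idx[cand[pick, 1]]
    j <- idx[cand[pick, 2]]
    if (comm_id[j] < comm_id[i]) { tmp <- i; i <- j; j <- tmp }
    w[i, ] <- w[i, ] + w[j, ]
    w[, i] <- w[, i] + w[, j]
    active[j] <- FALSE
    node_comm[node_comm == j] <- i
    q_cur <- q_cur + mx
    if (q_cur > best_q + 1e-12) {
      best_q <- q_cur
      best_mem <- node_comm
    }
  }
  module_partition(g, best_mem)
}

#' Node roles in the (z, P) plane
#'
#' For each node, the within-module degree z-score
#' `z_i = (kappa_i - mean_s kappa) / sd_s kappa` (module-wise, population
#' SD; a zero-SD module gives z = 0) and the participation coefficient
#' `P_i = 1 - sum_s (kappa_is / k_i)^2`, then the Guimera–Amaral role
#' letter: nodes with `z > z_cutoff` are module hubs. Non-hubs split
#' into (A) ultra-peripheral, (B) peripheral, (C) connector and (D)
#' kinless by the `p_nonhub` boundaries; hubs into (E) provincial, (F)
#' connector and (G) kinless by `p_hub`.
#'
#' @param g A [backbone_graph()].
#' @param partition A [module_partition()] (or membership vector).
#' @param z_cutoff Hub threshold on z (default 2.5).
#' @param p_nonhub Increasing P boundaries separating roles A|B|C|D
#'   (default `c(0.05, 0.62, 0.80)`).
#' @param p_hub Increasing P boundaries separating roles E|F|G
#'   (default `c(0.30, 0.75)`).
#' @return A tibble, one row per node: `node`, `label`, `module`,
#'   `degree`, `kappa` (within-module degree), `z`, `p`, `role`, and
#'   `degenerate` (TRUE for isolated nodes, whose P is reported as 0
#'   and role as "A").
#' @export
node_roles <- function(g, partition, z_cutoff = 2.5,
                       p_nonhub = c(0.05, 0.62, 0.80),
                       p_hub = c(0.30, 0.75)) {
  stopifnot(inherits(g, "backbone_graph"))
  mem <- if (inherits(partition, "module_partition")) {
    partition$membership
  } else {
    as.integer(factor(partition, levels = unique(partition)))
  }
  n <- g$n_nodes
  m <- max(mem)
  deg <- node_degrees(g)
  a <- adjacency_matrix(g)
  dimnames(a) <- NULL
  # kappa_to[i, s]: edges from node i into module s
  kappa_to <- vapply(seq_len(m), function(s) {
    rowSums(a[, mem == s, drop = FALSE])
  }, numeric(n))
  kappa_to <- matrix(kappa_to, nrow = n)
  kappa <- kappa_to[cbind(seq_len(n), mem)]
  z <- numeric(n)
  for (s in seq_len(m)) {
    ks <- kappa[mem == s]
    sds <- sqrt(mean((ks - mean(ks))^2))
    z[mem == s] <- if (sds > 0) (ks - mean(ks)) / sds else 0
  }
  p <- ifelse(deg == 0, 0, 1 - rowSums((kappa_to / pmax(deg, 1))^2))
  role <- character(n)
  hub <- z > z_cutoff
  role[!hub] <- as.character(
    cut(p[!hub], c(-Inf, p_nonhub, Inf), labels = c("A", "B", "C", "D")))
  role[hub] <- as.character(
    cut(p[hub], c(-Inf, p_hub, Inf), labels = c("E", "F", "G")))
  role[deg == 0] <- "A"
  tibble::tibble(
    node = seq_len(n),
    label = g$labels %||% paste0("v", seq_len(n)),
    module = mem,
    degree = deg,
    kappa = kappa,
    z = z,
    p = p,
    role = role,
    degenerate = deg == 0
  )
}

#' Modularity of the backbone versus rewired nulls across costs
#'
#' At each cost, detects communities on the backbone and on an ensemble
#' of degree-preserving rewired graphs; a backbone Q well above the null
#' mean indicates nonrandom modular organisation.
#'
#' @inheritParams smallworld_sweep
#' @return A tibble, one row per cost: `cost`, `n_edges`, `q_brain`,
#'   `q_rand_mean`, `q_rand_sd`, `n_modules`.
#' @export
nonrandom_modularity_sweep <- function(snr, costs, n_null = 100,
                                       seed = 1L, n_swap_factor = 10) {
  stopifnot(n_null >= 1)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L,
                          n_null * length(costs))
  purrr::imap_dfr(costs, function(cc, ci) {
    g <- threshold_to_cost(snr, cc)
    part <- detect_communities(g)
    seeds <- sub_seeds[(ci - 1) * n_null + seq_len(n_null)]
    q_r <- vapply(seeds, function(s) {
      detect_communities(
        rewire_preserving_degrees(g, n_swap_factor, seed = s))$q
    }, numeric(1))
    tibble::tibble(cost = cc, n_edges = nrow(g$edges),
                   q_brain = part$q,
                   q_rand_mean = mean(q_r), q_rand_sd = sd(q_r),
                   n_modules = part$n_modules)
  })
}
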