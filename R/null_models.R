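#' Degree-preserving rewiring
#'
#' Randomises a graph while keeping every node's degree exactly fixed,
#' by repeated double-edge swaps: edges `a-b` and `c-d` become `a-d` and
#' `c-b`, with swaps that would create a self-loop or duplicate edge
#' rejected. This is the Maslov–Sneppen null: same nodes, same edge
#' count, same degree sequence, wiring otherwise random.
#'
#' @param g A [backbone_graph()] with at least 2 edges (fewer, or graphs
#'   with no legal swap such as a star, are returned unchanged).
#' @param n_swap_factor Number of attempted swaps per edge (default 10).
#' @param seed Optional RNG seed for a reproducible realisation.
#' @return A [backbone_graph()] with the same degree sequence.
#' @export
rewire_preserving_degrees <- function(g, n_swap_factor = 10, seed = NULL) {
  stopifnot(inherits(g, "backbone_graph"))
  if (!is.null(seed)) set.seed(seed)
  m <- g$edges
  ne <- nrow(m)
  if (ne < 2) return(g)
  adj <- matrix(FALSE, g$n_nodes, g$n_nodes)
  adj[m] <- TRUE
  adj[m[, c(2, 1), drop = FALSE]] <- TRUE
  n_try <- ceiling(n_swap_factor * ne)
  e1s <- sample.int(ne, n_try, replace = TRUE)
  e2s <- sample.int(ne, n_try, replace = TRUE)
  flip <- runif(n_try) < 0.5
  for (t in seq_len(n_try)) {
    i <- e1s[t]
    j <- e2s[t]
    if (i == j) next
    a <- m[i, 1]; b <- m[i, 2]
    c_ <- m[j, 1]; d <- m[j, 2]
    if (flip[t]) { tmp <- c_; c_ <- d; d <- tmp }
    # propose a-d and c-b
    if (a == d || c_ == b) next
    if (adj[a, d] || adj[c_, b]) next
    adj[a, b] <- adj[b, a] <- FALSE
    adj[c_, d] <- adj[d, c_] <- FALSE
    adj[a, d] <- adj[d, a] <- TRUE
    adj[c_, b] <- adj[b, c_] <- TRUE
    m[i, ] <- c(min(a, d), max(a, d))
    m[j, ] <- c(min(c_, b), max(c_, b))
  }
  backbone_graph(g$n_nodes, m, labels = g$labels)
}

#' Matched ring lattice
#'
#' The regular-lattice comparator: nodes on a circle, edges added in
#' increasing circular distance (the distance-1 ring first, then
#' distance-2 chords, ...), within a distance tier in increasing node
#' index, until exactly `n_edges` edges are placed. Matches a reference
#' graph's node and edge counts while concentrating wiring locally,
#' which is what penalises long-distance communication.
#'
#' @param n Number of nodes.
#' @param n_edges Number of edges, at most `n (n - 1) / 2`.
#' @param labels Optional node labels.
#' @return A [backbone_graph()].
#' @examples
#' matched_lattice(6, 6) # the 6-cycle
#' @export
matched_lattice <- function(n, n_edges, labels = NULL) {
  n <- as.integer(n)
  k <- n * (n - 1) / 2
  if (n_edges > k) stop("n_edges exceeds the possible ", k, call. = FALSE)
  edges <- matrix(integer(0), ncol = 2)
  for (d in seq_len(floor(n / 2))) {
    i <- seq_len(if (2 * d == n) n / 2 else n)
    j <- ((i + d - 1) %% n) + 1
    tier <- cbind(pmin(i, j), pmax(i, j))
    edges <- rbind(edges, tier)
    if (nrow(edges) >= n_edges) break
  }
  backbone_graph(n, edges[seq_len(n_edges), , drop = FALSE],
                 labels = labels)
}

#' Small-world assessment across a cost sweep
#'
#' At each target cost, compares the backbone's global and local
#' efficiency with (i) the mean over an ensemble of degree-preserving
#' rewired random graphs and (ii) a matched ring lattice. A network is
#' small-world when it is locally more efficient than its random
#' comparators and globally more efficient than its lattice comparator.
#'
#' @param snr An [compute_snr()] result.
#' @param costs Target costs in `(0, 1]`.
#' @param n_null Ensemble size (rewired realisations per cost).
#' @param seed RNG seed for the ensemble.
#' @param n_swap_factor Swap attempts per edge for each realisation.
#' @return A tibble of class `smallworld_sweep`, one row per cost:
#'   backbone `e_glob`/`e_loc`, ensemble means and SDs
#'   (`e_glob_rand_mean`, `e_glob_rand_sd`, `e_loc_rand_mean`,
#'   `e_loc_rand_sd`), lattice values (`e_glob_latt`, `e_loc_latt`) and
#'   the `small_world` flag.
#' @export
smallworld_sweep <- function(snr, costs, n_null = 100, seed = 1L,
                             n_swap_factor = 10) {
  stopifnot(n_null >= 1)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L,
                          n_null * length(costs))
  out <- purrr::imap_dfr(costs, function(cc, ci) {
    g <- threshold_to_cost(snr, cc)
    eg <- global_efficiency(g)
    el <- local_efficiency(g)
    seeds <- sub_seeds[(ci - 1) * n_null + seq_len(n_null)]
    nulls <- purrr::map(seeds, function(s) {
      rewire_preserving_degrees(g, n_swap_factor, seed = s)
    })
    eg_r <- vapply(nulls, global_efficiency, numeric(1))
    el_r <- vapply(nulls, local_efficiency, numeric(1))
    latt <- matched_lattice(g$n_nodes, nrow(g$edges))
    eg_l <- global_efficiency(latt)
    el_l <- local_efficiency(latt)
    tibble::tibble(
      cost = cc, n_edges = nrow(g$edges),
      e_glob = eg, e_loc = el,
      e_glob_rand_mean = mean(eg_r), e_glob_rand_sd = sd(eg_r),
      e_loc_rand_mean = mean(el_r), e_loc_rand_sd = sd(el_r),
      e_glob_latt = eg_l, e_loc_latt = el_l,
      small_world = el > mean(el_r) && eg > eg_l
    )
  })
  class(out) <- c("smallworld_sweep", class(out))
  out
}
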