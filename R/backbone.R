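#' Connectivity SNR matrix
#'
#' For every region pair, the reciprocal of the coefficient of variation
#' of the fiber count across a group's subjects: `SNR = mean / SD`.
#' A pair connected by a consistent number of fibers scores high; the
#' measure is scale-invariant, so it does not depend on the total number
#' of fibers a subject's tractography reconstructs. Subjects without the
#' connection contribute zero counts (absence is signal, not
#' missingness); the SD uses the sample (n - 1) denominator. Sentinels:
#' `SNR = Inf` for a positive-mean, zero-variance pair (perfectly
#' consistent), `SNR = 0` where the mean is 0.
#'
#' @param cohort A [fiber_cohort()].
#' @param group Optional age-group label; restricts to the subjects with
#'   that `age_group`. `NULL` uses the whole cohort.
#' @return An object of class `snr_matrix`: list with symmetric matrices
#'   `mean`, `sd`, `snr` (zero diagonals), the `atlas`, the `group`
#'   label and `n_subjects`.
#' @export
compute_snr <- function(cohort, group = NULL) {
  stopifnot(inherits(cohort, "fiber_cohort"))
  idx <- if (is.null(group)) {
    seq_len(nrow(cohort$subjects))
  } else {
    which(cohort$subjects$age_group == group)
  }
  if (length(idx) < 2) {
    stop("SNR needs at least 2 subjects in the group (SD undefined)",
         call. = FALSE)
  }
  cm <- cohort$counts[idx, , , drop = FALSE]
  s <- length(idx)
  mu <- colMeans(cm, dims = 1)
  v <- (colMeans(cm^2, dims = 1) - mu^2) * s / (s - 1)
  v[v < 0] <- 0  # guard tiny negative round-off
  sdm <- sqrt(v)
  snr <- ifelse(mu == 0, 0, ifelse(sdm == 0, Inf, mu / sdm))
  diag(snr) <- 0
  structure(list(mean = mu, sd = sdm, snr = snr, atlas = cohort$atlas,
                 group = group %||% "all", n_subjects = s),
            class = "snr_matrix")
}

#' @export
print.snr_matrix <- function(x, ...) {
  cat(sprintf("<snr_matrix: %d regions, group '%s', %d subjects>\n",
              nrow(x$snr), x$group, x$n_subjects))
  invisible(x)
}

# deterministic pair ranking: SNR desc, then mean desc, then
# lexicographic pair index — makes thresholding order-invariant
snr_ranking <- function(snr) {
  n <- nrow(snr$snr)
  ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  ord <- order(-snr$snr[ut], -snr$mean[ut], seq_len(nrow(ut)))
  list(pairs = ut, order = ord)
}

#' Threshold an SNR matrix to a target network cost
#'
#' Retains the `E = round(target_cost * K)` region pairs with the
#' highest SNR (`K = N (N - 1) / 2`), breaking ties deterministically by
#' higher mean count and then lexicographic pair index; zero-variance
#' positive-mean pairs (`SNR = Inf`) rank above every finite value.
#'
#' @param snr An [compute_snr()] result.
#' @param target_cost Fraction of possible edges to keep, in `(0, 1]`.
#' @return A [backbone_graph()] with attributes `realized_cost`
#'   (`E / K`) and `snr_threshold` (SNR of the weakest retained pair).
#' @examples
#' \donttest{
#' cohort <- sample_cohort(cohort_config(n_subjects_per_group = 6))
#' g <- threshold_to_cost(compute_snr(cohort, "1yr"), 0.21)
#' attr(g, "realized_cost")
#' }
#' @export
threshold_to_cost <- function(snr, target_cost) {
  stopifnot(inherits(snr, "snr_matrix"))
  if (!(target_cost > 0 && target_cost <= 1)) {
    stop("target_cost must be in (0, 1]", call. = FALSE)
  }
  n <- nrow(snr$snr)
  k <- n * (n - 1) / 2
  e <- floor(target_cost * k + 0.5)  # half-up rounding
  if (e < 1) {
    stop("target_cost ", target_cost, " yields zero edges", call. = FALSE)
  }
  rk <- snr_ranking(snr)
  keep <- rk$order[seq_len(e)]
  g <- backbone_graph(n, rk$pairs[keep, , drop = FALSE],
                      labels = snr$atlas$label)
  attr(g, "realized_cost") <- e / k
  attr(g, "snr_threshold") <- snr$snr[rk$pairs[keep[e], , drop = FALSE]]
  g
}

#' Backbones across a grid of network costs
#'
#' Thresholds one SNR matrix at each requested cost and records the size
#' of the largest connected component — the diagnostic used to pick the
#' working cost (the smallest cost at which no node is isolated).
#'
#' @param snr An [compute_snr()] result.
#' @param costs Numeric vector of target costs in `(0, 1]`.
#' @return A tibble with one row per cost: `cost`, `n_edges`,
#'   `realized_cost`, `largest_component`, and the graph itself in the
#'   list-column `graph`.
#' @export
cost_sweep <- function(snr, costs) {
  purrr::map_dfr(costs, function(cc) {
    g <- threshold_to_cost(snr, cc)
    tibble::tibble(cost = cc,
                   n_edges = nrow(g$edges),
                   realized_cost = attr(g, "realized_cost"),
                   largest_component = largest_component_size(g),
                   graph = list(g))
  })
}

#' Fiber-length summary over a backbone
#'
#' For each backbone edge, the mean fiber length across the group's
#' subjects that have the connection; pooled into the group mean and the
#' empirical cumulative distribution of edge lengths (the 0.90 quantile
#' marks how short "most" connections are).
#'
#' @param cohort A [fiber_cohort()] with lengths.
#' @param backbone A [backbone_graph()] over the cohort's atlas.
#' @param group Optional age-group label (as in [compute_snr()]).
#' @return An object of class `length_summary`: list with `edges` (a
#'   tibble: `from`, `to`, `mean_length`), `group`, `mean_length`
#'   (pooled group mean, mm), `q90`, and `ecdf` (the empirical CDF as a
#'   function). Backbone edges with no length data are excluded with a
#'   warning.
#' @export
length_summary <- function(cohort, backbone, group = NULL) {
  stopifnot(inherits(cohort, "fiber_cohort"),
            inherits(backbone, "backbone_graph"))
  if (is.null(cohort$lengths)) {
    stop("cohort has no fiber lengths", call. = FALSE)
  }
  idx <- if (is.null(group)) {
    seq_len(nrow(cohort$subjects))
  } else {
    which(cohort$subjects$age_group == group)
  }
  if (length(idx) == 0) stop("empty group '", group, "'", call. = FALSE)
  edges <- backbone$edges
  per_edge <- vapply(seq_len(nrow(edges)), function(r) {
    l <- cohort$lengths[idx, edges[r, 1], edges[r, 2]]
    l <- l[l > 0]
    if (length(l) == 0) NA_real_ else mean(l)
  }, numeric(1))
  if (anyNA(per_edge)) {
    warning(sum(is.na(per_edge)),
            " backbone edge(s) had no length data and were excluded",
            call. = FALSE)
  }
  lab <- backbone$labels %||% paste0("v", seq_len(backbone$n_nodes))
  tab <- tibble::tibble(from = lab[edges[, 1]], to = lab[edges[, 2]],
                        mean_length = per_edge)
  vals <- per_edge[!is.na(per_edge)]
  structure(list(edges = tab,
                 group = group %||% "all",
                 mean_length = mean(vals),
                 q90 = unname(quantile(vals, 0.9, type = 1)),
                 ecdf = stats::ecdf(vals)),
            class = "length_summary")
}

#' @export
print.length_summary <- function(x, ...) {
  cat(sprintf(
    "<length_summary: group '%s', %d edges, mean %.2f mm, q90 %.2f mm>\n",
    x$group, sum(!is.na(x$edges$mean_length)), x$mean_length, x$q90))
  invisible(x)
}
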