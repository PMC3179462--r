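#' Two-sample permutation test
#'
#' Pools both samples, relabels them while preserving the group sizes,
#' and recomputes the statistic (difference of group means by default)
#' for each relabelling. The two-sided p-value is the proportion of
#' permutations whose absolute statistic is at least the absolute
#' observed value — the literal proportion, with no add-one correction
#' (a warning is raised when it is exactly 0, which Monte-Carlo p-values
#' should not be quoted as).
#'
#' @param values_a,values_b Numeric samples, both nonempty.
#' @param n_perm Number of random relabellings (default 1000); ignored
#'   when `exact = TRUE`.
#' @param seed Optional RNG seed.
#' @param exact Enumerate all `choose(n, n_a)` relabellings instead of
#'   sampling (feasible for small samples).
#' @param statistic Function of two samples; default
#'   `mean(a) - mean(b)`.
#' @return A list of class `permutation_result`: `observed`, `n_perm`
#'   (relabellings actually evaluated), `p_two_sided`, `exact`, `seed`.
#' @examples
#' permutation_test(c(0, 0, 0), c(1, 1, 1), exact = TRUE)$p_two_sided
#' @export
permutation_test <- function(values_a, values_b, n_perm = 1000,
                             seed = NULL, exact = FALSE,
                             statistic = function(a, b) mean(a) - mean(b)) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  if (!exact && n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pooled <- c(values_a, values_b)
  na <- length(values_a)
  n <- length(pooled)
  observed <- statistic(values_a, values_b)
  stats_fun <- function(idx_a) {
    statistic(pooled[idx_a], pooled[-idx_a])
  }
  if (exact) {
    splits <- combn(n, na)
    perm_stats <- apply(splits, 2, stats_fun)
    n_used <- ncol(splits)
  } else {
    perm_stats <- vapply(seq_len(n_perm), function(i) {
      stats_fun(sample.int(n, na))
    }, numeric(1))
    n_used <- n_perm
  }
  p <- mean(abs(perm_stats) >= abs(observed) - 1e-12)
  if (p == 0) {
    warning("permutation p-value is exactly 0; report as < 1/n_perm",
            call. = FALSE)
  }
  structure(list(observed = observed, n_perm = n_used,
                 p_two_sided = p, exact = exact, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result: observed %.4g, p = %.4g (%s, %d relabellings)>\n",
    x$observed, x$p_two_sided,
    if (x$exact) "exact" else "Monte-Carlo", x$n_perm))
  invisible(x)
}

#' Inter-hemispheric symmetry of a node metric
#'
#' Pairs each left-hemisphere region with its right partner (by label
#' stem) and regresses the right value on the left by ordinary least
#' squares. A slope of 1 with high correlation indicates perfect
#' hemispheric symmetry; slopes below 1 indicate relatively weaker
#' right-hemisphere values for strongly lateralised-left nodes (and
#' vice versa).
#'
#' @param values Per-node numeric vector in atlas order (e.g. the
#'   `betweenness` column of [node_metrics()]), or a [node_metrics()]
#'   tibble (its `betweenness` column is used).
#' @param atlas The [region_atlas()]; every left region must have a
#'   right partner, otherwise an error lists the offenders.
#' @param level Confidence level for the normal-theory band (default
#'   0.95).
#' @return A list of class `symmetry_fit`: `slope`, `intercept`,
#'   `pearson_r`, `level`, the underlying `lm` fit (`model`) and the
#'   paired data (`pairs`: `stem`, `left`, `right`).
#' @export
hemisphere_symmetry <- function(values, atlas, level = 0.95) {
  if (is.data.frame(values)) {
    if (!"betweenness" %in% names(values)) {
      stop("data frame input must have a betweenness column",
           call. = FALSE)
    }
    values <- values$betweenness
  }
  if (length(values) != nrow(atlas)) {
    stop("need one value per atlas region", call. = FALSE)
  }
  pr <- atlas_pairs(atlas)
  dat <- tibble::tibble(stem = pr$stem,
                        left = values[pr$left],
                        right = values[pr$right])
  model <- lm(right ~ left, data = dat)
  structure(list(slope = unname(coef(model)[2]),
                 intercept = unname(coef(model)[1]),
                 pearson_r = stats::cor(dat$left, dat$right),
                 level = level,
                 model = model,
                 pairs = dat),
            class = "symmetry_fit")
}

#' @export
print.symmetry_fit <- function(x, ...) {
  cat(sprintf(
    "<symmetry_fit: right = %.4f + %.4f * left, r = %.4f (%d pairs)>\n",
    x$intercept, x$slope, x$pearson_r, nrow(x$pairs)))
  invisible(x)
}

# precompute flattened pair matrices once so each permutation only does
# column means over the relabelled subject rows
flatten_cohort_pairs <- function(cohort) {
  n <- nrow(cohort$atlas)
  ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  ns <- nrow(cohort$subjects)
  cnt <- matrix(0, ns, nrow(ut))
  len <- NULL
  for (s in seq_len(ns)) cnt[s, ] <- cohort$counts[s, , ][ut]
  if (!is.null(cohort$lengths)) {
    len <- matrix(0, ns, nrow(ut))
    for (s in seq_len(ns)) len[s, ] <- cohort$lengths[s, , ][ut]
  }
  list(pairs = ut, counts = cnt, lengths = len, n = n)
}

# metric of the backbone rebuilt from the given subject rows
subset_backbone_metric <- function(flat, rows, metric, n_edges) {
  s <- length(rows)
  cm <- flat$counts[rows, , drop = FALSE]
  mu <- colMeans(cm)
  v <- (colMeans(cm^2) - mu^2) * s / (s - 1)
  v[v < 0] <- 0
  sdm <- sqrt(v)
  snr <- ifelse(mu == 0, 0, ifelse(sdm == 0, Inf, mu / sdm))
  keep <- order(-snr, -mu, seq_along(snr))[seq_len(n_edges)]
  if (metric == "mean_length") {
    per_edge <- vapply(keep, function(p) {
      l <- flat$lengths[rows, p]
      l <- l[l > 0]
      if (length(l) == 0) NA_real_ else mean(l)
    }, numeric(1))
    return(mean(per_edge, na.rm = TRUE))
  }
  a <- matrix(0L, flat$n, flat$n)
  ep <- flat$pairs[keep, , drop = FALSE]
  a[ep] <- 1L
  a[ep[, c(2, 1), drop = FALSE]] <- 1L
  if (metric == "e_glob") {
    eff_from_adj(a)
  } else {
    mean(vapply(seq_len(flat$n), function(i) {
      nb <- which(a[i, ] > 0)
      if (length(nb) < 2) return(0)
      eff_from_adj(a[nb, nb, drop = FALSE])
    }, numeric(1)))
  }
}

#' Group comparison of backbone-level metrics
#'
#' Builds one backbone per group at the stated cost, computes a group-
#' level metric (global efficiency, local efficiency, or mean backbone
#' fiber length), and tests every pair of groups with a subject-
#' relabelling permutation test: because a backbone (and hence its
#' metric) is one value per group, the resampling unit is the subject —
#' each relabelling reassigns subjects to the two groups, rebuilds both
#' backbones from scratch and recomputes the metric difference.
#'
#' @param cohort A [fiber_cohort()].
#' @param grouping Metadata column to split on (`"age_group"` or
#'   `"sex"`).
#' @param metric One of `"e_glob"`, `"e_loc"`, `"mean_length"`.
#' @param cost Target backbone cost (default 0.21).
#' @param n_perm Permutations per pairwise test (default 1000).
#' @param seed RNG seed.
#' @return A list of class `group_comparison`: `groups` (tibble:
#'   `group`, `n_subjects`, `value`), `pairs` (tibble: `group_a`,
#'   `group_b`, `observed_diff`, `p_two_sided`), plus `metric`, `cost`,
#'   `n_perm`, `seed`.
#' @export
compare_groups <- function(cohort, grouping = "age_group",
                           metric = c("e_glob", "e_loc", "mean_length"),
                           cost = 0.21, n_perm = 1000, seed = 1L) {
  stopifnot(inherits(cohort, "fiber_cohort"))
  metric <- match.arg(metric)
  if (!grouping %in% names(cohort$subjects)) {
    stop("no metadata column '", grouping, "'", call. = FALSE)
  }
  if (metric == "mean_length" && is.null(cohort$lengths)) {
    stop("cohort has no fiber lengths", call. = FALSE)
  }
  labels <- as.character(cohort$subjects[[grouping]])
  groups <- unique(labels)
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(labels)
  if (any(sizes < 2)) {
    stop("every group needs at least 2 subjects; offending: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  flat <- flatten_cohort_pairs(cohort)
  k <- ncol(flat$counts)
  n_edges <- floor(cost * k + 0.5)
  if (n_edges < 1) stop("cost yields zero edges", call. = FALSE)
  vals <- vapply(groups, function(gp) {
    subset_backbone_metric(flat, which(labels == gp), metric, n_edges)
  }, numeric(1))
  combos <- combn(groups, 2)
  pairs <- purrr::map_dfr(seq_len(ncol(combos)), function(ci) {
    ga <- combos[1, ci]
    gb <- combos[2, ci]
    rows_a <- which(labels == ga)
    rows_b <- which(labels == gb)
    pool <- c(rows_a, rows_b)
    na <- length(rows_a)
    obs <- vals[[ga]] - vals[[gb]]
    perm <- vapply(seq_len(n_perm), function(i) {
      pa <- sample(pool, na)
      subset_backbone_metric(flat, pa, metric, n_edges) -
        subset_backbone_metric(flat, setdiff(pool, pa), metric, n_edges)
    }, numeric(1))
    tibble::tibble(group_a = ga, group_b = gb, observed_diff = obs,
                   p_two_sided = mean(abs(perm) >= abs(obs) - 1e-12))
  })
  structure(list(groups = tibble::tibble(group = groups,
                                         n_subjects = as.integer(sizes[groups]),
                                         value = unname(vals)),
                 pairs = pairs,
                 metric = metric, cost = cost,
                 n_perm = n_perm, seed = seed),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison: %s at cost %.2f, %d permutations>\n",
              x$metric, x$cost, x$n_perm))
  print(x$groups)
  print(x$pairs)
  invisible(x)
}
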