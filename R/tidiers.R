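#' @describeIn module_partition Per-node module assignment as a tibble
#'   (`node`, `label`, `module`).
#' @param x A `module_partition`.
#' @param ... Unused.
#' @export
tidy.module_partition <- function(x, ...) {
  tibble::tibble(node = seq_along(x$membership),
                 label = x$labels %||%
                   paste0("v", seq_along(x$membership)),
                 module = x$membership)
}

#' @describeIn module_partition One-row summary (`n_modules`, `q`,
#'   `n_edges`).
#' @export
glance.module_partition <- function(x, ...) {
  tibble::tibble(n_modules = x$n_modules, q = x$q, n_edges = x$n_edges)
}

#' @describeIn fit_degree_distribution Parameter estimates as a tibble.
#' @param x A `degree_fit`.
#' @param ... Unused.
#' @export
tidy.degree_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "k_cutoff", "log_c", "loglog_slope",
             "loglog_intercept"),
    estimate = c(x$alpha, x$k_cutoff, x$truncated$log_c,
                 x$line$slope, x$line$intercept)
  )
}

#' @describeIn fit_degree_distribution One-row goodness-of-fit summary.
#' @export
glance.degree_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, k_cutoff = x$k_cutoff,
                 r2_truncated = x$r2_truncated,
                 gradient_magnitude = x$gradient_magnitude,
                 r2_loglog = x$r2_loglog,
                 fit_k_min = x$fit_range[1], fit_k_max = x$fit_range[2])
}

#' @describeIn permutation_test One-row summary of the test.
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(observed = x$observed, p_two_sided = x$p_two_sided,
                 n_perm = x$n_perm, exact = x$exact)
}

#' @describeIn hemisphere_symmetry Coefficient table of the right-on-
#'   left regression.
#' @param x A `symmetry_fit`.
#' @param ... Unused.
#' @export
tidy.symmetry_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(s), estimate = unname(s[, 1]),
                 std.error = unname(s[, 2]),
                 statistic = unname(s[, 3]),
                 p.value = unname(s[, 4]))
}

#' @describeIn hemisphere_symmetry One-row summary (`slope`,
#'   `intercept`, `pearson_r`, `r.squared`, `n_pairs`).
#' @export
glance.symmetry_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 pearson_r = x$pearson_r,
                 r.squared = summary(x$model)$r.squared,
                 n_pairs = nrow(x$pairs))
}

#' @describeIn compare_groups Pairwise tests as a tibble.
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @export
tidy.group_comparison <- function(x, ...) {
  x$pairs
}

#' @describeIn compare_groups Per-group metric values as a tibble.
#' @export
glance.group_comparison <- function(x, ...) {
  tidyr::pivot_wider(x$groups[, c("group", "value")],
                     names_from = "group", values_from = "value")
}

#' @describeIn length_summary Per-edge mean lengths as a tibble.
#' @param x A `length_summary`.
#' @param ... Unused.
#' @export
tidy.length_summary <- function(x, ...) {
  x$edges
}

#' @describeIn length_summary One-row summary (`group`, `mean_length`,
#'   `q90`, `n_edges`).
#' @export
glance.length_summary <- function(x, ...) {
  tibble::tibble(group = x$group, mean_length = x$mean_length,
                 q90 = x$q90, n_edges = sum(!is.na(x$edges$mean_length)))
}
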