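#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a small-world sweep
#'
#' Local and global efficiency of the backbone against the rewired-
#' ensemble band and the matched lattice, across network cost.
#'
#' @param object A [smallworld_sweep()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.smallworld_sweep <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(cost = object$cost, panel = "global efficiency",
                   series = "backbone", value = object$e_glob,
                   lo = NA_real_, hi = NA_real_),
    tibble::tibble(cost = object$cost, panel = "global efficiency",
                   series = "rewired null",
                   value = object$e_glob_rand_mean,
                   lo = object$e_glob_rand_mean - object$e_glob_rand_sd,
                   hi = object$e_glob_rand_mean + object$e_glob_rand_sd),
    tibble::tibble(cost = object$cost, panel = "global efficiency",
                   series = "lattice", value = object$e_glob_latt,
                   lo = NA_real_, hi = NA_real_),
    tibble::tibble(cost = object$cost, panel = "local efficiency",
                   series = "backbone", value = object$e_loc,
                   lo = NA_real_, hi = NA_real_),
    tibble::tibble(cost = object$cost, panel = "local efficiency",
                   series = "rewired null",
                   value = object$e_loc_rand_mean,
                   lo = object$e_loc_rand_mean - object$e_loc_rand_sd,
                   hi = object$e_loc_rand_mean + object$e_loc_rand_sd),
    tibble::tibble(cost = object$cost, panel = "local efficiency",
                   series = "lattice", value = object$e_loc_latt,
                   lo = NA_real_, hi = NA_real_)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$cost, .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi,
                                      fill = .data$series),
                         alpha = 0.2, colour = NA, na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "network cost", y = "efficiency",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a broad-scale degree fit
#'
#' Degree CCDF on double-logarithmic axes with the fitted straight line
#' (power-law regime) and the truncated power-law curve.
#'
#' @param object A [fit_degree_distribution()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.degree_fit <- function(object, ...) {
  pts <- dplyr::filter(object$ccdf, .data$k > 0, .data$ccdf > 0)
  grid <- tibble::tibble(k = seq(min(pts$k), max(pts$k), length.out = 200))
  grid$trunc <- exp(object$truncated$log_c +
                      (object$alpha - 1) * log(grid$k) -
                      grid$k / object$k_cutoff)
  line_tbl <- dplyr::filter(pts, .data$k >= object$fit_range[1],
                            .data$k <= object$fit_range[2])
  line_tbl$fit <- exp(object$line$intercept +
                        object$line$slope * log(line_tbl$k))
  ggplot2::ggplot(pts, ggplot2::aes(.data$k, .data$ccdf)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$trunc,
                                    colour = "truncated power law")) +
    ggplot2::geom_line(data = line_tbl,
                       ggplot2::aes(y = .data$fit,
                                    colour = "log-log line")) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "P(K ≥ k)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot node roles in the (z, P) plane
#'
#' @param roles A [node_roles()] tibble.
#' @param z_cutoff,p_nonhub,p_hub Boundaries to draw; defaults match
#'   [node_roles()].
#' @return A ggplot.
#' @export
plot_node_roles <- function(roles, z_cutoff = 2.5,
                            p_nonhub = c(0.05, 0.62, 0.80),
                            p_hub = c(0.30, 0.75)) {
  ggplot2::ggplot(roles, ggplot2::aes(.data$p, .data$z,
                                      colour = .data$role)) +
    ggplot2::geom_hline(yintercept = z_cutoff, linetype = 2) +
    ggplot2::geom_vline(xintercept = p_nonhub, linetype = 3) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "participation coefficient P",
                  y = "within-module degree z", colour = "role") +
    ggplot2::theme_minimal()
}

#' Plot an inter-hemispheric symmetry fit
#'
#' Right-versus-left scatter with the OLS line and its confidence band;
#' the identity line marks perfect symmetry.
#'
#' @param object A [hemisphere_symmetry()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.symmetry_fit <- function(object, ...) {
  dat <- object$pairs
  grid <- tibble::tibble(left = seq(min(dat$left), max(dat$left),
                                    length.out = 100))
  ci <- predict(object$model, newdata = grid, interval = "confidence",
                level = object$level)
  grid <- dplyr::bind_cols(grid, tibble::as_tibble(ci))
  ggplot2::ggplot(dat, ggplot2::aes(.data$left, .data$right)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_ribbon(data = grid,
                         ggplot2::aes(x = .data$left, y = .data$fit,
                                      ymin = .data$lwr, ymax = .data$upr),
                         alpha = 0.2) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$fit), colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "left-hemisphere value",
                  y = "right-hemisphere value") +
    ggplot2::theme_minimal()
}

#' Plot fiber-length cumulative distributions
#'
#' Empirical CDFs of backbone-edge mean fiber lengths, one curve per
#' summary, with the 0.90 frequency line that separates the short-range
#' bulk from the long-fiber tail.
#'
#' @param ... Named [length_summary()] objects (names become curve
#'   labels).
#' @return A ggplot.
#' @export
plot_length_cdfs <- function(...) {
  summaries <- list(...)
  if (is.null(names(summaries)) || any(names(summaries) == "")) {
    names(summaries) <- vapply(summaries, function(s) s$group,
                               character(1))
  }
  dat <- purrr::imap_dfr(summaries, function(s, nm) {
    v <- sort(s$edges$mean_length[!is.na(s$edges$mean_length)])
    tibble::tibble(group = nm, length = v,
                   cdf = seq_along(v) / length(v))
  })
  ggplot2::ggplot(dat, ggplot2::aes(.data$length, .data$cdf,
                                    colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = 0.9, linetype = 2) +
    ggplot2::labs(x = "mean fiber length (mm)",
                  y = "cumulative frequency", colour = NULL) +
    ggplot2::theme_minimal()
}
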