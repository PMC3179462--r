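#' Complementary cumulative degree distribution
#'
#' `P(K >= k)` over the integer grid from the smallest to the largest
#' observed degree. Cumulative distributions smooth the noise of the raw
#' degree histogram and are the canvas for broad-scale fitting.
#'
#' @param g A [backbone_graph()].
#' @return A tibble with columns `k` and `ccdf` (nonincreasing;
#'   `ccdf = 1` at the smallest observed degree).
#' @examples
#' degree_ccdf(backbone_graph(4, rbind(c(1, 2), c(1, 3), c(1, 4))))
#' @export
degree_ccdf <- function(g) {
  deg <- node_degrees(g)
  k <- seq(min(deg), max(deg))
  tibble::tibble(k = k,
                 ccdf = vapply(k, function(x) mean(deg >= x), numeric(1)))
}

ccdf_points <- function(ccdf, fit_range = NULL) {
  pts <- dplyr::filter(ccdf, .data$k > 0, .data$ccdf > 0)
  if (!is.null(fit_range)) {
    if (length(fit_range) == 2) {
      pts <- dplyr::filter(pts, .data$k >= fit_range[1],
                           .data$k <= fit_range[2])
    } else {
      pts <- dplyr::filter(pts, .data$k %in% fit_range)
    }
  }
  pts
}

#' Straight-line fit in the double-logarithmic plot
#'
#' Least squares of `log P(K >= k)` on `log k`. The magnitude of the
#' slope is the "gradient magnitude" of the power-law regime; R-squared
#' (in log space) measures how well a pure power law describes the
#' range.
#'
#' @param ccdf A [degree_ccdf()] tibble.
#' @param fit_range Optional restriction: a length-2 `c(lo, hi)` range
#'   or an explicit vector of degrees. At least 3 positive points must
#'   remain.
#' @return A list of class `loglog_fit`: `slope`, `intercept`,
#'   `gradient_magnitude`, `r2`, `n_points`, `fit_range`, and
#'   `degenerate` (TRUE when the response had zero variance, where
#'   R-squared is defined as 1 by convention).
#' @export
fit_loglog_line <- function(ccdf, fit_range = NULL) {
  pts <- ccdf_points(ccdf, fit_range)
  if (nrow(pts) < 3) {
    stop("log-log fit needs >= 3 positive points in range", call. = FALSE)
  }
  y <- log(pts$ccdf)
  x <- log(pts$k)
  degenerate <- var(y) == 0
  if (degenerate) {
    fit <- list(slope = 0, intercept = mean(y), r2 = 1)
  } else {
    m <- lm(y ~ x)
    ss_res <- sum(stats::residuals(m)^2)
    ss_tot <- sum((y - mean(y))^2)
    fit <- list(slope = unname(coef(m)[2]),
                intercept = unname(coef(m)[1]),
                r2 = 1 - ss_res / ss_tot)
  }
  structure(list(slope = fit$slope, intercept = fit$intercept,
                 gradient_magnitude = abs(fit$slope), r2 = fit$r2,
                 n_points = nrow(pts),
                 fit_range = range(pts$k), degenerate = degenerate),
            class = "loglog_fit")
}

#' Truncated power-law fit to the degree CCDF
#'
#' Fits `P(K >= k) = c * k^(alpha - 1) * exp(-k / k_c)` — a power-law
#' regime with an exponential cutoff, the signature of broad-scale
#' networks — by least squares in log space. The model is linear in
#' `(log c, alpha - 1, -1/k_c)` with regressors `(1, log k, k)`, so the
#' log-space least-squares optimum is found exactly in one step. When
#' the fitted exponential coefficient is nonnegative (no cutoff within
#' the data), `k_cutoff` is reported as `Inf`.
#'
#' @param ccdf A [degree_ccdf()] tibble.
#' @param fit_range Optional restriction as in [fit_loglog_line()]; at
#'   least 4 positive points must remain.
#' @return A list of class `trunc_powerlaw_fit`: `alpha`, `k_cutoff`,
#'   `log_c`, `r2`, `n_points`, `fit_range`.
#' @export
fit_truncated_powerlaw <- function(ccdf, fit_range = NULL) {
  pts <- ccdf_points(ccdf, fit_range)
  if (nrow(pts) < 4) {
    stop("truncated power-law fit needs >= 4 positive points",
         call. = FALSE)
  }
  y <- log(pts$ccdf)
  lk <- log(pts$k)
  k <- pts$k
  m <- lm(y ~ lk + k)
  cf <- coef(m)
  if (anyNA(cf)) {
    stop("truncated power-law fit is degenerate (collinear predictors); ",
         "widen the fit range", call. = FALSE)
  }
  ss_res <- sum(stats::residuals(m)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(alpha = unname(cf["lk"]) + 1,
                 k_cutoff = if (cf["k"] < 0) unname(-1 / cf["k"]) else Inf,
                 log_c = unname(cf["(Intercept)"]),
                 r2 = r2, n_points = nrow(pts),
                 fit_range = range(pts$k)),
            class = "trunc_powerlaw_fit")
}

#' Full broad-scale characterisation of a degree distribution
#'
#' Builds the degree CCDF, fits the truncated power law over all
#' positive points, then fits the straight log-log line over the linear
#' regime — by default all degrees up to the estimated cutoff `k_c`
#' ("decays linearly before a sharp cutoff"), or an explicit range.
#'
#' @param g A [backbone_graph()].
#' @param linear_range Optional explicit range for the log-log line;
#'   default `k <= k_cutoff` from the truncated fit.
#' @return A list of class `degree_fit`: the `ccdf` tibble, `alpha`,
#'   `k_cutoff`, `r2_truncated`, `gradient_magnitude`, `r2_loglog`,
#'   `fit_range` (of the linear regime), plus the two component fits
#'   (`truncated`, `line`).
#' @export
fit_degree_distribution <- function(g, linear_range = NULL) {
  ccdf <- degree_ccdf(g)
  trunc <- fit_truncated_powerlaw(ccdf)
  if (is.null(linear_range)) {
    hi <- min(trunc$k_cutoff, max(ccdf$k))
    linear_range <- c(min(ccdf$k), hi)
    # keep enough points for a line even when the cutoff bites early
    if (sum(ccdf$k > 0 & ccdf$ccdf > 0 & ccdf$k <= hi) < 3) {
      linear_range <- range(ccdf$k)
    }
  }
  line <- fit_loglog_line(ccdf, fit_range = linear_range)
  structure(list(ccdf = ccdf,
                 alpha = trunc$alpha,
                 k_cutoff = trunc$k_cutoff,
                 r2_truncated = trunc$r2,
                 gradient_magnitude = line$gradient_magnitude,
                 r2_loglog = line$r2,
                 fit_range = line$fit_range,
                 truncated = trunc, line = line),
            class = "degree_fit")
}

#' @export
print.degree_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<degree_fit: alpha %.3f, k_c %.2f (R2 %.4f); ",
    "log-log gradient %.3f over k in [%d, %d] (R2 %.4f)>\n"),
    x$alpha, x$k_cutoff, x$r2_truncated, x$gradient_magnitude,
    x$fit_range[1], x$fit_range[2], x$r2_loglog))
  invisible(x)
}
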