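#' Configuration for a synthetic fiber-count cohort
#'
#' Defines the study conditions the generator emulates: a longitudinal
#' cohort (default 39 subjects, 18 male / 21 female, scanned in three
#' age groups) whose anatomical ground truth is a modular backbone over
#' a 78-region cortical atlas. The backbone is a degree-corrected
#' stochastic block model: hemisphere-paired modules with dense
#' within-module wiring, plus lognormal node propensities that produce
#' the broad-scale (heavy-tailed, but not scale-free) degree sequence
#' observed in cortical networks. Consistent (true-edge) fiber counts
#' are negative-binomial; spurious connections appear independently per
#' subject at a low rate with strongly overdispersed low counts, which
#' is what makes the SNR consistency filter discriminative. Fiber
#' lengths are lognormal around an age-group mean, emulating the
#' maturation-driven lengthening of reconstructed fibers.
#'
#' @param atlas A [region_atlas()]; default the 78-region cortical AAL
#'   atlas.
#' @param groups Tibble with one row per age group: `group` label,
#'   `count_factor` (multiplier on the consistent count mean; neonates
#'   yield fewer reconstructed fibers) and `length_mean_mm` (group mean
#'   fiber length).
#' @param n_subjects_per_group,n_male Cohort size per group and number
#'   of male subjects (the rest are female); subjects are longitudinal,
#'   so the same ids recur in every group.
#' @param modules_truth Integer membership vector over regions (the
#'   planted partition), or `NULL` for the default: 4 hemisphere-paired
#'   modules of near-equal stem blocks.
#' @param p_in,p_out Within/between-module base edge probabilities,
#'   `0 <= p_out < p_in <= 1`.
#' @param propensity_sdlog Spread (sdlog) of the mean-1 lognormal node
#'   propensities; 0 gives a plain stochastic block model.
#' @param count_mean_consistent,count_dispersion Negative-binomial mean
#'   and size for fiber counts on true edges.
#' @param noise_edge_rate Probability that a non-backbone pair receives
#'   spurious counts in a given subject.
#' @param noise_count_mean,noise_count_dispersion Negative-binomial mean
#'   and size for spurious counts (small mean, strong overdispersion).
#' @param length_pair_sdlog,length_subject_sdlog Lognormal spread of the
#'   stable per-pair length profile and of the per-subject length noise.
#' @param sex_count_factor Named multipliers (`M`, `F`) on the count
#'   mean; both 1 by default (no planted sex effect).
#' @param seed RNG seed; the cohort is fully reproducible from it.
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(atlas = aal78_atlas(),
                          groups = tibble::tibble(
                            group = c("2wk", "1yr", "2yr"),
                            count_factor = c(0.6, 1, 1),
                            length_mean_mm = c(40.22, 66.16, 62.45)
                          ),
                          n_subjects_per_group = 39,
                          n_male = 18,
                          modules_truth = NULL,
                          p_in = 0.85,
                          p_out = 0.08,
                          propensity_sdlog = 0.75,
                          count_mean_consistent = 40,
                          count_dispersion = 8,
                          noise_edge_rate = 0.15,
                          noise_count_mean = 3,
                          noise_count_dispersion = 0.5,
                          length_pair_sdlog = 0.3,
                          length_subject_sdlog = 0.3,
                          sex_count_factor = c(M = 1, F = 1),
                          seed = 1L) {
  groups <- tibble::as_tibble(groups)
  if (nrow(groups) == 0) stop("groups must be nonempty", call. = FALSE)
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop("need 0 <= p_out < p_in <= 1", call. = FALSE)
  }
  if (count_dispersion <= 0 || noise_count_dispersion <= 0) {
    stop("dispersion parameters must be > 0", call. = FALSE)
  }
  if (n_male < 0 || n_male > n_subjects_per_group) {
    stop("n_male must be between 0 and n_subjects_per_group",
         call. = FALSE)
  }
  n <- nrow(atlas)
  if (is.null(modules_truth)) {
    modules_truth <- default_planted_modules(atlas)
  }
  modules_truth <- as.integer(modules_truth)
  if (length(modules_truth) != n || anyNA(modules_truth)) {
    stop("modules_truth must assign every region to a module",
         call. = FALSE)
  }
  structure(list(
    atlas = atlas, groups = groups,
    n_subjects_per_group = as.integer(n_subjects_per_group),
    n_male = as.integer(n_male),
    modules_truth = modules_truth,
    p_in = p_in, p_out = p_out,
    propensity_sdlog = propensity_sdlog,
    count_mean_consistent = count_mean_consistent,
    count_dispersion = count_dispersion,
    noise_edge_rate = noise_edge_rate,
    noise_count_mean = noise_count_mean,
    noise_count_dispersion = noise_count_dispersion,
    length_pair_sdlog = length_pair_sdlog,
    length_subject_sdlog = length_subject_sdlog,
    sex_count_factor = sex_count_factor,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# 4 hemisphere-paired modules: contiguous blocks of label stems, so the
# left and right partner of a stem always share a module
default_planted_modules <- function(atlas, n_modules = 4) {
  n <- nrow(atlas)
  pairs <- tryCatch(atlas_pairs(atlas), error = function(e) NULL)
  if (is.null(pairs)) {
    return(as.integer(cut(seq_len(n), n_modules, labels = FALSE)))
  }
  stem_module <- as.integer(cut(seq_len(nrow(pairs)), n_modules,
                                labels = FALSE))
  mem <- integer(n)
  mem[pairs$left] <- stem_module
  mem[pairs$right] <- stem_module
  mem
}

#' Plant a ground-truth modular backbone
#'
#' Draws one realisation of the degree-corrected stochastic block model
#' defined by a [cohort_config()]: node propensities `w_i` are mean-1
#' lognormal, and a pair `(i, j)` is an edge with probability
#' `min(1, p_base * w_i * w_j)` where `p_base` is `p_in` within a
#' planted module and `p_out` between modules.
#'
#' @param config A [cohort_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A list with elements `graph` (a [backbone_graph()]),
#'   `partition` (the planted [module_partition()]) and `propensity`
#'   (the node weights). Warns when `p_in` times the smallest module
#'   size is below 1 (isolated modules become likely).
#' @export
plant_backbone <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- nrow(config$atlas)
  mem <- config$modules_truth
  min_size <- min(tabulate(mem))
  if (config$p_in * min_size < 1) {
    warning("p_in times the smallest module size is below 1; ",
            "expect isolated modules", call. = FALSE)
  }
  s <- config$propensity_sdlog
  w <- if (s > 0) rlnorm(n, -s^2 / 2, s) else rep(1, n)
  ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
  base <- ifelse(mem[ut[, 1]] == mem[ut[, 2]], config$p_in, config$p_out)
  p <- pmin(1, base * w[ut[, 1]] * w[ut[, 2]])
  keep <- runif(length(p)) < p
  g <- backbone_graph(n, ut[keep, , drop = FALSE],
                      labels = config$atlas$label)
  list(graph = g,
       partition = if (nrow(g$edges) > 0) module_partition(g, mem),
       propensity = w)
}

#' Sample a synthetic fiber-count cohort
#'
#' Generates the full cohort described by a [cohort_config()]: one
#' anatomical backbone planted once (shared by all age groups — group
#' effects act on counts and lengths, not wiring), negative-binomial
#' fiber counts on true edges, independent per-subject spurious
#' connections elsewhere, and lognormal fiber lengths whose group means
#' follow `groups$length_mean_mm`. All draws derive from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A [fiber_cohort()] whose `"truth"` attribute carries the
#'   planted `graph`, `partition` and `propensity` from
#'   [plant_backbone()].
#' @examples
#' cfg <- cohort_config(n_subjects_per_group = 4, seed = 7)
#' cohort <- sample_cohort(cfg)
#' cohort
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  truth <- plant_backbone(config)          # seeds the RNG stream
  n <- nrow(config$atlas)
  ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
  np <- nrow(ut)
  edge_key <- paste(truth$graph$edges[, 1], truth$graph$edges[, 2])
  is_edge <- paste(ut[, 1], ut[, 2]) %in% edge_key
  nt <- sum(is_edge)

  # stable per-pair length profile (anatomical distances do not vary
  # by subject), mean 1
  ps <- config$length_pair_sdlog
  pair_len <- if (ps > 0) rlnorm(np, -ps^2 / 2, ps) else rep(1, np)

  nsub <- config$n_subjects_per_group
  sex <- rep(c("M", "F"), c(config$n_male, nsub - config$n_male))
  base_id <- sprintf("s%02d", seq_len(nsub))
  subjects <- tidyr::crossing(
    group = factor(config$groups$group, levels = config$groups$group),
    idx = seq_len(nsub)
  )
  subjects <- dplyr::transmute(
    subjects,
    subject_id = sprintf("%s_%s", base_id[.data$idx], .data$group),
    base_id = base_id[.data$idx],
    age_group = as.character(.data$group),
    sex = sex[.data$idx]
  )
  ns <- nrow(subjects)
  counts <- array(0, dim = c(ns, n, n))
  lengths <- array(0, dim = c(ns, n, n))
  ss <- config$length_subject_sdlog
  for (s in seq_len(ns)) {
    grp <- subjects$age_group[s]
    grow <- config$groups[config$groups$group == grp, ]
    mu <- config$count_mean_consistent * grow$count_factor *
      config$sex_count_factor[[subjects$sex[s]]]
    cnt <- numeric(np)
    cnt[is_edge] <- rnbinom(nt, mu = mu, size = config$count_dispersion)
    on <- runif(np - nt) < config$noise_edge_rate
    cnt[!is_edge] <- rnbinom(np - nt, mu = config$noise_count_mean,
                             size = config$noise_count_dispersion) * on
    subj_len <- if (ss > 0) rlnorm(np, -ss^2 / 2, ss) else rep(1, np)
    len <- grow$length_mean_mm * pair_len * subj_len * (cnt > 0)
    m <- matrix(0, n, n)
    m[ut] <- cnt
    counts[s, , ] <- m + t(m)
    ml <- matrix(0, n, n)
    ml[ut] <- len
    lengths[s, , ] <- ml + t(ml)
  }
  out <- fiber_cohort(counts, subjects, config$atlas, lengths = lengths)
  attr(out, "truth") <- truth
  out
}
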