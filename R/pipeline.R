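#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis: the synthetic-cohort
#' configuration (ignored when a cohort is supplied to
#' [run_pipeline()]), the working backbone cost, the cost grid for the
#' sweeps, null-ensemble and permutation sizes, and the master seed
#' from which all stage seeds are derived.
#'
#' @param cohort A [cohort_config()] for the simulate stage.
#' @param cost Working network cost (default 0.21, the smallest cost at
#'   which the backbone is typically fully connected).
#' @param sweep_costs Cost grid for the small-world and modularity
#'   sweeps.
#' @param n_null Rewired realisations per cost in the sweeps.
#' @param n_perm Permutations per group test in the bundled report
#'   (kept moderate because each permutation rebuilds two backbones;
#'   [permutation_test()] itself defaults to 1000).
#' @param seed Master seed. Stage seeds are drawn from it by seeding
#'   the RNG once and taking one integer per stage, in stage order
#'   (simulate, small-world, modularity, comparisons).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            cost = 0.21,
                            sweep_costs = c(0.10, 0.15, 0.21, 0.30),
                            n_null = 20,
                            n_perm = 200,
                            seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"),
            cost > 0, cost <= 1, all(sweep_costs > 0 & sweep_costs <= 1))
  structure(list(cohort = cohort, cost = cost,
                 sweep_costs = sweep_costs,
                 n_null = as.integer(n_null),
                 n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

role_counts <- function(roles) {
  as.list(table(factor(roles$role, levels = LETTERS[1:7])))
}

#' Run the full backbone analysis pipeline
#'
#' Reproduces the whole analysis sequence on one cohort: simulate (or
#' take the given cohort), build per-group SNR backbones at the working
#' cost, check connectedness across the cost grid, compute efficiency
#' and centrality metrics, run the small-world and modularity null
#' sweeps, detect communities and classify node roles, fit the degree
#' distribution, summarise fiber lengths, regress hemispheric symmetry
#' of betweenness, and run the group comparisons (age on mean fiber
#' length and global efficiency; sex on global and local efficiency
#' within each age group). Deterministic given the config's seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, a
#'   machine-readable `summary.json` plus per-group CSV / Pajek files
#'   are written there.
#' @param cohort Optional [fiber_cohort()]; when `NULL` the cohort is
#'   simulated from `config$cohort`.
#' @return Invisibly, a list with the cohort, all per-group results and
#'   the `summary` list that `summary.json` serialises.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 10L, 4)
  names(stage_seeds) <- c("simulate", "smallworld", "modularity",
                          "comparisons")
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
  }
  if (is.null(cohort)) {
    cohort <- run_stage("simulate", {
      cfg <- config$cohort
      cfg$seed <- stage_seeds[["simulate"]]
      sample_cohort(cfg)
    })
  }
  groups <- unique(cohort$subjects$age_group)
  has_lengths <- !is.null(cohort$lengths)

  per_group <- lapply(setNames(groups, groups), function(gp) {
    run_stage(paste0("group:", gp), {
      snr <- compute_snr(cohort, gp)
      sweep_tab <- cost_sweep(snr, config$sweep_costs)
      g <- threshold_to_cost(snr, config$cost)
      eff <- efficiency_report(g)
      nm <- node_metrics(g)
      part <- detect_communities(g)
      roles <- node_roles(g, part)
      # degenerate at extreme costs (e.g. a regular complete graph has a
      # single-point CCDF); the report then simply omits the fit
      dfit <- tryCatch(fit_degree_distribution(g),
                       error = function(e) NULL)
      sw <- smallworld_sweep(snr, config$sweep_costs,
                             n_null = config$n_null,
                             seed = stage_seeds[["smallworld"]])
      qs <- nonrandom_modularity_sweep(snr, config$sweep_costs,
                                       n_null = config$n_null,
                                       seed = stage_seeds[["modularity"]])
      sym <- tryCatch(suppressWarnings(
        hemisphere_symmetry(nm, cohort$atlas)),
        error = function(e) NULL)
      lens <- if (has_lengths) length_summary(cohort, g, gp)
      list(snr = snr, graph = g, sweep = sweep_tab, efficiency = eff,
           node_metrics = nm, partition = part, roles = roles,
           degree_fit = dfit, smallworld = sw, modularity = qs,
           symmetry = sym, lengths = lens)
    })
  })

  comparisons <- run_stage("comparisons", {
    cs <- stage_seeds[["comparisons"]]
    out <- list()
    if (length(groups) >= 2) {
      if (has_lengths) {
        out$age_mean_length <- compare_groups(
          cohort, "age_group", "mean_length", cost = config$cost,
          n_perm = config$n_perm, seed = cs)
      }
      out$age_e_glob <- compare_groups(
        cohort, "age_group", "e_glob", cost = config$cost,
        n_perm = config$n_perm, seed = cs + 1L)
    }
    if ("sex" %in% names(cohort$subjects) &&
        length(unique(cohort$subjects$sex)) == 2) {
      out$sex_by_age <- purrr::map(setNames(groups, groups), function(gp) {
        sub <- cohort_subset(cohort,
                             cohort$subjects$age_group == gp)
        list(e_glob = compare_groups(sub, "sex", "e_glob",
                                     cost = config$cost,
                                     n_perm = config$n_perm,
                                     seed = cs + 2L),
             e_loc = compare_groups(sub, "sex", "e_loc",
                                    cost = config$cost,
                                    n_perm = config$n_perm,
                                    seed = cs + 3L))
      })
    }
    out
  })

  summary <- list(
    seeds = c(list(master = config$seed), as.list(stage_seeds)),
    cost = config$cost,
    sweep_costs = config$sweep_costs,
    n_null = config$n_null,
    n_perm = config$n_perm,
    n_regions = nrow(cohort$atlas),
    n_scans = nrow(cohort$subjects),
    groups = lapply(per_group, function(r) {
      out <- list(
        realized_cost = attr(r$graph, "realized_cost"),
        n_edges = nrow(r$graph$edges),
        largest_component = r$efficiency$largest_component,
        e_glob = r$efficiency$e_glob,
        e_loc = r$efficiency$e_loc,
        q = r$partition$q,
        n_modules = r$partition$n_modules,
        q_rand_mean = r$modularity$q_rand_mean[
          r$modularity$cost == config$cost][1],
        q_rand_sd = r$modularity$q_rand_sd[
          r$modularity$cost == config$cost][1],
        small_world = setNames(as.list(r$smallworld$small_world),
                               paste0("cost_", r$smallworld$cost)),
        degree_fit = if (!is.null(r$degree_fit)) {
          as.list(glance(r$degree_fit))
        },
        symmetry = if (!is.null(r$symmetry)) {
          list(slope = r$symmetry$slope,
               intercept = r$symmetry$intercept,
               pearson_r = r$symmetry$pearson_r)
        },
        role_counts = role_counts(r$roles)
      )
      if (!is.null(r$lengths)) {
        out$mean_fiber_length <- r$lengths$mean_length
        out$length_q90 <- r$lengths$q90
      }
      out
    }),
    comparisons = local({
      flat <- list()
      if (!is.null(comparisons$age_mean_length)) {
        flat$age_mean_length <- tidy(comparisons$age_mean_length)
      }
      if (!is.null(comparisons$age_e_glob)) {
        flat$age_e_glob <- tidy(comparisons$age_e_glob)
      }
      if (!is.null(comparisons$sex_by_age)) {
        flat$sex_by_age <- lapply(comparisons$sex_by_age, function(x) {
          list(e_glob = tidy(x$e_glob), e_loc = tidy(x$e_loc))
        })
      }
      flat
    })
  )

  if (!is.null(out_dir)) {
    run_stage("report", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      for (gp in groups) {
        r <- per_group[[gp]]
        stub <- function(name, ext = "csv") {
          file.path(out_dir, sprintf("%s_%s.%s", name, gp, ext))
        }
        readr::write_csv(r$node_metrics, stub("node_metrics"),
                         progress = FALSE)
        readr::write_csv(r$roles, stub("roles"), progress = FALSE)
        readr::write_csv(tidy(r$partition), stub("partition"),
                         progress = FALSE)
        if (!is.null(r$degree_fit)) {
          readr::write_csv(r$degree_fit$ccdf, stub("degree_ccdf"),
                           progress = FALSE)
        }
        readr::write_csv(tibble::as_tibble(r$smallworld),
                         stub("smallworld"), progress = FALSE)
        readr::write_csv(r$modularity, stub("modularity"),
                         progress = FALSE)
        write_pajek(r$graph, stub("backbone", "net"),
                    partition = r$partition)
      }
    })
  }
  invisible(list(cohort = cohort, per_group = per_group,
                 comparisons = comparisons, summary = summary,
                 stage_seeds = stage_seeds))
}
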