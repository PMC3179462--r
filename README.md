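# fibernet

Structural brain-network analysis from multi-subject fiber-count
cohorts.

Tractography pipelines summarise a subject's white-matter wiring as a
symmetric matrix of fiber counts over a fixed cortical atlas (here the
78-region cortical AAL parcellation, 39 per hemisphere). Counts vary
strongly across subjects and with reconstruction yield, so fibernet
works with the *consistency backbone*: for every region pair it
computes the connectivity SNR — the mean fiber count across subjects
divided by its standard deviation (the reciprocal coefficient of
variation) — and keeps the top `round(cost * N(N-1)/2)` pairs at a
chosen network cost. The backbone is then analysed as a simple
unweighted graph:

- **Small-worldness** — global efficiency
  `E_glob = (1/(N(N-1))) Σ_{i≠j} 1/d_ij` and local efficiency
  `E_loc` (mean neighbourhood efficiency), compared against
  degree-preserving rewired nulls (Maslov–Sneppen double-edge swaps)
  and matched ring lattices across a cost sweep.
- **Modularity and roles** — fast-greedy (Clauset–Newman–Moore)
  optimisation of `Q = Σ_s [l_s/L − (d_s/2L)²]`, rewired-null
  comparison, and Guimerà–Amaral role cartography from the
  within-module degree z-score and participation coefficient
  `P_i = 1 − Σ_s (κ_is/k_i)²`.
- **Broad-scale degree structure** — CCDF-based fits of the log-log
  line and the truncated power law
  `P(K ≥ k) = c·k^(α−1)·exp(−k/k_c)`.
- **Centrality and robustness** — normalised betweenness (star hub =
  1) and vulnerability (relative `E_glob` drop under node deletion).
- **Group statistics** — subject-relabelling permutation tests for
  age/sex differences in backbone metrics and fiber lengths, and
  left/right symmetry regression of node betweenness.
- **Synthetic cohorts** — a seeded generator (degree-corrected
  stochastic block model backbone, negative-binomial counts, spurious
  low-SNR connections, age-shifted lognormal fiber lengths) that
  emulates a longitudinal pediatric cohort of 39 subjects × 3 age
  groups, so the whole pipeline is testable without imaging data.

Intended users: researchers analysing region-level structural
connectomes who want a tested, scriptable R implementation of this
classic backbone workflow, with tibble outputs, `tidy()`/`glance()`
methods and ggplot2 `autoplot()`s.

## Worked example

```r
library(fibernet)

cohort <- sample_cohort(cohort_config(seed = 1))
cohort
#> <fiber_cohort: 117 subjects, 78 regions, with fiber lengths>
#>   age_group sex       n
#> 1 1yr       F        21
#> 2 1yr       M        18
#> 3 2wk       F        21
#> ...

snr <- compute_snr(cohort, group = "1yr")
backbone <- threshold_to_cost(snr, 0.21)
efficiency_report(backbone)
#>   n_nodes n_edges  cost e_glob e_loc largest_component
#> 1      78     631 0.210  0.576 0.703                77
```

631 edges is exactly `round(0.21 * 3003)`. `E_glob = 0.58` and
`E_loc = 0.70` say a message can cross the whole network in roughly
`1/0.58 ≈ 1.7` hops on average while neighbourhoods stay densely
inter-wired; one node fell below the backbone threshold at this cost
(largest component 77 of 78 — `cost_sweep()` shows where it joins).

```r
sw <- smallworld_sweep(snr, c(0.10, 0.15, 0.21, 0.30), n_null = 20, seed = 2)
dplyr::select(sw, cost, e_glob, e_loc, e_loc_rand_mean, e_glob_latt, small_world)
#>    cost e_glob e_loc e_loc_rand_mean e_glob_latt small_world
#> 1  0.1   0.463 0.348           0.237       0.292 TRUE
#> 2  0.15  0.526 0.552           0.434       0.381 TRUE
#> 3  0.21  0.576 0.703           0.582       0.470 TRUE
#> 4  0.3   0.649 0.691           0.660       0.575 TRUE
```

At every cost the backbone is more locally efficient than its
degree-matched rewired nulls and more globally efficient than its
matched lattice — the small-world signature.

```r
detect_communities(backbone)
#> <module_partition: 5 modules over 78 nodes, Q = 0.3841>

glance(fit_degree_distribution(backbone, linear_range = c(12, 36)))
#>   alpha k_cutoff r2_truncated gradient_magnitude r2_loglog ...
#> 1  1.76     5.94        0.985               2.94     0.961
```

The truncated power law describes the degree CCDF well
(R² = 0.985) with a finite cutoff — hubs exist but extreme hubs do
not (broad-scale, not scale-free) — and the decaying regime of the
log-log plot has gradient magnitude 2.9.

```r
compare_groups(cohort, "age_group", "mean_length", cost = 0.21,
               n_perm = 200, seed = 3)
#> <group_comparison: mean_length at cost 0.21, 200 permutations>
#>   group n_subjects value
#> 1 2wk           39  40.7
#> 2 1yr           39  67.0
#> 3 2yr           39  63.3
#>   group_a group_b observed_diff p_two_sided
#> 1 2wk     1yr            -26.2            0
#> 2 2wk     2yr            -22.6            0
#> 3 1yr     2yr              3.65           0
```

Backbone fibers of the 2-week group are ~25 mm shorter than in the
older groups, and even the small 3.7 mm dip from 1 to 2 years is
resolved (every p is below 1/200 under subject-relabelling
permutation; a literal 0 proportion is reported with a warning) —
the generator's planted age profile of mean fiber lengths, recovered.

The full sequence — simulate, per-group backbones, metrics, null
sweeps, communities/roles, degree fits, group tests, JSON + CSV +
Pajek report — is one call:

```r
run_pipeline(pipeline_config(seed = 1), out_dir = "report")
```

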