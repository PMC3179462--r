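---
title: "Consistency backbones and small-world analysis of fiber-count cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consistency backbones and small-world analysis of fiber-count cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

fibernet analyses structural brain networks built from multi-subject
fiber-count matrices: for each pair of cortical regions in a fixed
atlas, a tractography pipeline has counted the streamline fibers
connecting them, and the question is what the *population-consistent*
wiring — the backbone — looks like as a graph. This vignette explains
the models and conventions the package implements, why the defaults
are what they are, and what its synthetic cohorts can and cannot tell
you about real imaging data.

## From counts to a backbone

Fiber counts are noisy and their absolute scale depends on how many
streamlines a subject's tractography reconstructs, so the package
never interprets counts as edge weights. Instead, for every region
pair it computes the *connectivity SNR* across a group of subjects:

$$\mathrm{SNR}_{ij} = \mu_{ij} / \sigma_{ij},$$

the reciprocal coefficient of variation of the fiber count. A pair
connected by a consistent number of fibers — whatever that number is —
scores high; a pair that appears sporadically with wildly varying
counts scores low. Because numerator and denominator scale together,
the statistic is invariant to rescaling all of a pair's counts, which
removes the per-subject reconstruction-yield confound.

Conventions, chosen where the definition leaves room:

* the SD uses the sample (n−1) denominator, the usual cohort
  convention;
* a subject without the connection contributes a zero count — absence
  of a tract is evidence, not missing data;
* a positive-mean, zero-variance pair gets `SNR = Inf` and ranks above
  every finite value (perfectly consistent connections are maximally
  reliable under this logic), ordered among themselves by mean count;
* a zero-mean pair gets `SNR = 0`.

The SNR matrix is thresholded *by cost*, not by value: with
$K = N(N-1)/2$ possible edges, `threshold_to_cost()` keeps the top
$E = \mathrm{round}(c \cdot K)$ pairs (half-up rounding; the
definition speaks of a cost, so some deterministic edge-count
convention is needed). Ties break by higher mean count, then by
lexicographic pair index, which makes the result invariant to region
order and makes edge sets nest across increasing costs. The default
working cost is 0.21 — on the 78-region atlas that is 631 of 3003
pairs — chosen as the region where `cost_sweep()` typically shows the
largest connected component reaching all nodes; the sweep is there to
verify that on your data rather than assume it.

## The graph metrics

All metrics treat the backbone as a simple undirected unweighted
graph. Distances are hop counts from breadth-first search, and
disconnected pairs contribute zero to every inverse-distance sum.

*Global efficiency* is the mean inverse shortest-path length over
ordered pairs,
$E_{glob} = \frac{1}{N(N-1)} \sum_{i \ne j} 1/d_{ij}$ — the capacity
for parallel, integrated transfer. *Local efficiency* is the mean over
nodes of the global efficiency of each node's neighbour-induced
subgraph, computed with the subgraph's own node count in the
normalisation; nodes of degree ≤ 1 have no meaningful neighbourhood
and contribute 0 (the definition is silent on the degenerate case;
this is the standard Latora–Marchiori reading). *Cost* is
$|E|/K$. *Betweenness* sums, over unordered pairs, the fraction of
shortest paths through a node, normalised by $(N-1)(N-2)/2$ so a star
hub scores exactly 1; it is computed with Brandes' dependency
accumulation and verified in the tests against explicit path
enumeration. *Vulnerability* of node $i$ is the relative drop in
global efficiency when $i$ is deleted, with the damaged graph
normalised by its own $N-1$ nodes — the efficiency definition applied
verbatim to the damaged graph, which is why removing a peripheral node
can make vulnerability slightly negative.

## Null models and the small-world verdict

A backbone is called small-world when it beats each null family on its
own ground: local efficiency above the mean of degree-preserving
*rewired* random graphs (Maslov–Sneppen double-edge swaps, default 10
attempted swaps per edge, rejecting self-loops and duplicates; the
degree sequence is preserved exactly, so degree effects cannot explain
the difference) and global efficiency above a *matched ring lattice*
(same node and edge count, edges filled in increasing circular
distance, a construction that concentrates wiring locally and so
penalises long-range communication; ring lattices are the
Watts–Strogatz convention and the natural reading of "regular
lattice"). The default ensemble size is 100 realisations per cost in
the user-facing functions — ensemble SDs on 78-node graphs stabilise
well below that — and 20 in the bundled pipeline report, which is the
size at which the pipeline's own assertions (ordering of means, not
tail probabilities) are already stable.

## Modularity, communities and roles

Modularity of a partition is
$Q = \sum_s [\, l_s/L - (d_s/2L)^2 \,]$ with $l_s$ the within-module
edge count and $d_s$ the summed member degrees. `detect_communities()`
implements the fast agglomerative (Clauset–Newman–Moore) optimiser:
start from singletons, repeatedly merge the edge-connected pair of
communities with the largest $\Delta Q$, and return the best partition
seen along the merge path. Ties are broken by the lowest
community-id pair (ids are the smallest member node), purely for
reproducibility. Separate components can never merge, so isolated
nodes remain singleton modules. The tests bound the greedy optimum
against exhaustive partition search on small graphs and check
recovery of planted partitions (adjusted Rand index) at realistic
sizes.

Node roles use the Guimerà–Amaral cartography: the within-module
degree z-score (population SD within each module; a zero-SD module
maps to z = 0 for all members, avoiding spurious ±∞ for uniform
modules) and the participation coefficient
$P_i = 1 - \sum_s (\kappa_{is}/k_i)^2$. Nodes with $z > 2.5$ are
module hubs. The P boundaries default to the standard scheme —
non-hubs split at 0.05 / 0.62 / 0.80 into ultra-peripheral (A),
peripheral (B), connector (C) and kinless (D); hubs split at
0.30 / 0.75 into provincial (E), connector (F) and kinless (G) — and
are configurable, since different atlases and costs shift where mass
sits in the (z, P) plane. Isolated nodes have undefined P; they are
reported as P = 0, role A, with a `degenerate` flag.

## Broad-scale degree fitting

Degree distributions are characterised on the complementary cumulative
distribution $P(K \ge k)$, which smooths histogram noise. Two fits are
reported: a straight line on the double-logarithmic plot (its absolute
slope is the "gradient magnitude" of the power-law regime) and the
truncated power law

$$P(K \ge k) = c\, k^{\alpha - 1} e^{-k/k_c},$$

the broad-scale signature — hubs exist, extreme hubs do not. Both are
least-squares fits in log space. A point worth knowing: the truncated
model is *linear* in $(\log c,\ \alpha - 1,\ -1/k_c)$ with regressors
$(1,\ \log k,\ k)$, so its log-space least-squares optimum is found
exactly by one linear solve — no iterative optimiser, no multi-start,
no convergence failures. When the fitted exponential coefficient is
nonnegative the data show no cutoff inside the observed range and
$k_c$ is reported as `Inf`, which correctly lands above the maximum
observed degree. The linear regime for the log-log line defaults to
$k \le \hat k_c$ ("linear before the sharp cutoff"); when that leaves
fewer than three points the full positive range is used, and an
explicit range can always be supplied. R² in a zero-variance response
is defined as 1 and flagged.

## Permutation testing and group comparisons

Group differences are tested by pooling and relabelling: the two-sided
p-value is the literal proportion of relabellings whose absolute
statistic is at least the absolute observed one, with no add-one
correction (a p of exactly 0 triggers a warning, since a Monte-Carlo
zero should be reported as below 1/n_perm). Exhaustive enumeration is
available for small samples. The default is 1000 random permutations.

Backbone-level metrics pose a subtlety: a group's efficiency is one
number per group, not per subject, so there is nothing to t-test. The
resampling unit is therefore the *subject*: every relabelling
reassigns subjects to the two groups, rebuilds both group backbones
from the permuted subject sets at the same cost, and recomputes the
metric difference. This is the only unit that preserves the backbone
construction; it is also what makes these tests computationally heavy,
which is why the bundled pipeline report uses 200 permutations per
pairwise test (the tests' calibration checks use the cheap vector
statistic at 200–2000 permutations, and 500 null replicates).

Hemispheric symmetry is assessed by pairing each left region with its
right partner via the label stem and regressing right on left node
betweenness by OLS, with normal-theory confidence bands; slope 1 with
high correlation is perfect symmetry.

## The synthetic cohort generator

The generator exists so every downstream stage is testable without any
imaging data. Its defaults encode the study design the package
targets: 39 longitudinal subjects (18 male, 21 female) scanned in
three age groups (2 weeks, 1 year, 2 years) over the 78-region
cortical atlas.

The anatomical ground truth is a single degree-corrected stochastic
block model planted once per cohort: four hemisphere-paired modules
(contiguous stem blocks, so left and right partners share a module),
within-module base probability 0.85, between-module 0.08, and mean-1
lognormal node propensities with sdlog 0.75. The propensities give the
degree sequence its heavy right tail — a plain SBM has binomial
degrees and could never exercise the broad-scale fitting code — while
the blocks give the modularity the community detector must find. These
values were chosen once, by simulating the planted graph across seeds
until its expected cost sat near the 0.21 working regime and its
maximum degree reliably exceeded twice the median, and then frozen.

Counts on true edges are negative binomial (mean 40, size 8), *not*
Poisson: the SNR filter separates consistent from spurious connections
only because overdispersion differs between them. Spurious connections
appear independently per subject on non-backbone pairs at rate 0.15
with strongly overdispersed low counts (mean 3, size 0.5) — across
subjects these pairs have small means and large SDs, which is exactly
what the SNR statistic rejects. Neonate scans yield fewer fibers
(count factor 0.6 for the 2-week group); since SNR is
scale-invariant, this changes yields without changing backbone
recovery, mirroring the real confound. Fiber lengths are lognormal
around the group means 40.22 / 66.16 / 62.45 mm with a stable per-pair
profile (anatomical distances do not vary by subject, all lengths
being defined in a common stereotaxic space) times per-subject noise;
older groups therefore have stochastically longer fibers. No sex
effect is planted by default; tests that need one set a
`sex_count_factor` or group effect explicitly.

What the generator does **not** emulate — and hence what passing tests
do not demonstrate about real data: mirrored left/right wiring (the
hemispheres are modularly paired but wired independently, so the
synthetic inter-hemispheric betweenness regression centres on slope 0
rather than the positive slopes real cohorts show); spatial geometry
(lengths are draws, not distances between region centroids, so length
and topology are independent by construction); within-subject
longitudinal correlation (the three timepoints of a subject share
only the backbone, not scan-level noise); and any of the upstream
imaging chain (registration error, tensor-fit bias, tract-splitting
artefacts enter real counts in structured ways the negative binomial
does not capture).

## Numerical and reproducibility choices

* Node indices are 1-based everywhere inside the package — the native
  R convention, and also Pajek's, so the export needs no conversion.
* Disconnected distances are `Inf` and contribute 0 to all $1/d$
  sums; path counts for disconnected pairs are 0.
* Input count matrices must be exactly symmetric; asymmetry is an
  error, never silently repaired, because it indicates an upstream
  bug rather than a format dialect.
* Whether the cost threshold is applied per group or shared is left to
  the caller: `compute_snr()` takes a group argument, and the same
  SNR matrix can be thresholded at any cost, so either protocol is a
  two-line change. The pipeline applies it per group.
* All stochastic stages take explicit seeds. `run_pipeline()` derives
  per-stage seeds from the master seed by seeding the RNG once and
  drawing one integer per stage in fixed order, so stages are
  individually reproducible and never share a stream; the seeds are
  recorded in the output manifest, and identical configs produce
  byte-identical JSON reports.
* Problem sizes in the bundled report: the full default cohort (78
  regions, 3 × 39 scans), 4-point cost grid, 20 rewired realisations
  per cost, 200 permutations per pairwise test. These are the
  package's reporting defaults; the underlying functions default to
  100 realisations and 1000 permutations.

## Worked example

```{r example, eval = FALSE}
library(fibernet)

cohort <- sample_cohort(cohort_config(seed = 1))
snr <- compute_snr(cohort, group = "1yr")

backbone <- threshold_to_cost(snr, 0.21)
efficiency_report(backbone)

sw <- smallworld_sweep(snr, c(0.10, 0.15, 0.21, 0.30),
                       n_null = 20, seed = 2)
autoplot(sw)

part <- detect_communities(backbone)
roles <- node_roles(backbone, part)
plot_node_roles(roles)

fit <- fit_degree_distribution(backbone)
glance(fit)

compare_groups(cohort, "age_group", "mean_length",
               cost = 0.21, n_perm = 200, seed = 3)
```

## Known limitations

The implementation targets atlas-scale graphs (tens to a few hundred
nodes); the all-pairs algorithms are quadratic-to-cubic in N and are
not meant for voxel-level networks. Community detection is the greedy
modularity optimiser only — adequate at this scale and faithful to
the method the analysis is built around, but subject to modularity's
resolution limit; no consensus clustering is attempted. Degree fits
are R²-based least squares on the CCDF by design, not
maximum-likelihood tail inference, and should be read as descriptive
curve summaries rather than hypothesis tests for power-law behaviour.
The permutation machinery assumes exchangeability of subjects across
groups under the null, which longitudinal designs violate if the same
subjects appear in both groups being compared — compare timepoints of
a longitudinal cohort with that caveat in mind.
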