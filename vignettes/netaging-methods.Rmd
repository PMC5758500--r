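---
title: "Methods: graph-theoretic analysis of resting-state networks across age groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-theoretic analysis of resting-state networks across age groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netaging)
```

## The analysis problem

Healthy aging reorganises the brain's large-scale functional networks:
resting-state studies repeatedly find lower modularity and local efficiency
in older adults, broadly preserved global efficiency, and less stable
community structure — a topological expression of functional
*dedifferentiation*. `netaging` implements a complete, testable pipeline for
this style of analysis in a two-group (younger/older), two-session study
design with a subsequent multi-day working-memory training phase:

1. **Connectivity.** Pearson correlations between ROI time courses,
   Fisher-z transformed, diagonal zeroed (`correlation_matrix()`).
2. **Thresholding.** Proportional connection-density binarization over a
   grid of densities, and edge-wise FDR-thresholded signed weighted graphs
   (`threshold_density()`, `threshold_fdr()`).
3. **Community structure.** Louvain modularity optimisation with iterative
   fine-tuning, consensus clustering through agreement matrices at the
   subject and group level, and a resolution/threshold parameter sweep
   (`louvain_partition()`, `fine_tune()`, `consensus_partition()`,
   `sweep_parameters()`).
4. **Graph metrics.** Modularity, global and local efficiency,
   participation coefficients, and within/between-module weighted
   connectivity restricted to consistently assigned nodes
   (`modularity_score()`, `global_efficiency()`, `local_efficiency()`,
   `participation()`, `consistent_nodes()`, `module_connectivity()`).
5. **Statistics.** Partition-similarity permutation tests on normalized
   mutual information; ICC(A,2) test-retest reliability; permutation group
   comparisons with max-statistic family-wise error correction; Spearman
   and motion-partialled Spearman associations between baseline metrics and
   early learning rates from a per-subject linear spline.
6. **Synthetic cohorts.** A generator with planted modular covariance,
   group effects, session reliability, motion, and learning curves coupled
   to network structure, so that every downstream stage has a ground truth
   to be tested against (`sim_config()`, `sample_cohort()`).

`run_pipeline()` orchestrates all stages with a single master seed.

## Models and estimators

### Modularity

For a binary graph with adjacency $A$, $E$ edges and degrees $k_i$,

$$Q = \frac{1}{2E}\sum_{ij}\left[A_{ij} - \gamma\,\frac{k_i k_j}{2E}\right]\,
\delta(m_i, m_j),$$

summing over ordered pairs including $i=j$ ($A_{ii}=0$, but the null-model
term is counted — the standard Newman convention; the brute-force oracle in
the test suite uses the same convention). The resolution parameter $\gamma$
scales the configuration-model null; $\gamma = 1.25$ (the consensus-sweep
optimum in this literature) is the default everywhere. A subject's
*modularity score* is the mean of $Q$ over repeated Louvain + fine-tuning
optimisations (500 repetitions at analysis fidelity), which averages over
the algorithm's well-known degeneracy.

### Efficiency and participation

Global efficiency is the mean inverse shortest-path length over ordered
node pairs (disconnected pairs contribute 0). Local efficiency of node $i$
is the same quantity computed inside the sub-graph induced by $i$'s
neighbours; nodes with fewer than two neighbours get 0, since the defining
normaliser $N_{G_i}(N_{G_i}-1)$ is degenerate — this matches common
brain-connectivity toolbox behaviour. The participation coefficient is
$P(i) = 1 - \sum_m (k_i(m)/k_i)^2$ with $P = 0$ for isolated nodes.

### Louvain with fine-tuning and consensus

The Louvain optimiser (compiled code, weighted configuration-model null) is
authored in this package; `igraph`'s implementation serves only as an
independent cross-check in the tests. Node visit order is shuffled with R's
RNG, so every run is reproducible from a seed. *Fine-tuning* re-sweeps
single-node moves from a given labeling, accepting only positive modularity
gains, and re-runs Louvain initialised from the result; the output never
has lower modularity than the input (asserted property).

Consensus clustering repeatedly (a) builds the agreement matrix — the
fraction of ensemble partitions co-assigning each node pair, (b) zeroes
entries below $\tau$ (surviving entries keep their fractional values;
re-binarizing would discard information the next iteration can use), and
(c) re-partitions the thresholded agreement matrix with $R$ Louvain +
fine-tuning runs, until all $R$ runs of an iteration agree (checked by
exact partition identity — equivalent at convergence to the agreement
matrix being binary, and cheaper). Defaults: $\gamma = 1.25$, $\tau = 0.5$,
$R = 500$, at most 50 iterations, after which a different $\tau$ is
recommended in the error.

The $(\gamma, \tau)$ sweep covers $\gamma \in [1, 1.5]$ and
$\tau \in [0.2, 0.5]$ in steps of 0.05 (77 grid points). The sweep's input
is one mean positive-weight matrix per group-session cell; each cell's
consensus partition is derived by consensus clustering of repeated Louvain
runs on that matrix, and its weighted modularity is evaluated on the same
matrix. This is a design choice: the alternative — re-running every
subject's consensus partition at every grid point — multiplies the cost by
the cohort size while optimising the same objective; the grid table records
per-cell modularity and convergence so either reading can be audited.

### Consistent nodes and module metrics

Module labels of the four group-session consensus partitions are matched to
the first partition by maximum-overlap one-to-one assignment on the module
confusion matrix (exhaustive over label injections for the module counts
seen in practice, with a greedy fallback for degenerate many-module cases).
A node is *consistent* when its matched label agrees across all four
partitions; per-module summaries (participation, local efficiency,
within/between-module FDR-weighted connectivity) use consistent nodes only,
while inconsistent nodes keep their reference-partition label for neighbour
counting in the participation formula.

### Statistical machinery

*Partition similarity.* NMI uses the arithmetic-mean normalisation
$2I(X;Y)/(H(X)+H(Y))$ with natural logarithms — the most common variant;
the oracle tests pin this choice. Conventions: two single-module partitions
have NMI 1; exactly one single-module partition gives 0. The between-group
test compares the mean cross-group pairwise NMI (per density threshold,
then averaged) against a null that permutes group membership, declaring
significance when the observed value falls below the null's 5th percentile,
with the $+1$-corrected one-sided permutation p-value reported alongside.
Within-group similarity uses the same null two-sidedly (a group can be more
homogeneous *or* more heterogeneous than chance); within-subject stability
compares the two sessions' partitions per subject and tests the group
difference of mean NMI. Because the observed pairwise NMI matrix does not
change under permutation, it is computed once and re-indexed, making 5,000
permutations cheap.

*Reliability.* ICC(A,2) from the two-way ANOVA decomposition without
replication: $\mathrm{ICC} = (MS_R - MS_E)/[MS_R + (MS_C - MS_E)/n]$.
Negative values are reported as computed (transparency over cosmetics) and
banded "poor"; a zero-variance table is perfect agreement by convention
(ICC 1 with a warning). Interpretation bands: poor $<0.20$, fair to 0.40,
moderate to 0.60, strong to 0.80, almost perfect above; values in the
printed gaps resolve to the nearer band edge (cut points at 0.205, 0.405,
0.605, 0.805).

*Group comparisons.* Two-sided permutation tests on group mean differences
with the $+1$ finite-sample correction. Module-family comparisons use the
max-statistic method: one shared permutation stream records the maximum
absolute statistic across modules, and each module's corrected p-value is
computed against those maxima — strong FWE control under exchangeability.

*Learning.* Each subject's training curve (mean set size over 10 sessions)
is fit by ordinary least squares with a linear spline knotted at session 2;
the coefficient on session is the early (session 1→2) learning rate and
the summed slope coefficients the late rate. Per-subject OLS reproduces the
defining rates exactly for noiseless piecewise-linear data. Spearman
correlations (Pearson on mid-ranks, t-approximation p-values) relate
baseline brain-wide metrics to early slopes per group and session, with
per-threshold curves and motion-partialled coefficients (rank-residual
method); significant brain-wide results can be followed up per module with
max-statistic correction over the module family.

### FDR thresholding

Fisher-z values convert to two-sided p-values through the normal
approximation $z\sqrt{T-3} \sim N(0,1)$, where $T$ is the number of time
points behind the correlations — the conversion the package documents as
its choice, since connectivity-value FDR thresholding is usually described
without the p-value machinery. Benjamini–Hochberg step-up at $q = 0.05$ is
applied separately to the positive and negative edge families; survivors
keep their signed weights.

## The synthetic cohort generator

The generator's defaults encode the emulated study design: two groups of 20
subjects, 234 ROIs in 5 modules, 235 time points per session, two sessions,
10 training days. Each subject-session time series is drawn i.i.d. over
time from a zero-mean multivariate normal with unit-diagonal block
covariance: within-module correlation 0.30 (young) or 0.22 (older),
between-module 0.05/0.08 — magnitudes in line with published resting-state
system-level correlations and their age differences, with the older group
planted lower-within/higher-between, the dedifferentiation signature.
Subject- and session-level jitter (SD 0.03) on the within-module coupling
mixes according to `session_reliability` (default 0.7): at 1 both sessions
share the subject's generative covariance exactly. Motion is a truncated
normal per subject (means 0.15/0.18, SD 0.05, arbitrary composite-motion
units). Learning curves rise by a subject-specific early increment from
session 1 to 2 — `learning_coupling` (default 0.5 set-size units per SD)
times the subject's standardized planted coupling, plus a group baseline —
then by 0.4/session to a plateau at session 7, with additive Gaussian noise
(SD 0.25). The planted truth table is returned (and written) so
parameter-recovery tests can join estimates to generative values.

Deliberate simplifications: no temporal autocorrelation (band-pass
filtering and spectra are out of scope; only the correlation structure
drives downstream computation), no fMRI artifacts, no voxel level, and —
important for interpreting tests — no hub or spatially heterogeneous
structure: every within-module pair is exchangeable.

## What passing tests do and do not show

The test suite verifies the estimators against independent brute-force
oracles (exact to $10^{-10}$ on graphs small enough to enumerate), the
optimiser against exhaustive Bell-number search on ≤8-node graphs, type-I
calibration of all permutation engines (500 replicate nulls), ICC
behaviour against hand-computed ANOVA and the generator's reliability knob,
and qualitative recovery of the planted group and learning effects. Because
the generated cohorts are clean block models, passing these tests shows the
*machinery* is correct and calibrated — not that real fMRI data would yield
any particular result.

One planted-pattern check fails by design of the generator, and we report
it rather than hide it: with density-equated graphs, the older group's
higher between-module coupling admits systematically more between-module
edges, which bridge the otherwise component-split modules and *raise* its
global efficiency in every replicate cohort. Empirically, global efficiency
is broadly age-preserved; real cortex maintains integration through
connector hubs in both groups, a feature a homogeneous block covariance
cannot express. The corresponding acceptance expectation (no systematic
global-efficiency sign) therefore stays red, and per-group global
efficiency should not be interpreted as emulating empirical aging effects.

## Numerical choices and problem sizes

- Density grid 2–10% in 1% steps; edge count $K = \mathrm{round}(d \cdot
  N(N-1)/2)$ with round-half-up; ranking by raw signed value; cutoff ties
  broken by ascending (row, column) for determinism; isolated nodes are
  kept with degree 0, never dropped.
- Fisher-z clipping at $\pm(1 - 10^{-7})$ keeps duplicate time courses
  finite.
- Louvain move acceptance uses a $10^{-12}$ gain tolerance; equal-gain
  candidates prefer the smaller community id; a node moves to an empty
  community when every occupied candidate has negative gain.
- Ties in best-of-$R$ selection resolve to the lexicographically smallest
  canonical label sequence.
- All randomness flows from one master seed through deterministically
  derived child seeds, one per stochastic stage; reruns are byte-identical.
- Test and acceptance simulations run at reduced scale chosen for
  single-CPU practicality — cohorts of 40–100 nodes (5 modules), 8–15
  subjects per group, 120–235 time points, 3–20 Louvain repetitions per
  score, 200–500 permutations — while the `"paper"` profile keeps the
  analysis-fidelity settings (500 repetitions, 5,000 permutations).

## Known limitations

- The generator plants coupling-strength differences, not module
  *composition* differences, so between-group NMI tests on default
  synthetic cohorts are expectedly non-significant; composition effects can
  be emulated by supplying different `module_sizes` per group manually.
- The spline model is per-subject OLS; no shared random-effects structure
  across subjects is fit.
- Only the ICC(A,k) form is provided (no confidence intervals); only the
  arithmetic-mean NMI normalisation; no overlapping or hierarchical
  community detection.
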