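# netaging

Graph-theoretic analysis of resting-state functional brain networks in
two-group, two-session aging studies — from ROI time series to consensus
community structure, network metrics, reliability, and links with learning.

## The problem

Aging changes the topology of large-scale functional brain networks: older
adults tend to show lower modularity and local efficiency (functional
*dedifferentiation*), broadly preserved global efficiency, and less stable
community structure over time. Testing such effects properly requires a
long chain of machinery — Fisher-z connectivity matrices, density-equated
binary graphs, Louvain consensus partitions, brain-wide and per-module
graph metrics, permutation tests with family-wise error control,
test-retest ICCs, and rank correlations between baseline network properties
and training-derived learning rates. `netaging` implements that chain as a
tested, seeded, reproducible R pipeline, together with a synthetic cohort
generator with planted ground truth so every stage can be validated without
human data.

The core quantities, for a binary graph with adjacency $A$, $E$ edges and
degrees $k_i$:

- Modularity $Q = \frac{1}{2E}\sum_{ij}[A_{ij} - \gamma k_i k_j / 2E]\,\delta(m_i,m_j)$,
  maximised by repeated Louvain optimisation with iterative fine-tuning
  (resolution $\gamma = 1.25$) and stabilised by agreement-matrix consensus
  clustering (threshold $\tau = 0.5$).
- Global efficiency $E_{glob} = \frac{1}{N(N-1)}\sum_{i \ne j} 1/L_{ij}$ and
  local efficiency (the same quantity inside each node's neighbour
  sub-graph).
- Participation coefficient $P(i) = 1 - \sum_m (k_i(m)/k_i)^2$.
- Partition similarity by normalized mutual information,
  $2I(X;Y)/(H(X)+H(Y))$, tested by group-membership permutation.
- Test-retest reliability by ICC(A,2):
  $(MS_R - MS_E)/[MS_R + (MS_C - MS_E)/n]$.
- Early/late learning rates from a per-subject linear spline with a knot at
  training session 2, related to baseline metrics by (partial) Spearman
  correlation.

## Worked example

```r
library(netaging)

cfg <- sim_config(n_nodes = 60, module_sizes = rep(12, 5),
                  n_subjects_per_group = 8, n_timepoints = 150, seed = 42)
cohort <- sample_cohort(cfg)
res <- run_pipeline(cohort, pipeline_config("reduced", seed = 42))
print(res)
#> Pipeline run (profile reduced, seed 42, config 277c0398)
#> Subjects: 16 (older 8, young 8)
#> Consistent nodes: 60 across 5 modules
#> Group mean Q (t1): older 0.646, young 0.698
#> Between-group NMI: t1 obs 0.815 (p 0.0945), t2 obs 0.798 (p 0.821)
#> ICC (threshold-averaged, all): Q 0.72, Eglob 0.96, Eloc 0.86
```

The generator planted lower within-module coupling in the "older" group;
the pipeline recovers the expected ordering of threshold-averaged
modularity (0.646 < 0.698). All 60 nodes are consistently assigned to the
same 5 modules across the four group-session consensus partitions. The
between-group NMI test is not significant here because both synthetic
groups share the same planted module *composition* — the test responds to
where nodes live, not to how strongly modules cohere. Threshold-averaged
ICCs reflect the generator's session-reliability setting (0.7 by default).

Individual stages are plain functions if you want only part of the chain:

```r
C <- correlation_matrix(cohort$timeseries[["y01.1"]])  # Fisher-z matrix
g <- threshold_density(C, 0.05)                        # top 5% of edges
best_partition(g$adjacency * 1.0, gamma = 1.25, runs = 100, seed = 1)$Q

icc_a_k(cbind(c(0.62, 0.55, 0.71, 0.48, 0.66),
              c(0.60, 0.57, 0.69, 0.52, 0.64)))
#> ICC(A,2) = 0.973 (almost perfect), n = 5
```

See `vignettes/netaging-methods.Rmd` for the full model description,
parameter defaults, and the generator's assumptions and limitations.

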