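two_cliques <- function() {
  a <- matrix(0, 6, 6)
  a[1:3, 1:3] <- 1
  a[4:6, 4:6] <- 1
  diag(a) <- 0
  dimnames(a) <- list(paste0("n", 1:6), paste0("n", 1:6))
  a
}

test_that("louvain recovers components, merges complete graphs, finds SBM blocks", {
  a <- two_cliques()
  p <- louvain_partition(a, gamma = 1, seed = 1)
  expect_equal(as.integer(p), c(1, 1, 1, 2, 2, 2))

  # K6 at gamma = 1: exhaustive search confirms a single module is optimal
  k6 <- matrix(1, 6, 6) - diag(6)
  pk <- louvain_partition(k6, gamma = 1, seed = 2)
  expect_equal(attr(pk, "module_count"), 1)
  expect_equal(exhaustive_max_q(k6, 1), 0)

  set.seed(5)
  sbm <- planted_sbm(c(6, 6, 6, 6), p_in = 0.95, p_out = 0.02)
  ps <- louvain_partition(sbm$adjacency * 1.0, gamma = 1, seed = 3)
  expect_equal(nmi(ps, sbm$labels), 1)

  expect_error(louvain_partition(matrix(0, 4, 4)), "edges")
})

test_that("louvain is deterministic under a seed and label-permutation invariant", {
  set.seed(8)
  a <- random_binary_graph(16, 0.3)
  expect_identical(louvain_partition(a, 1.25, seed = 4),
                   louvain_partition(a, 1.25, seed = 4))
  # permute nodes, partition, map back: same community structure
  perm <- sample(16)
  ap <- a[perm, perm]
  p1 <- best_partition(a, 1, runs = 20, seed = 6)$partition
  p2 <- best_partition(ap, 1, runs = 20, seed = 6)$partition
  back <- integer(16)
  back[perm] <- as.integer(p2)
  expect_equal(nmi(p1, back), 1)
})

test_that("fine_tune is a fixed point at optima, repairs single swaps, never lowers Q", {
  a <- two_cliques()
  opt <- as_partition(setNames(c(1, 1, 1, 2, 2, 2), rownames(a)))
  expect_equal(as.integer(fine_tune(a, opt, gamma = 1, seed = 1)),
               as.integer(opt))
  bad <- as_partition(setNames(c(1, 1, 2, 2, 2, 2), rownames(a)))
  expect_equal(as.integer(fine_tune(a, bad, gamma = 1, seed = 2)),
               c(1, 1, 1, 2, 2, 2))
  # monotonicity over random graphs and random initial partitions
  set.seed(77)
  for (trial in 1:40) {
    g <- random_binary_graph(12, 0.35)
    if (sum(g) == 0) next
    init <- as_partition(setNames(sample(1:4, 12, TRUE), rownames(g)))
    out <- fine_tune(g * 1.0, init, gamma = 1.1)
    expect_gte(weighted_modularity(g * 1.0, out, 1.1),
               weighted_modularity(g * 1.0, init, 1.1) - 1e-12)
  }
})

test_that("best_partition attains the exhaustive optimum and is deterministic", {
  a <- two_cliques()
  bp <- best_partition(a, gamma = 1, runs = 10, seed = 3)
  expect_equal(bp$Q, exhaustive_max_q(a, 1), tolerance = 1e-12)
  expect_equal(bp$Q, 0.5, tolerance = 1e-12)
  bp2 <- best_partition(a, gamma = 1, runs = 10, seed = 3)
  expect_identical(as.integer(bp$partition), as.integer(bp2$partition))
  expect_error(best_partition(a, runs = 0), "runs")
})

test_that("our optimiser is at least as good as igraph's Louvain", {
  set.seed(31)
  for (trial in 1:5) {
    a <- random_binary_graph(25, 0.2)
    if (sum(a) == 0) next
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    ig <- igraph::cluster_louvain(g, resolution = 1)
    q_ig <- modularity(a, igraph::membership(ig), gamma = 1)
    q_ours <- best_partition(a * 1.0, gamma = 1, runs = 20,
                             seed = trial)$Q
    expect_gte(q_ours, q_ig - 1e-9)
  }
})

test_that("agreement matrices count co-assignments exactly", {
  nodes <- paste0("n", 1:8)
  p1 <- as_partition(setNames(c(1, 1, 1, 1, 2, 2, 2, 2), nodes))
  a1 <- agreement(list(p1, p1, p1))
  expect_true(all(a1 %in% c(0, 1)))
  expect_equal(unname(a1[1, 2]), 1)
  expect_equal(unname(a1[1, 5]), 0)
  expect_equal(unname(diag(a1)), rep(1, 8))
  p2 <- as_partition(setNames(c(1, 2, 1, 1, 2, 2, 1, 2), nodes))
  expect_equal(unname(agreement(list(p1, p2))[1, 2]), 0.5)
  # pair-counting oracle on random ensembles
  set.seed(12)
  parts <- lapply(1:10, function(i) {
    as_partition(setNames(sample(1:3, 8, TRUE), nodes))
  })
  am <- agreement(parts)
  for (i in 1:7) {
    for (j in (i + 1):8) {
      cnt <- sum(vapply(parts, function(p) p[[i]] == p[[j]], logical(1)))
      expect_equal(unname(am[i, j]), cnt / 10)
    }
  }
  expect_error(agreement(list(p1, as_partition(setNames(1:4, nodes[1:4])))),
               "node set")
})

test_that("consensus clustering returns unanimity immediately and recovers planted structure", {
  nodes <- paste0("n", 1:24)
  planted <- as_partition(setNames(rep(1:4, each = 6), nodes))
  expect_identical(
    as.integer(consensus_partition(list(planted, planted, planted),
                                   consensus_params(runs = 10, seed = 1))),
    as.integer(planted))
  # 10% corrupted ensembles at the default gamma = 1.25, tau = 0.5
  set.seed(42)
  noisy <- lapply(1:20, function(i) {
    l <- rep(1:4, each = 6)
    flip <- sample(24, 2)
    l[flip] <- sample(1:4, 2, TRUE)
    as_partition(setNames(l, nodes))
  })
  rec <- consensus_partition(noisy, consensus_params(gamma = 1.25, tau = 0.5,
                                                     runs = 30, seed = 2))
  expect_equal(nmi(rec, planted), 1)
  # tau close to 1 on heterogeneous inputs: nothing clears the threshold
  set.seed(9)
  hetero <- lapply(1:6, function(i) {
    as_partition(setNames(sample(1:6, 24, TRUE), nodes))
  })
  expect_error(
    consensus_partition(hetero, consensus_params(tau = 0.99, runs = 5,
                                                 seed = 3)),
    "tau")
})

test_that("subject and group consensus recover noiseless planted modules", {
  sigma <- build_block_covariance(c(5, 5, 5), 0.6, 0.05)
  C <- as_connectivity(atanh(sigma * 0.999), n_timepoints = 100)
  labels <- setNames(rep(1:3, each = 5), rownames(C))
  sp <- subject_consensus(C, consensus_params(runs = 20, seed = 5))
  expect_equal(nmi(sp, labels), 1)
  expect_identical(
    as.integer(subject_consensus(C, consensus_params(runs = 20, seed = 5))),
    as.integer(sp))
  # all-equal positive matrix at gamma = 1 collapses to one module
  eq <- as_connectivity(matrix(0.4, 6, 6))
  pe <- subject_consensus(eq, consensus_params(gamma = 1, runs = 10, seed = 6))
  expect_equal(attr(pe, "module_count"), 1)
  expect_error(group_consensus(list(sp)), "2 subjects")
})

test_that("the gamma/tau sweep evaluates the full grid and is self-consistent", {
  set.seed(17)
  mk_cell <- function(seed) {
    set.seed(seed)
    s <- build_block_covariance(c(6, 6, 6), 0.55, 0.05)
    w <- s + matrix(rnorm(18 * 18, 0, 0.01), 18, 18)
    w <- (w + t(w)) / 2
    diag(w) <- 0
    w[w < 0] <- 0
    dimnames(w) <- list(paste0("n", 1:18), paste0("n", 1:18))
    w
  }
  cells <- list(young.1 = mk_cell(1), older.1 = mk_cell(2))
  sw <- sweep_parameters(cells, gamma_range = c(1, 1.25),
                         tau_range = c(0.4, 0.5),
                         params = consensus_params(runs = 10, seed = 4))
  expect_equal(nrow(sw$grid), 2 * 2 * 2) # gamma x tau x cells
  expect_true(sw$gamma %in% c(1, 1.25) && sw$tau %in% c(0.4, 0.5))
  # reported mean Q equals independently recomputed modularity of the
  # returned partitions
  qs <- vapply(names(cells), function(cl) {
    weighted_modularity(cells[[cl]], sw$partitions[[cl]], sw$gamma)
  }, numeric(1))
  expect_equal(sw$mean_q, mean(qs), tolerance = 1e-12)
  # degenerate single-point grid returns that point
  sw1 <- sweep_parameters(cells, gamma_range = 1.25, tau_range = 0.5,
                          params = consensus_params(runs = 10, seed = 5))
  expect_equal(c(sw1$gamma, sw1$tau), c(1.25, 0.5))
  # default ranges span 11 x 7 = 77 points
  expect_equal(length(seq(1, 1.5, by = 0.05)) * length(seq(0.2, 0.5, by = 0.05)),
               77)
})
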