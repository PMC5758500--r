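test_that("all four graph metrics match brute-force oracles on random graphs", {
  set.seed(101)
  for (trial in 1:15) {
    n <- sample(6:12, 1)
    a <- random_binary_graph(n, runif(1, 0.2, 0.6))
    if (sum(a) == 0) next
    labels <- sample(1:3, n, replace = TRUE)
    gamma <- sample(c(1, 1.25), 1)
    expect_equal(modularity(a, labels, gamma),
                 brute_modularity(a, labels, gamma), tolerance = 1e-10)
    expect_equal(global_efficiency(a), brute_global_efficiency(a),
                 tolerance = 1e-10)
    expect_equal(unname(local_efficiency(a)), brute_local_efficiency(a),
                 tolerance = 1e-10)
    expect_equal(unname(participation(a, labels)),
                 brute_participation(a, labels), tolerance = 1e-10)
  }
})

test_that("modularity honours closed forms and stays below 1", {
  set.seed(33)
  for (trial in 1:10) {
    a <- random_binary_graph(10, 0.4)
    if (sum(a) == 0) next
    expect_equal(modularity(a, rep(1, 10), gamma = 1), 0, tolerance = 1e-12)
    expect_lt(modularity(a, sample(1:3, 10, TRUE), gamma = 1), 1)
  }
  expect_error(modularity(matrix(0, 4, 4), rep(1, 4)), "empty")
})

test_that("modularity_score averages repeated optimisation", {
  a <- matrix(0, 6, 6)
  a[1:3, 1:3] <- 1
  a[4:6, 4:6] <- 1
  diag(a) <- 0
  # every run finds the two-clique optimum, so the average is exactly 0.5
  expect_equal(modularity_score(a, gamma = 1, runs = 10, seed = 1), 0.5,
               tolerance = 1e-12)
  # R = 1 equals a single best-effort run
  set.seed(60)
  g <- random_binary_graph(12, 0.4)
  s1 <- modularity_score(g, gamma = 1.25, runs = 1, seed = 5)
  seeds <- derive_seeds(5, 1)
  p <- fine_tune(g * 1.0, louvain_partition(g * 1.0, 1.25, seed = seeds[1]),
                 1.25)
  expect_equal(s1, modularity(g, p, 1.25), tolerance = 1e-12)
})

test_that("efficiency metrics honour degenerate cases and monotonicity", {
  k5 <- matrix(1, 5, 5) - diag(5)
  expect_equal(global_efficiency(k5), 1)
  expect_equal(unname(local_efficiency(k5)), rep(1, 5))
  empty <- matrix(0, 5, 5)
  expect_equal(global_efficiency(empty), 0)
  # star graph: centre's neighbour sub-graph has no edges; leaves have 1
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(unname(local_efficiency(star)), rep(0, 5))
  # path graph P3
  p3 <- matrix(0, 3, 3)
  p3[1, 2] <- p3[2, 1] <- p3[2, 3] <- p3[3, 2] <- 1
  expect_equal(global_efficiency(p3), 5 / 6)
  # adding edges never lowers global efficiency
  set.seed(44)
  for (trial in 1:30) {
    a <- random_binary_graph(10, 0.3)
    b <- a
    off <- which(upper.tri(b) & b == 0)
    if (!length(off)) next
    add <- sample(off, min(3, length(off)))
    b[add] <- 1
    b[lower.tri(b)] <- t(b)[lower.tri(b)]
    expect_gte(global_efficiency(b), global_efficiency(a) - 1e-12)
  }
})

test_that("participation handles splits, isolated nodes and missing labels", {
  # degree-4 node with 2 edges in each of two modules
  a <- matrix(0, 5, 5)
  a[1, 2:5] <- a[2:5, 1] <- 1
  labels <- c(1, 1, 1, 2, 2)
  expect_equal(unname(participation(a, labels))[1], 0.5)
  # all edges inside its own module
  clique <- matrix(1, 4, 4) - diag(4)
  expect_equal(unname(participation(clique, rep(1, 4))), rep(0, 4))
  # degree-0 node gets 0 even when unlabeled
  iso <- matrix(0, 3, 3)
  iso[1, 2] <- iso[2, 1] <- 1
  expect_equal(unname(participation(iso, c(1, 1, NA))), c(0, 0, 0))
  expect_error(participation(iso, c(1, NA, 2)), "unlabeled")
})

test_that("consistent-node matching resolves permutations and flags flips", {
  nodes <- paste0("n", 1:20)
  base <- setNames(rep(1:4, each = 5), nodes)
  p <- as_partition(base)
  # identical partitions: everything consistent
  ca <- consistent_nodes(list(p, p, p, p))
  expect_equal(sum(!is.na(ca$module)), 20)
  # a single flipped node is the only inconsistency
  flip <- base
  flip["n7"] <- 4
  ca2 <- consistent_nodes(list(p, p, as_partition(flip), p))
  expect_true(is.na(ca2$module[["n7"]]))
  expect_equal(sum(is.na(ca2$module)), 1)
  # label-permuted copies are fully consistent
  perm <- setNames(c(3, 1, 4, 2)[base], nodes)
  ca3 <- consistent_nodes(list(p, as_partition(perm), p, as_partition(perm)))
  expect_equal(sum(!is.na(ca3$module)), 20)
  expect_error(consistent_nodes(list(p, as_partition(base[1:10]))),
               "node set")
})

test_that("module connectivity equals direct pair enumeration", {
  set.seed(55)
  n <- 12
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- rnorm(n * (n - 1) / 2) * (runif(n * (n - 1) / 2) < 0.5)
  w <- w + t(w)
  dimnames(w) <- list(paste0("n", 1:n), paste0("n", 1:n))
  module <- setNames(c(rep(1, 5), rep(2, 4), NA, NA, 3), rownames(w))
  mc <- module_connectivity(w, module)
  # oracle: explicit enumeration
  for (m in c(1, 2)) {
    idx <- which(!is.na(module) & module == m)
    s <- 0
    for (i in idx) for (j in idx) if (i < j) s <- s + w[i, j]
    expect_equal(mc$within$value[mc$within$module == m],
                 s / (length(idx) * (length(idx) - 1) / 2))
  }
  # module with a single consistent node: within undefined
  expect_true(is.na(mc$within$value[mc$within$module == 3]))
  ia <- which(!is.na(module) & module == 1)
  ib <- which(!is.na(module) & module == 2)
  s <- 0
  for (i in ia) for (j in ib) s <- s + w[i, j]
  expect_equal(mc$between$value[mc$between$module_a == 1 &
                                  mc$between$module_b == 2],
               s / (length(ia) * length(ib)))
  # uniform weights: within equals the common weight
  u <- matrix(0.3, 4, 4)
  diag(u) <- 0
  expect_equal(module_connectivity(u, setNames(rep(1, 4),
                                               NULL))$within$value, 0.3)
  # no surviving edges: all zeros
  z <- module_connectivity(matrix(0, 4, 4), rep(1, 4))
  expect_equal(z$within$value, 0)
})

test_that("metric tables have the bookkeeping shape and average correctly", {
  coh <- sample_cohort(tiny_config(seed = 30, n_subjects_per_group = 2))
  conn <- lapply(coh$timeseries, correlation_matrix)
  thr <- c(0.06, 0.10)
  mt <- compute_metric_tables(conn, coh$manifest, thresholds = thr,
                              gamma = 1.25, runs = 3, seed = 1)
  expect_equal(nrow(mt), 4 * 2 * (length(thr) + 1))
  expect_true(all(mt$Eglob >= 0 & mt$Eglob <= 1))
  expect_true(all(mt$Eloc >= 0 & mt$Eloc <= 1))
  for (key in unique(paste(mt$subject_id, mt$session))) {
    sub <- mt[paste(mt$subject_id, mt$session) == key, ]
    expect_equal(sub$Q[sub$density == "mean"],
                 mean(sub$Q[sub$density != "mean"]), tolerance = 1e-12)
  }
  # single-threshold grid: the averaged row equals the single row
  m1 <- compute_metric_tables(conn[1], coh$manifest[1, ], thresholds = 0.1,
                              runs = 2, seed = 2)
  expect_equal(m1$Q[m1$density == "mean"], m1$Q[m1$density != "mean"])
})
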