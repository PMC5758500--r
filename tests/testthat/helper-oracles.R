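# Independent brute-force oracles and fixture builders. Everything here is
# deliberately naive (double loops, full enumeration) and shares no code with
# the implementation under test.

random_binary_graph <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  a <- a + t(a)
  dimnames(a) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  a
}

# Newman modularity by explicit double loop over ordered pairs incl. i == j.
brute_modularity <- function(a, labels, gamma = 1) {
  n <- nrow(a)
  k <- sapply(seq_len(n), function(i) sum(a[i, ]))
  e2 <- sum(k)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (labels[i] == labels[j]) {
        q <- q + a[i, j] - gamma * k[i] * k[j] / e2
      }
    }
  }
  q / e2
}

# All-pairs shortest paths, Floyd-Warshall.
floyd_warshall <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

brute_global_efficiency <- function(a) {
  n <- nrow(a)
  d <- floyd_warshall(a)
  s <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(d[i, j])) s <- s + 1 / d[i, j]
    }
  }
  s / (n * (n - 1))
}

brute_local_efficiency <- function(a) {
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2) next
    sub <- a[nb, nb, drop = FALSE]
    d <- floyd_warshall(sub)
    s <- 0
    for (j in seq_along(nb)) {
      for (h in seq_along(nb)) {
        if (j != h && is.finite(d[j, h])) s <- s + 1 / d[j, h]
      }
    }
    out[i] <- s / (length(nb) * (length(nb) - 1))
  }
  out
}

brute_participation <- function(a, labels) {
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(a[i, ])
    if (k == 0) next
    acc <- 0
    for (m in unique(labels)) {
      km <- sum(a[i, labels == m])
      acc <- acc + (km / k)^2
    }
    out[i] <- 1 - acc
  }
  out
}

# NMI from first principles: explicit entropy sums over the joint counts.
nmi_oracle <- function(x, y) {
  n <- length(x)
  ux <- unique(x)
  uy <- unique(y)
  hx <- 0
  for (u in ux) {
    p <- sum(x == u) / n
    hx <- hx - p * log(p)
  }
  hy <- 0
  for (u in uy) {
    p <- sum(y == u) / n
    hy <- hy - p * log(p)
  }
  if (hx + hy == 0) return(1)
  if (hx == 0 || hy == 0) return(0)
  i_xy <- 0
  for (u in ux) {
    for (v in uy) {
      pj <- sum(x == u & y == v) / n
      if (pj > 0) {
        i_xy <- i_xy + pj * log(pj / ((sum(x == u) / n) * (sum(y == v) / n)))
      }
    }
  }
  2 * i_xy / (hx + hy)
}

# All set partitions of n items via restricted growth strings.
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (lab in seq_len(maxlab + 1)) {
      rec(c(prefix, lab), max(maxlab, lab))
    }
  }
  rec(integer(0), 0L)
  out
}

# Exhaustive maximum modularity over every set partition of a small graph.
exhaustive_max_q <- function(a, gamma = 1) {
  parts <- all_set_partitions(nrow(a))
  max(vapply(parts, function(p) brute_modularity(a, p, gamma), numeric(1)))
}

# Hand ANOVA sums of squares for the ICC oracle.
hand_icc_a_k <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  gm <- mean(x)
  ss_r <- 0
  for (i in seq_len(n)) ss_r <- ss_r + k * (mean(x[i, ]) - gm)^2
  ss_c <- 0
  for (j in seq_len(k)) ss_c <- ss_c + n * (mean(x[, j]) - gm)^2
  ss_e <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      ss_e <- ss_e + (x[i, j] - mean(x[i, ]) - mean(x[, j]) + gm)^2
    }
  }
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  (ms_r - ms_e) / (ms_r + (ms_c - ms_e) / n)
}

# A small planted-partition (SBM-like) binary graph with strong contrast.
planted_sbm <- function(block_sizes, p_in = 0.9, p_out = 0.05) {
  labels <- rep(seq_along(block_sizes), block_sizes)
  n <- length(labels)
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- if (labels[i] == labels[j]) p_in else p_out
      a[i, j] <- a[j, i] <- as.integer(stats::runif(1) < p)
    }
  }
  dimnames(a) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  list(adjacency = a, labels = stats::setNames(labels, rownames(a)))
}

# Tiny synthetic cohort configuration used across tests.
tiny_config <- function(seed = 1, ...) {
  args <- list(n_nodes = 40, module_sizes = c(8, 8, 8, 8, 8),
               n_subjects_per_group = 4, n_timepoints = 120, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}
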