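#' Canonicalize a module labeling
#'
#' Relabels module ids to consecutive integers in order of first occurrence,
#' so that partitions that differ only by a label permutation compare equal.
#'
#' @param labels integer (or factor/character) module labels, optionally named
#'   by node id.
#' @param nodes node ids; defaults to `names(labels)`.
#' @return an integer vector of class `"partition"` with contiguous labels
#'   starting at 1 and a `module_count` attribute.
#' @export
as_partition <- function(labels, nodes = names(labels)) {
  if (inherits(labels, "partition")) {
    labels <- unclass(labels)
  }
  lab <- match(labels, unique(labels))
  if (anyNA(lab)) stop("partition labels must not contain NA", call. = FALSE)
  names(lab) <- nodes
  attr(lab, "module_count") <- max(lab)
  class(lab) <- "partition"
  lab
}

#' @export
print.partition <- function(x, ...) {
  cat("Partition of", length(x), "nodes into",
      attr(x, "module_count"), "modules\n")
  invisible(x)
}

partition_equal <- function(a, b) {
  identical(as.integer(as_partition(a)), as.integer(as_partition(b)))
}

# Extract a validated non-negative weight matrix from the accepted inputs.
weights_matrix <- function(w) {
  if (inherits(w, "connectivity_matrix")) w <- positive_weights(w)
  if (inherits(w, "binary_graph")) w <- w$adjacency
  check_square_symmetric(w, "weight matrix")
  if (any(w < 0)) stop("Louvain weights must be non-negative", call. = FALSE)
  m <- w
  diag(m) <- 0
  if (all(m == 0)) stop("graph has no positive-weight edges", call. = FALSE)
  m
}

matrix_edges <- function(w) {
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  list(i = idx[, 1] - 1L, j = idx[, 2] - 1L, w = w[idx])
}

#' Louvain community detection
#'
#' Two-phase Louvain modularity optimisation on a non-negative symmetric
#' weight matrix, with a weighted configuration-model null scaled by the
#' resolution parameter `gamma`. Node visit order is randomised; supplying
#' `seed` makes the run reproducible.
#'
#' @param weights symmetric non-negative matrix (diagonal ignored), a
#'   [connectivity_matrix] (its positive part is used) or a binary graph.
#' @param gamma resolution parameter (> 0); larger values favour smaller
#'   modules. Default 1.25.
#' @param seed integer seed, or NULL to continue the current RNG stream.
#' @return a [as_partition()] labeling.
#' @export
louvain_partition <- function(weights, gamma = 1.25, seed = NULL) {
  w <- weights_matrix(weights)
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ed <- matrix_edges(w)
  lab <- louvain_cpp(nrow(w), ed$i, ed$j, ed$w, gamma, NULL)
  as_partition(lab, nodes = rownames(w))
}

#' Iterative community fine-tuning
#'
#' Repeatedly sweeps single-node reassignments that increase modularity and
#' re-runs Louvain initialised from the improved labeling, until a full sweep
#' yields no gain. The returned partition never has lower modularity than the
#' input.
#'
#' @inheritParams louvain_partition
#' @param partition initial labeling of the same nodes.
#' @export
fine_tune <- function(weights, partition, gamma = 1.25, seed = NULL) {
  w <- weights_matrix(weights)
  p <- as_partition(partition)
  if (length(p) != nrow(w)) {
    stop("partition length does not match the graph", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  ed <- matrix_edges(w)
  lab <- louvain_cpp(nrow(w), ed$i, ed$j, ed$w, gamma, as.integer(p) - 1L)
  out <- as_partition(lab, nodes = rownames(w))
  if (weighted_modularity(w, out, gamma) <
      weighted_modularity(w, p, gamma) - 1e-9) {
    # the sweep accepts only positive gains, so this cannot trigger; kept as
    # a hard guarantee of the monotonicity contract
    out <- p
  }
  out
}

#' Weighted modularity of a labeling
#'
#' Newman modularity with the weighted configuration-model null:
#' Q = (1/2m) * sum_ij (W_ij - gamma * s_i s_j / 2m) delta(m_i, m_j),
#' summing over ordered pairs including i = j (W_ii = 0).
#'
#' @inheritParams louvain_partition
#' @param partition module labeling.
#' @export
weighted_modularity <- function(weights, partition, gamma = 1.25) {
  w <- weights_matrix(weights)
  p <- as_partition(partition)
  s <- rowSums(w)
  m2 <- sum(s)
  co <- outer(as.integer(p), as.integer(p), "==")
  sum((w - gamma * outer(s, s) / m2) * co) / m2
}

#' Best-of-R Louvain partition
#'
#' Runs `louvain_partition()` followed by [fine_tune()] `runs` times with
#' distinct derived seeds and returns the partition with maximal weighted
#' modularity (ties broken by the lexicographically smallest canonical label
#' sequence).
#'
#' @inheritParams louvain_partition
#' @param runs number of repetitions (>= 1).
#' @return list with elements `partition` and `Q`.
#' @export
best_partition <- function(weights, gamma = 1.25, runs = 500, seed = NULL) {
  if (runs < 1) stop("runs must be >= 1", call. = FALSE)
  w <- weights_matrix(weights)
  parts <- louvain_ensemble(w, gamma, runs, seed)
  qs <- vapply(parts, function(p) weighted_modularity(w, p, gamma), numeric(1))
  best <- which(qs > max(qs) - 1e-12)
  if (length(best) > 1) {
    keys <- vapply(parts[best],
                   function(p) paste(as.integer(p), collapse = ","),
                   character(1))
    best <- best[order(keys)[1]]
  } else {
    best <- best[1]
  }
  list(partition = parts[[best]], Q = qs[best])
}

# R independent louvain+fine_tune runs with derived seeds.
louvain_ensemble <- function(w, gamma, runs, seed) {
  seeds <- derive_seeds(seed, runs)
  lapply(seeds, function(s) {
    p0 <- louvain_partition(w, gamma, seed = s)
    fine_tune(w, p0, gamma)
  })
}

#' Agreement (co-assignment) matrix of a partition ensemble
#'
#' Entry (i, j) is the fraction of partitions assigning nodes i and j to the
#' same module.
#'
#' @param partitions list of partitions over the same node set.
#' @export
agreement <- function(partitions) {
  if (length(partitions) < 1) stop("need at least one partition", call. = FALSE)
  parts <- lapply(partitions, as_partition)
  n <- length(parts[[1]])
  nodes <- names(parts[[1]])
  for (p in parts) {
    if (length(p) != n || !identical(names(p), nodes)) {
      stop("all partitions must share one node set", call. = FALSE)
    }
  }
  acc <- matrix(0, n, n)
  for (p in parts) {
    acc <- acc + outer(as.integer(p), as.integer(p), "==")
  }
  a <- acc / length(parts)
  dimnames(a) <- list(nodes, nodes)
  a
}

#' Consensus clustering parameters
#'
#' @param gamma Louvain resolution (default 1.25).
#' @param tau agreement threshold in (0, 1) (default 0.5).
#' @param runs Louvain repetitions per consensus stage (default 500).
#' @param max_iter maximum consensus iterations (default 50).
#' @param seed master seed for all stochastic stages.
#' @export
consensus_params <- function(gamma = 1.25, tau = 0.5, runs = 500,
                             max_iter = 50, seed = NULL) {
  stopifnot(gamma > 0, tau > 0, tau < 1, runs >= 1, max_iter >= 1)
  structure(list(gamma = gamma, tau = tau, runs = runs,
                 max_iter = max_iter, seed = seed),
            class = "consensus_params")
}

#' Consensus partition of an ensemble
#'
#' Iteratively builds the agreement matrix of the current ensemble, zeroes
#' entries below `tau`, and re-partitions the thresholded agreement matrix
#' with `runs` Louvain + fine-tuning repetitions, until all repetitions of an
#' iteration agree.
#'
#' @param partitions list of partitions over one node set.
#' @param params a [consensus_params()] object.
#' @export
consensus_partition <- function(partitions, params = consensus_params()) {
  parts <- lapply(partitions, as_partition)
  seeds <- derive_seeds(params$seed, params$max_iter)
  for (it in seq_len(params$max_iter)) {
    a <- agreement(parts)
    off <- a[upper.tri(a)]
    if (length(off) && max(off) < params$tau) {
      stop("no pair of nodes reaches the agreement threshold tau = ",
           params$tau, "; try a lower tau", call. = FALSE)
    }
    a[a < params$tau] <- 0
    diag(a) <- 0
    parts <- louvain_ensemble(a, params$gamma, params$runs, seeds[it])
    first <- parts[[1]]
    if (all(vapply(parts[-1], partition_equal, logical(1), b = first))) {
      return(first)
    }
  }
  stop("consensus clustering did not converge in ", params$max_iter,
       " iterations; try a different tau", call. = FALSE)
}

#' Subject-level consensus partition
#'
#' Generates `runs` Louvain + fine-tuning partitions of the positive weights
#' of a connectivity matrix, then reduces them to a single representative
#' partition by [consensus_partition()].
#'
#' @param C a [connectivity_matrix] or non-negative weight matrix.
#' @inheritParams consensus_partition
#' @export
subject_consensus <- function(C, params = consensus_params()) {
  w <- weights_matrix(C)
  seeds <- derive_seeds(params$seed, 2)
  parts <- louvain_ensemble(w, params$gamma, params$runs, seeds[1])
  first <- parts[[1]]
  if (all(vapply(parts[-1], partition_equal, logical(1), b = first))) {
    return(first)
  }
  inner <- params
  inner$seed <- seeds[2]
  consensus_partition(parts, inner)
}

#' Group-level consensus partition
#'
#' Consensus clustering applied to the subject-level consensus partitions of
#' all participants in one group.
#'
#' @param subject_partitions list (>= 2) of subject partitions.
#' @inheritParams consensus_partition
#' @export
group_consensus <- function(subject_partitions, params = consensus_params()) {
  if (length(subject_partitions) < 2) {
    stop("group consensus needs at least 2 subjects", call. = FALSE)
  }
  consensus_partition(subject_partitions, params)
}

#' Sweep the (gamma, tau) consensus parameter grid
#'
#' For every grid point, derives a consensus partition for each group-session
#' cell from that cell's mean positive-weight matrix and evaluates its
#' weighted modularity on the same matrix. Returns the grid and the point
#' maximising the mean modularity across cells (ties: smallest gamma, then
#' smallest tau). Cells that fail to converge mark the grid point as failed
#' and exclude it from the argmax.
#'
#' @param cell_matrices named list of group-session mean positive-weight
#'   matrices (e.g. young.1, young.2, older.1, older.2).
#' @param gamma_range,tau_range grids (defaults 1-1.5 and 0.2-0.5, step 0.05).
#' @param params baseline [consensus_params()]; its gamma/tau are overridden
#'   at each grid point.
#' @return list with `gamma`, `tau`, `mean_q`, `partitions` (at the optimum)
#'   and the full `grid` table.
#' @export
sweep_parameters <- function(cell_matrices,
                             gamma_range = seq(1, 1.5, by = 0.05),
                             tau_range = seq(0.2, 0.5, by = 0.05),
                             params = consensus_params()) {
  if (length(cell_matrices) < 1) stop("need at least one cell", call. = FALSE)
  cells <- names(cell_matrices) %||% as.character(seq_along(cell_matrices))
  grid <- expand.grid(gamma = gamma_range, tau = tau_range,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$gamma, grid$tau), , drop = FALSE]
  seeds <- derive_seeds(params$seed, nrow(grid) * length(cells))
  rows <- list()
  point_mean <- rep(NA_real_, nrow(grid))
  point_parts <- vector("list", nrow(grid))
  k <- 0
  for (gidx in seq_len(nrow(grid))) {
    qs <- rep(NA_real_, length(cells))
    ok <- TRUE
    parts <- list()
    for (cidx in seq_along(cells)) {
      k <- k + 1
      pp <- consensus_params(gamma = grid$gamma[gidx], tau = grid$tau[gidx],
                             runs = params$runs, max_iter = params$max_iter,
                             seed = seeds[k])
      res <- tryCatch(subject_consensus(cell_matrices[[cidx]], pp),
                      error = function(e) e)
      if (inherits(res, "error")) {
        ok <- FALSE
      } else {
        parts[[cells[cidx]]] <- res
        qs[cidx] <- weighted_modularity(weights_matrix(cell_matrices[[cidx]]),
                                        res, grid$gamma[gidx])
      }
      rows[[k]] <- data.frame(gamma = grid$gamma[gidx], tau = grid$tau[gidx],
                              cell = cells[cidx], Q = qs[cidx],
                              converged = !inherits(res, "error"))
    }
    if (ok) {
      point_mean[gidx] <- mean(qs)
      point_parts[[gidx]] <- parts
    }
  }
  if (all(is.na(point_mean))) {
    stop("no grid point converged for all cells", call. = FALSE)
  }
  best <- which(point_mean == max(point_mean, na.rm = TRUE))[1]
  list(gamma = grid$gamma[best], tau = grid$tau[best],
       mean_q = point_mean[best], partitions = point_parts[[best]],
       grid = tibble::as_tibble(do.call(rbind, rows)))
}
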