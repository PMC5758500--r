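adjacency_of <- function(G) {
  if (inherits(G, "binary_graph")) G$adjacency
  else check_square_symmetric(as.matrix(G), "adjacency")
}

#' Modularity of a partition on a binary graph
#'
#' Newman modularity with resolution gamma:
#' Q = (1/2E) * sum_ij (A_ij - gamma * k_i k_j / 2E) * delta(m_i, m_j),
#' summed over ordered pairs including i = j (A_ii = 0, but the null-model
#' term e_ii is counted, the standard convention).
#'
#' @param G a `binary_graph` (or 0/1 adjacency matrix).
#' @param partition module labeling of the nodes.
#' @param gamma resolution parameter; 1 gives classic Newman-Girvan Q.
#' @export
modularity <- function(G, partition, gamma = 1) {
  a <- adjacency_of(G)
  p <- as_partition(partition)
  k <- rowSums(a)
  e2 <- sum(k)
  if (e2 == 0) stop("empty graph has no modularity", call. = FALSE)
  co <- outer(as.integer(p), as.integer(p), "==")
  sum((a - gamma * outer(k, k) / e2) * co) / e2
}

#' Modularity score: mean Q over repeated Louvain optimisation
#'
#' The per-subject modularity score is the average of Q over `runs`
#' independent Louvain + fine-tuning optimisations at resolution `gamma`
#' (default 1.25, the value used for consensus clustering).
#'
#' @inheritParams modularity
#' @param runs number of repetitions (study value 500).
#' @param seed RNG seed.
#' @export
modularity_score <- function(G, gamma = 1.25, runs = 500, seed = NULL) {
  a <- adjacency_of(G)
  if (sum(a) == 0) stop("empty graph has no modularity", call. = FALSE)
  parts <- louvain_ensemble(a * 1.0, gamma, runs, seed)
  mean(vapply(parts, function(p) modularity(a, p, gamma), numeric(1)))
}

# All-pairs shortest-path (hop) distances of a small binary adjacency matrix
# by frontier expansion; Inf where disconnected.
bfs_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  reach <- a > 0
  step <- 1
  repeat {
    new <- reach & is.infinite(d)
    if (!any(new)) break
    d[new] <- step
    reach <- (reach %*% a) > 0
    step <- step + 1
    if (step > n) break
  }
  d
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs,
#' E_glob = 1/(N(N-1)) * sum_{i != j} 1/L_ij, with disconnected pairs
#' contributing 0.
#'
#' @inheritParams modularity
#' @export
global_efficiency <- function(G) {
  a <- adjacency_of(G)
  n <- nrow(a)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  d <- igraph::distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency (per node)
#'
#' For each node, the efficiency of the sub-graph induced by its immediate
#' neighbours (the node itself excluded):
#' E_loc(i) = 1/(N_Gi (N_Gi - 1)) * sum_{j != h in G_i} 1/L_jh, where path
#' lengths are computed inside the neighbour sub-graph. Nodes with fewer than
#' 2 neighbours get 0.
#'
#' @inheritParams modularity
#' @return named numeric vector of per-node local efficiencies; average it
#'   for the graph- or module-level summary.
#' @export
local_efficiency <- function(G) {
  a <- adjacency_of(G)
  n <- nrow(a)
  out <- setNames(numeric(n), rownames(a))
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    d <- bfs_distances(a[nb, nb, drop = FALSE])
    inv <- 1 / d
    diag(inv) <- 0
    inv[is.infinite(d)] <- 0
    out[i] <- sum(inv) / (k * (k - 1))
  }
  out
}

#' Participation coefficient (per node)
#'
#' P(i) = 1 - sum_m (k_i(m) / k_i)^2, where k_i(m) counts node i's edges into
#' module m. Degree-0 nodes get 0. Every node with edges must carry a module
#' label.
#'
#' @inheritParams modularity
#' @param assignment a partition, or a named module vector possibly containing
#'   NA for nodes without a module; NA-labeled nodes with edges are an error.
#' @export
participation <- function(G, assignment) {
  a <- adjacency_of(G)
  lab <- if (inherits(assignment, "partition")) {
    as.integer(assignment)
  } else {
    as.integer(factor(assignment))
  }
  if (length(lab) != nrow(a)) {
    stop("assignment length must match the graph", call. = FALSE)
  }
  k <- rowSums(a)
  if (any(is.na(lab) & k > 0)) {
    bad <- rownames(a)[is.na(lab) & k > 0]
    stop("unlabeled node(s) with edges: ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  lab_f <- lab
  lab_f[is.na(lab_f)] <- 0L
  mods <- sort(unique(lab_f[lab_f > 0]))
  ind <- outer(lab_f, mods, "==") * 1.0
  km <- a %*% ind
  p <- 1 - rowSums((km / pmax(k, 1))^2)
  p[k == 0] <- 0
  setNames(as.numeric(p), rownames(a))
}

# Optimal one-to-one matching of the columns of a confusion matrix to its
# rows, maximising total overlap. Exhaustive over injections of the smaller
# side when feasible, greedy otherwise.
match_modules <- function(conf) {
  nr <- nrow(conf)
  nc <- ncol(conf)
  s <- min(nr, nc)
  if (choose(max(nr, nc), s) * factorial(s) <= 50000) {
    small_rows <- nr <= nc
    ns <- if (small_rows) nr else nc
    nl <- if (small_rows) nc else nr
    best <- NULL
    best_val <- -Inf
    perm_rec <- function(chosen, remaining) {
      if (length(chosen) == ns) {
        val <- sum(vapply(seq_len(ns), function(i) {
          if (small_rows) conf[i, chosen[i]] else conf[chosen[i], i]
        }, numeric(1)))
        if (val > best_val) {
          best_val <<- val
          best <<- chosen
        }
        return()
      }
      for (c in remaining) {
        perm_rec(c(chosen, c), setdiff(remaining, c))
      }
    }
    perm_rec(integer(0), seq_len(nl))
    pairs <- if (small_rows) {
      cbind(row = seq_len(ns), col = best)
    } else {
      cbind(row = best, col = seq_len(ns))
    }
  } else {
    ord <- order(-as.vector(conf))
    used_r <- logical(nr)
    used_c <- logical(nc)
    pairs <- NULL
    for (o in ord) {
      r <- (o - 1) %% nr + 1
      c <- (o - 1) %/% nr + 1
      if (!used_r[r] && !used_c[c]) {
        used_r[r] <- TRUE
        used_c[c] <- TRUE
        pairs <- rbind(pairs, cbind(row = r, col = c))
        if (nrow(pairs) == s) break
      }
    }
  }
  map <- rep(NA_integer_, nc)
  map[pairs[, "col"]] <- pairs[, "row"]
  map
}

#' Consistently assigned nodes across the four group-level partitions
#'
#' Matches the module labels of each partition to a reference partition (the
#' first) by maximum-overlap one-to-one assignment on the module confusion
#' matrix. A node is consistent iff its matched label agrees across all
#' partitions; others are marked inconsistent (NA).
#'
#' @param partitions list of (typically 4: group x session) partitions over
#'   one node set; the first is the reference.
#' @return list of class `canonical_assignment`: `module` (named integer,
#'   NA = inconsistent), `consistent_count` per module, `reference`.
#' @export
consistent_nodes <- function(partitions) {
  parts <- lapply(partitions, as_partition)
  ref <- parts[[1]]
  nodes <- names(ref)
  for (p in parts) {
    if (length(p) != length(ref) || !identical(names(p), nodes)) {
      stop("partitions must share one node set", call. = FALSE)
    }
  }
  mapped <- matrix(NA_integer_, length(ref), length(parts))
  mapped[, 1] <- as.integer(ref)
  for (j in seq_along(parts)[-1]) {
    p <- parts[[j]]
    conf <- table(factor(as.integer(ref), levels = seq_len(max(ref))),
                  factor(as.integer(p), levels = seq_len(max(p))))
    map <- match_modules(unclass(conf))
    mapped[, j] <- map[as.integer(p)]
  }
  consistent <- apply(mapped, 1, function(r) {
    !anyNA(r) && all(r == r[1])
  })
  module <- ifelse(consistent, mapped[, 1], NA_integer_)
  names(module) <- nodes
  counts <- table(factor(module, levels = seq_len(max(ref))))
  structure(list(module = module,
                 consistent_count = as.integer(counts),
                 reference = ref),
            class = "canonical_assignment")
}

#' @export
print.canonical_assignment <- function(x, ...) {
  cat("Canonical assignment:", sum(!is.na(x$module)), "of",
      length(x$module), "nodes consistent across partitions\n")
  invisible(x)
}

#' Within- and between-module FDR-weighted connectivity
#'
#' For each module (consistent nodes only): the sum of surviving weights
#' among its node pairs divided by the number of possible pairs
#' n_m (n_m - 1) / 2. For each module pair: the sum of weights across,
#' divided by n_m * n_m'. Modules with fewer than 2 consistent nodes get NA
#' within-module values.
#'
#' @param W a `signed_weighted_graph` from [threshold_fdr()].
#' @param assignment a [consistent_nodes()] result (or named module vector).
#' @return list with tibbles `within` (module, n_nodes, value) and `between`
#'   (module_a, module_b, value).
#' @export
module_connectivity <- function(W, assignment) {
  w <- if (inherits(W, "signed_weighted_graph")) W$weights else W
  module <- if (inherits(assignment, "canonical_assignment")) {
    assignment$module
  } else {
    assignment
  }
  if (length(module) != nrow(w)) {
    stop("assignment length must match the graph", call. = FALSE)
  }
  mods <- sort(unique(module[!is.na(module)]))
  within <- lapply(mods, function(m) {
    idx <- which(!is.na(module) & module == m)
    n_m <- length(idx)
    val <- if (n_m < 2) NA_real_ else {
      sub <- w[idx, idx]
      sum(sub[upper.tri(sub)]) / (n_m * (n_m - 1) / 2)
    }
    data.frame(module = m, n_nodes = n_m, value = val)
  })
  pairs <- if (length(mods) >= 2) combn(mods, 2, simplify = FALSE) else list()
  between <- lapply(pairs, function(pr) {
    ia <- which(!is.na(module) & module == pr[1])
    ib <- which(!is.na(module) & module == pr[2])
    data.frame(module_a = pr[1], module_b = pr[2],
               value = sum(w[ia, ib]) / (length(ia) * length(ib)))
  })
  list(within = tibble::as_tibble(do.call(rbind, within)),
       between = if (length(between)) {
         tibble::as_tibble(do.call(rbind, between))
       } else {
         tibble::tibble(module_a = integer(), module_b = integer(),
                        value = numeric())
       })
}

#' Brain-wide metric table across the density grid
#'
#' For every subject x session x density threshold: modularity score (mean Q
#' over `runs` Louvain + fine-tuning repetitions at `gamma`), global
#' efficiency and mean local efficiency, plus threshold-averaged rows
#' (density `"mean"`), the values the study's group comparisons use.
#'
#' @param conn named list ("subject.session") of [correlation_matrix()]
#'   results.
#' @param manifest cohort manifest tibble (subject_id, group, session, ...).
#' @param thresholds density grid; default 0.02-0.10 step 0.01.
#' @param gamma,runs,seed passed to [modularity_score()].
#' @return tibble: subject_id, group, session, density (character), Q,
#'   Eglob, Eloc.
#' @export
compute_metric_tables <- function(conn, manifest,
                                  thresholds = seq(0.02, 0.10, by = 0.01),
                                  gamma = 1.25, runs = 500, seed = NULL) {
  keys <- paste0(manifest$subject_id, ".", manifest$session)
  missing <- setdiff(keys, names(conn))
  if (length(missing)) {
    stop("missing connectivity for: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  seeds <- derive_seeds(seed, length(keys) * length(thresholds))
  rows <- list()
  k <- 0
  for (r in seq_along(keys)) {
    per_thr <- matrix(NA_real_, length(thresholds), 3)
    for (ti in seq_along(thresholds)) {
      k <- k + 1
      g <- threshold_density(conn[[keys[r]]], thresholds[ti])
      per_thr[ti, ] <- c(
        modularity_score(g, gamma = gamma, runs = runs, seed = seeds[k]),
        global_efficiency(g),
        mean(local_efficiency(g)))
    }
    df <- data.frame(subject_id = manifest$subject_id[r],
                     group = manifest$group[r],
                     session = manifest$session[r],
                     density = c(format(thresholds), "mean"),
                     Q = c(per_thr[, 1], mean(per_thr[, 1])),
                     Eglob = c(per_thr[, 2], mean(per_thr[, 2])),
                     Eloc = c(per_thr[, 3], mean(per_thr[, 3])),
                     stringsAsFactors = FALSE)
    rows[[r]] <- df
  }
  tibble::as_tibble(do.call(rbind, rows))
}

#' Per-module metric table
#'
#' Mean participation coefficient and mean local efficiency over the
#' consistent nodes of each module, per subject x session, averaged across
#' the density grid; plus within/between-module FDR-weighted connectivity
#' (positive and negative families) from the unthresholded matrices.
#'
#' @inheritParams compute_metric_tables
#' @param assignment a [consistent_nodes()] result.
#' @param fdr_q FDR level for the weighted connectivity (default 0.05).
#' @return list of tibbles: `modules` (subject, session, module,
#'   participation, Eloc, within_pos, within_neg) and `pairs` (between-module
#'   positive/negative connectivity).
#' @export
compute_module_metrics <- function(conn, manifest, assignment,
                                   thresholds = seq(0.02, 0.10, by = 0.01),
                                   fdr_q = 0.05) {
  keys <- paste0(manifest$subject_id, ".", manifest$session)
  module <- assignment$module
  mods <- sort(unique(module[!is.na(module)]))
  # participation needs every connected node labeled: inconsistent nodes keep
  # their reference-partition label for neighbour counting
  full_label <- as.integer(assignment$reference)
  rows <- list()
  prow <- list()
  for (r in seq_along(keys)) {
    C <- conn[[keys[r]]]
    pmat <- matrix(0, length(mods), length(thresholds))
    emat <- matrix(0, length(mods), length(thresholds))
    for (ti in seq_along(thresholds)) {
      g <- threshold_density(C, thresholds[ti])
      pvec <- participation(g, full_label)
      evec <- local_efficiency(g)
      for (mi in seq_along(mods)) {
        idx <- which(!is.na(module) & module == mods[mi])
        pmat[mi, ti] <- mean(pvec[idx])
        emat[mi, ti] <- mean(evec[idx])
      }
    }
    wpos <- module_connectivity(threshold_fdr(C, q = fdr_q, "positive"),
                                assignment)
    wneg <- module_connectivity(threshold_fdr(C, q = fdr_q, "negative"),
                                assignment)
    rows[[r]] <- data.frame(subject_id = manifest$subject_id[r],
                            group = manifest$group[r],
                            session = manifest$session[r],
                            module = mods,
                            participation = rowMeans(pmat),
                            Eloc = rowMeans(emat),
                            within_pos = wpos$within$value,
                            within_neg = wneg$within$value,
                            stringsAsFactors = FALSE)
    if (nrow(wpos$between)) {
      prow[[r]] <- data.frame(subject_id = manifest$subject_id[r],
                              group = manifest$group[r],
                              session = manifest$session[r],
                              module_a = wpos$between$module_a,
                              module_b = wpos$between$module_b,
                              between_pos = wpos$between$value,
                              between_neg = wneg$between$value,
                              stringsAsFactors = FALSE)
    }
  }
  list(modules = tibble::as_tibble(do.call(rbind, rows)),
       pairs = tibble::as_tibble(do.call(rbind, prow)))
}
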