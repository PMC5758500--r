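#' Normalized mutual information between two partitions
#'
#' NMI = 2 I(X;Y) / (H(X) + H(Y)) from the module contingency table, natural
#' logarithms. Ranges from 0 (independent) to 1 (identical up to relabeling).
#' Both partitions single-module: defined as 1; exactly one single-module: 0.
#'
#' @param p1,p2 partitions over the same node set.
#' @export
nmi <- function(p1, p2) {
  a <- as_partition(p1)
  b <- as_partition(p2)
  if (length(a) != length(b) ||
      (!is.null(names(a)) && !is.null(names(b)) &&
       !identical(names(a), names(b)))) {
    stop("partitions must share one node set", call. = FALSE)
  }
  n <- length(a)
  ct <- table(as.integer(a), as.integer(b)) / n
  pi_ <- rowSums(ct)
  pj_ <- colSums(ct)
  h1 <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  h2 <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  if (h1 + h2 == 0) return(1)
  if (h1 == 0 || h2 == 0) return(0)
  nz <- ct > 0
  i_xy <- sum(ct[nz] * log(ct[nz] / outer(pi_, pj_)[nz]))
  2 * i_xy / (h1 + h2)
}

# Mean-over-thresholds pairwise NMI matrices for a list of subjects, each
# holding one partition per density threshold. Returns a list: `mean` (S x S)
# and `per_threshold` (list of S x S). Computing these once lets every
# permutation reuse them: shuffling group labels only re-indexes the matrix.
pairwise_nmi <- function(partitions) {
  parts <- lapply(partitions, function(p) if (is.list(p)) p else list(p))
  nthr <- length(parts[[1]])
  s <- length(parts)
  per <- lapply(seq_len(nthr), function(t) {
    m <- diag(1, s)
    for (i in seq_len(s - 1)) {
      for (j in (i + 1):s) {
        m[i, j] <- m[j, i] <- nmi(parts[[i]][[t]], parts[[j]][[t]])
      }
    }
    m
  })
  acc <- Reduce(`+`, per) / nthr
  list(mean = acc, per_threshold = per)
}

mean_cross <- function(m, in1, in2) {
  mean(m[in1, in2])
}

mean_within <- function(m, idx) {
  sub <- m[idx, idx]
  mean(sub[upper.tri(sub)])
}

perm_p_le <- function(null, obs) (1 + sum(null <= obs)) / (length(null) + 1)

perm_p_two <- function(null, obs) {
  lo <- (1 + sum(null <= obs)) / (length(null) + 1)
  hi <- (1 + sum(null >= obs)) / (length(null) + 1)
  min(1, 2 * min(lo, hi))
}

#' Between-group partition-similarity permutation test
#'
#' Observed statistic: the mean pairwise NMI over all cross-group subject
#' pairs (per density threshold, then averaged). The null randomises group
#' membership while retaining group sizes. Following the study's decision
#' rule, the difference is significant when the observed between-group NMI
#' falls below the 5th percentile of the null; the one-sided permutation
#' p-value with the +1 finite-sample correction is reported alongside.
#'
#' @param partitions list, one element per subject: either a single partition
#'   or a list of partitions (one per density threshold, each the
#'   highest-modularity partition for that threshold).
#' @param groups group label per subject (2 levels).
#' @param n_perm number of permutations (study value 5000).
#' @param seed RNG seed.
#' @return an `nmi_test` list: observed, per_threshold, null, p_value,
#'   significant, n_perm.
#' @export
between_group_test <- function(partitions, groups, n_perm = 5000,
                               seed = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  groups <- as.factor(groups)
  lev <- levels(groups)
  if (length(lev) != 2 || any(table(groups) < 2)) {
    stop("need two groups with >= 2 subjects each", call. = FALSE)
  }
  pw <- pairwise_nmi(partitions)
  g1 <- which(groups == lev[1])
  g2 <- which(groups == lev[2])
  obs <- mean_cross(pw$mean, g1, g2)
  obs_thr <- vapply(pw$per_threshold, mean_cross, numeric(1), g1, g2)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_perm), function(b) {
    perm <- sample(seq_along(groups))
    mean_cross(pw$mean, perm[seq_along(g1)], perm[-seq_along(g1)])
  }, numeric(1))
  structure(list(observed = obs, per_threshold = obs_thr, null = null,
                 p_value = perm_p_le(null, obs),
                 significant = obs < quantile(null, 0.05),
                 n_perm = n_perm),
            class = "nmi_test")
}

#' @export
print.nmi_test <- function(x, ...) {
  cat("NMI permutation test: observed =", round(x$observed, 4),
      " p =", signif(x$p_value, 3), "\n")
  invisible(x)
}

#' Within-group partition-similarity permutation tests
#'
#' Mean pairwise NMI among the subjects of each group, compared (two-sided)
#' with the null obtained by randomising group membership: a group may be
#' more homogeneous or more heterogeneous than chance.
#'
#' @inheritParams between_group_test
#' @return named list of `nmi_test` objects, one per group.
#' @export
within_group_similarity_test <- function(partitions, groups, n_perm = 5000,
                                         seed = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  groups <- as.factor(groups)
  lev <- levels(groups)
  if (length(lev) != 2 || any(table(groups) < 2)) {
    stop("need two groups with >= 2 subjects each", call. = FALSE)
  }
  pw <- pairwise_nmi(partitions)
  if (!is.null(seed)) set.seed(seed)
  sizes <- table(groups)
  out <- list()
  perms <- lapply(seq_len(n_perm), function(b) sample(seq_along(groups)))
  for (g in lev) {
    idx <- which(groups == g)
    obs <- mean_within(pw$mean, idx)
    obs_thr <- vapply(pw$per_threshold, mean_within, numeric(1), idx)
    null <- vapply(perms, function(perm) {
      mean_within(pw$mean, perm[seq_len(length(idx))])
    }, numeric(1))
    out[[g]] <- structure(list(observed = obs, per_threshold = obs_thr,
                               null = null,
                               p_value = perm_p_two(null, obs),
                               significant = perm_p_two(null, obs) < 0.05,
                               n_perm = n_perm),
                          class = "nmi_test")
  }
  out
}

#' Group difference in within-subject partition stability over time
#'
#' Computes each subject's NMI between the session-1 and session-2 partitions
#' (per threshold, then averaged) and tests the difference of group means by
#' permuting group labels (two-sided, +1 correction).
#'
#' @param partitions_t1,partitions_t2 lists, one element per subject (single
#'   partition or per-threshold list), aligned with `groups`.
#' @inheritParams between_group_test
#' @return a `perm_test` list: per_subject NMI, statistic (group-1 mean minus
#'   group-2 mean), null, p_value.
#' @export
within_subject_over_time_test <- function(partitions_t1, partitions_t2,
                                          groups, n_perm = 5000,
                                          seed = NULL) {
  if (length(partitions_t1) != length(partitions_t2) ||
      length(partitions_t1) != length(groups)) {
    stop("both sessions are required for every subject", call. = FALSE)
  }
  groups <- as.factor(groups)
  lev <- levels(groups)
  per_subject <- vapply(seq_along(groups), function(i) {
    a <- partitions_t1[[i]]
    b <- partitions_t2[[i]]
    if (!is.list(a)) a <- list(a)
    if (!is.list(b)) b <- list(b)
    mean(vapply(seq_along(a), function(t) nmi(a[[t]], b[[t]]), numeric(1)))
  }, numeric(1))
  names(per_subject) <- names(partitions_t1)
  permutation_group_test(per_subject, groups, n_perm = n_perm, seed = seed)
}
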