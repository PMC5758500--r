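#' Two-sample permutation test on group means
#'
#' Statistic: mean of group 1 minus mean of group 2 (first factor level
#' first). The null shuffles group labels retaining group sizes; the p-value
#' is two-sided with the +1 finite-sample correction.
#'
#' @param values numeric vector, one value per subject.
#' @param groups two-level group label per subject.
#' @param n_perm number of permutations (default 5000).
#' @param seed RNG seed.
#' @return a `perm_test` list: statistic, null, p_value, n_perm, plus the
#'   per-subject values.
#' @export
permutation_group_test <- function(values, groups, n_perm = 5000,
                                   seed = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  groups <- as.factor(groups)
  lev <- levels(groups)
  if (length(lev) != 2 || any(table(groups) < 2)) {
    stop("need two groups with >= 2 subjects each", call. = FALSE)
  }
  if (length(values) != length(groups)) {
    stop("values and groups must align", call. = FALSE)
  }
  i1 <- groups == lev[1]
  obs <- mean(values[i1]) - mean(values[!i1])
  if (!is.null(seed)) set.seed(seed)
  n1 <- sum(i1)
  null <- vapply(seq_len(n_perm), function(b) {
    perm <- sample(values)
    mean(perm[seq_len(n1)]) - mean(perm[-seq_len(n1)])
  }, numeric(1))
  structure(list(statistic = obs, null = null,
                 p_value = (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1),
                 n_perm = n_perm, per_subject = values, groups = groups),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test: statistic =", signif(x$statistic, 4),
      " p =", signif(x$p_value, 3), "\n")
  invisible(x)
}

#' Max-statistic family-wise error corrected group comparisons
#'
#' One group comparison per module, corrected across the module family with
#' the max-statistic method: a single shared permutation stream records, per
#' permutation, the maximum over modules of |mean difference|; each module's
#' p_fwe is the fraction of those maxima at least as large as its observed
#' |statistic| (+1 correction). Uncorrected p-values come from each module's
#' own null in the same stream.
#'
#' @param value_matrix numeric subjects x modules matrix (same subjects in
#'   every column).
#' @inheritParams permutation_group_test
#' @return tibble: module, statistic, p_uncorrected, p_fwe; the permutation
#'   null maxima are attached as attribute `max_null`.
#' @export
max_stat_fwe <- function(value_matrix, groups, n_perm = 5000, seed = NULL) {
  x <- as.matrix(value_matrix)
  groups <- as.factor(groups)
  lev <- levels(groups)
  if (length(lev) != 2 || any(table(groups) < 2)) {
    stop("need two groups with >= 2 subjects each", call. = FALSE)
  }
  if (nrow(x) != length(groups)) {
    stop("value_matrix rows and groups must align", call. = FALSE)
  }
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  i1 <- groups == lev[1]
  n1 <- sum(i1)
  obs <- colMeans(x[i1, , drop = FALSE]) - colMeans(x[!i1, , drop = FALSE])
  if (!is.null(seed)) set.seed(seed)
  nulls <- matrix(NA_real_, n_perm, ncol(x))
  for (b in seq_len(n_perm)) {
    perm <- sample(nrow(x))
    nulls[b, ] <- colMeans(x[perm[seq_len(n1)], , drop = FALSE]) -
      colMeans(x[perm[-seq_len(n1)], , drop = FALSE])
  }
  max_null <- apply(abs(nulls), 1, max)
  p_unc <- vapply(seq_len(ncol(x)), function(m) {
    (1 + sum(abs(nulls[, m]) >= abs(obs[m]))) / (n_perm + 1)
  }, numeric(1))
  p_fwe <- vapply(seq_len(ncol(x)), function(m) {
    (1 + sum(max_null >= abs(obs[m]))) / (n_perm + 1)
  }, numeric(1))
  out <- tibble::tibble(
    module = colnames(x) %||% as.character(seq_len(ncol(x))),
    statistic = as.numeric(obs),
    p_uncorrected = p_unc,
    p_fwe = p_fwe)
  attr(out, "max_null") <- max_null
  out
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (average ranks for ties); p from
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom,
#' two-sided.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return list: rho, p_value, n.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4) {
    stop("need equal lengths >= 4", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("constant vector has no rank correlation", call. = FALSE)
  }
  rho <- cor(rank(x), rank(y))
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Partial Spearman correlation controlling for a covariate
#'
#' Rank-transforms all three vectors, regresses the x- and y-ranks on the
#' covariate ranks, and correlates the residuals. A constant covariate falls
#' back to the plain Spearman correlation with a warning.
#'
#' @param x,y numeric vectors (length >= 5).
#' @param covariate nuisance variable (e.g. composite motion).
#' @return list: rho, p_value, n.
#' @export
partial_spearman <- function(x, y, covariate) {
  n <- length(x)
  if (length(y) != n || length(covariate) != n || n < 5) {
    stop("need equal lengths >= 5", call. = FALSE)
  }
  if (sd(covariate) == 0) {
    warning("constant covariate: falling back to plain Spearman correlation")
    return(spearman_cor(x, y))
  }
  rx <- rank(x); ry <- rank(y); rz <- rank(covariate)
  ex <- residuals(lm(rx ~ rz))
  ey <- residuals(lm(ry ~ rz))
  # a variable fully explained by the covariate leaves only floating-point
  # dust in the residuals; the partial correlation is 0 by definition then
  if (sd(ex) < 1e-8 * sd(rx) || sd(ey) < 1e-8 * sd(ry)) {
    return(list(rho = 0, p_value = 1, n = n))
  }
  rho <- cor(ex, ey)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 3) / (1 - rho^2))
    2 * pt(-abs(tt), df = n - 3)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Per-subject learning slopes from a linear spline
#'
#' Least-squares fit of score ~ 1 + s + (s - knot)_+ over training sessions
#' s, with the knot at the second session: the early slope (coefficient on s)
#' is the session 1-to-2 learning rate; the late slope (sum of the two slope
#' coefficients) is the rate from the knot on.
#'
#' @param scores numeric vector of per-session scores (mean set size), or a
#'   data frame with columns `session` and `score`.
#' @param sessions session indices (default `seq_along(scores)`).
#' @param knot spline knot (default 2).
#' @return list: early_slope, late_slope, residual_sd, n_sessions.
#' @export
fit_learning_slopes <- function(scores, sessions = NULL, knot = 2) {
  if (is.data.frame(scores)) {
    sessions <- scores$session
    scores <- scores$score
  }
  if (is.null(sessions)) sessions <- seq_along(scores)
  if (length(scores) < 3) stop("need >= 3 sessions", call. = FALSE)
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (knot <= min(sessions) || knot >= max(sessions)) {
    stop("knot must lie inside the session range", call. = FALSE)
  }
  hinge <- pmax(sessions - knot, 0)
  fit <- lm(scores ~ sessions + hinge)
  cf <- coef(fit)
  list(early_slope = unname(cf["sessions"]),
       late_slope = unname(cf["sessions"] + cf["hinge"]),
       residual_sd = sd(residuals(fit)),
       n_sessions = length(scores))
}

#' Slopes for every subject in a learning-curve table
#'
#' @param learning tibble with columns subject_id, session, score.
#' @inheritParams fit_learning_slopes
#' @return tibble: subject_id, early_slope, late_slope, residual_sd.
#' @export
learning_slopes_table <- function(learning, knot = 2) {
  ids <- unique(learning$subject_id)
  rows <- lapply(ids, function(id) {
    cur <- learning[learning$subject_id == id, ]
    fs <- fit_learning_slopes(cur$score, cur$session, knot = knot)
    data.frame(subject_id = id, early_slope = fs$early_slope,
               late_slope = fs$late_slope, residual_sd = fs$residual_sd,
               stringsAsFactors = FALSE)
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Associate baseline network metrics with early learning rates
#'
#' Spearman correlation between each threshold-averaged brain-wide metric and
#' the early learning slope, separately per group and session, with the
#' per-threshold rho curve and the motion-partialled coefficient. When a
#' per-module value matrix is supplied for a significant brain-wide result,
#' module-level associations are assessed with max-statistic FWE correction
#' over the module family (permuting the learning slopes).
#'
#' @param metric_table a [compute_metric_tables()] result.
#' @param slopes a [learning_slopes_table()] result.
#' @param motion named per-subject motion vector (or manifest tibble).
#' @param metrics metric columns to test.
#' @param module_values optional named list: metric name -> subjects x
#'   modules matrix of per-module values for the follow-up.
#' @param n_perm permutations for the module-level max-stat correction.
#' @param seed RNG seed.
#' @return tibble: metric, group, session, n, rho, p_value, rho_partial,
#'   p_partial, with per-threshold rho curves in attribute `per_threshold`
#'   and module follow-ups in attribute `module_followup`.
#' @export
associate_metrics_learning <- function(metric_table, slopes, motion,
                                       metrics = c("Q", "Eglob", "Eloc"),
                                       module_values = NULL,
                                       n_perm = 5000, seed = NULL) {
  if (is.data.frame(motion)) {
    motion <- setNames(motion$motion[!duplicated(motion$subject_id)],
                       motion$subject_id[!duplicated(motion$subject_id)])
  }
  unmatched <- setdiff(unique(metric_table$subject_id), slopes$subject_id)
  if (length(unmatched)) {
    stop("no learning data for subject(s): ",
         paste(head(unmatched, 5), collapse = ", "), call. = FALSE)
  }
  rows <- list()
  curves <- list()
  followups <- list()
  k <- 0
  thr_levels <- setdiff(unique(metric_table$density), "mean")
  for (g in unique(metric_table$group)) {
    for (sess in sort(unique(metric_table$session))) {
      cell <- metric_table[metric_table$group == g &
                             metric_table$session == sess, ]
      subj <- unique(cell$subject_id)
      es <- slopes$early_slope[match(subj, slopes$subject_id)]
      mo <- motion[subj]
      for (metric in metrics) {
        avg <- cell[cell$density == "mean", ]
        v <- avg[[metric]][match(subj, avg$subject_id)]
        sc <- spearman_cor(v, es)
        pc <- partial_spearman(v, es, mo)
        per_thr <- vapply(thr_levels, function(d) {
          vt <- cell[cell$density == d, ]
          spearman_cor(vt[[metric]][match(subj, vt$subject_id)], es)$rho
        }, numeric(1))
        k <- k + 1
        rows[[k]] <- data.frame(metric = metric, group = g, session = sess,
                                n = length(subj), rho = sc$rho,
                                p_value = sc$p_value,
                                rho_partial = pc$rho,
                                p_partial = pc$p_value,
                                stringsAsFactors = FALSE)
        curves[[paste(metric, g, sess, sep = ".")]] <- per_thr
        if (!is.null(module_values) && sc$p_value < 0.05 &&
            !is.null(module_values[[metric]])) {
          mv <- module_values[[metric]][subj, , drop = FALSE]
          followups[[paste(metric, g, sess, sep = ".")]] <-
            module_association_fwe(mv, es, n_perm = n_perm, seed = seed)
        }
      }
    }
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  attr(out, "per_threshold") <- curves
  attr(out, "module_followup") <- followups
  out
}

# Max-statistic FWE over modules for metric-learning correlations: permute
# the slopes, record the max |rho| over modules per permutation.
module_association_fwe <- function(module_values, early_slopes,
                                   n_perm = 5000, seed = NULL) {
  x <- as.matrix(module_values)
  obs <- vapply(seq_len(ncol(x)), function(m) {
    spearman_cor(x[, m], early_slopes)$rho
  }, numeric(1))
  if (!is.null(seed)) set.seed(seed)
  max_null <- vapply(seq_len(n_perm), function(b) {
    es <- sample(early_slopes)
    max(abs(vapply(seq_len(ncol(x)), function(m) {
      cor(rank(x[, m]), rank(es))
    }, numeric(1))))
  }, numeric(1))
  tibble::tibble(
    module = colnames(x) %||% as.character(seq_len(ncol(x))),
    rho = obs,
    p_fwe = vapply(obs, function(r) {
      (1 + sum(max_null >= abs(r))) / (n_perm + 1)
    }, numeric(1)))
}
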