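#' Simulation configuration for a synthetic two-group, two-session cohort
#'
#' The defaults emulate the study design the analysis targets: two groups of
#' 20 subjects ("young", "older"), 234 ROIs organised into 5 modules, 235
#' time points per resting-state session, two sessions, and 10 training
#' sessions of a working-memory task. The "older" group is planted with
#' lower within-module and higher between-module coupling, the topological
#' signature of age-related dedifferentiation.
#'
#' @param n_nodes total number of ROIs.
#' @param module_sizes module sizes, summing to `n_nodes`.
#' @param n_subjects_per_group subjects per group.
#' @param n_timepoints samples per session.
#' @param r_within_by_group named (young, older) within-module correlations.
#' @param r_between_by_group named between-module correlations.
#' @param subject_sd SD of per-subject jitter on the within-module coupling.
#' @param session_reliability fraction in `[0, 1]` of the subject-specific
#'   coupling jitter shared between the two sessions (1 = both sessions use
#'   the identical generative covariance).
#' @param motion_mean_by_group,motion_sd per-group mean and SD of the
#'   composite motion scalar (arbitrary units, truncated at 0).
#' @param learning_coupling slope linking the standardized planted
#'   within-module coupling to the early (session 1 to 2) learning increment,
#'   in set-size units per SD.
#' @param learning_noise_sd additive noise on the learning scores (set-size
#'   units).
#' @param late_rate set-size gain per session after the early phase, up to
#'   the plateau.
#' @param plateau_session training session after which scores stop rising.
#' @param n_training_sessions number of training sessions (default 10).
#' @param seed RNG seed; identical config + seed reproduces byte-identical
#'   cohorts.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_nodes = 234,
                       module_sizes = c(50, 50, 46, 44, 44),
                       n_subjects_per_group = 20,
                       n_timepoints = 235,
                       r_within_by_group = c(young = 0.30, older = 0.22),
                       r_between_by_group = c(young = 0.05, older = 0.08),
                       subject_sd = 0.03,
                       session_reliability = 0.7,
                       motion_mean_by_group = c(young = 0.15, older = 0.18),
                       motion_sd = 0.05,
                       learning_coupling = 0.5,
                       learning_noise_sd = 0.25,
                       late_rate = 0.4,
                       plateau_session = 7,
                       n_training_sessions = 10,
                       seed = 1L) {
  if (sum(module_sizes) != n_nodes) {
    stop("module_sizes must sum to n_nodes", call. = FALSE)
  }
  rs <- c(r_within_by_group, r_between_by_group)
  if (any(rs <= -1 | rs >= 1)) {
    stop("correlations must lie in (-1, 1)", call. = FALSE)
  }
  if (any(r_within_by_group <= r_between_by_group)) {
    stop("r_within must exceed r_between for a planted modular structure",
         call. = FALSE)
  }
  if (session_reliability < 0 || session_reliability > 1) {
    stop("session_reliability must be in [0, 1]", call. = FALSE)
  }
  if (n_timepoints < 2) stop("n_timepoints must be >= 2", call. = FALSE)
  if (n_training_sessions < 3) {
    stop("need >= 3 training sessions for the spline fit", call. = FALSE)
  }
  groups <- names(r_within_by_group) %||% c("young", "older")
  structure(list(n_nodes = n_nodes, module_sizes = module_sizes,
                 groups = groups,
                 n_subjects_per_group = n_subjects_per_group,
                 n_timepoints = n_timepoints,
                 r_within_by_group = r_within_by_group,
                 r_between_by_group = r_between_by_group,
                 subject_sd = subject_sd,
                 session_reliability = session_reliability,
                 motion_mean_by_group = motion_mean_by_group,
                 motion_sd = motion_sd,
                 learning_coupling = learning_coupling,
                 learning_noise_sd = learning_noise_sd,
                 late_rate = late_rate,
                 plateau_session = plateau_session,
                 n_training_sessions = n_training_sessions,
                 seed = seed),
            class = "sim_config")
}

#' Block covariance matrix with planted modules
#'
#' Unit-diagonal matrix with `r_within` on same-module off-diagonal entries
#' and `r_between` elsewhere. Errors (naming the smallest eigenvalue) if the
#' combination is not positive semi-definite.
#'
#' @param module_sizes module sizes.
#' @param r_within,r_between correlations in (-1, 1).
#' @export
build_block_covariance <- function(module_sizes, r_within, r_between) {
  n <- sum(module_sizes)
  labels <- rep(seq_along(module_sizes), module_sizes)
  s <- matrix(r_between, n, n)
  same <- outer(labels, labels, "==")
  s[same] <- r_within
  diag(s) <- 1
  ev <- min(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) {
    stop("block covariance is not positive semi-definite ",
         "(smallest eigenvalue ", format(ev), ")", call. = FALSE)
  }
  attr(s, "module_labels") <- labels
  s
}

#' Generate a synthetic cohort
#'
#' Draws, for every subject and session, a T x N time-series matrix from a
#' zero-mean multivariate normal whose within-module coupling perturbs the
#' group value by subject- and session-level jitter mixed according to
#' `session_reliability`. Motion scalars are drawn per subject, and each
#' subject receives a saturating piecewise-linear learning curve whose
#' session 1-to-2 increment is `learning_coupling` times the subject's
#' standardized planted coupling, plus noise.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; when given, time series (TSV),
#'   manifest, learning curves and the planted-truth table (CSV) are written
#'   there.
#' @return list with `manifest` (tibble: subject_id, group, session,
#'   timeseries_path, motion), `timeseries` (named list, "subject.session"),
#'   `learning` (tibble: subject_id, session, score), `truth` (tibble of
#'   generative parameters per subject) and `module_labels`.
#' @export
sample_cohort <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  groups <- config$groups
  nodes <- paste0("roi", sprintf("%03d", seq_len(config$n_nodes)))
  labels <- rep(seq_along(config$module_sizes), config$module_sizes)
  subjects <- data.frame(
    subject_id = sprintf("%s%02d", substr(rep(groups,
                            each = config$n_subjects_per_group), 1, 1),
                         rep(seq_len(config$n_subjects_per_group),
                             length(groups))),
    group = rep(groups, each = config$n_subjects_per_group),
    stringsAsFactors = FALSE)
  ns <- nrow(subjects)
  rel <- config$session_reliability
  subj_jit <- rnorm(ns, 0, config$subject_sd)
  sess_jit <- matrix(rnorm(ns * 2, 0, config$subject_sd), ns, 2)
  motion <- pmax(0, rnorm(ns,
                          config$motion_mean_by_group[subjects$group],
                          config$motion_sd))
  if (!is.null(dir) && !dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", dir, call. = FALSE)
  }
  ts_list <- list()
  manifest <- list()
  truth <- list()
  r_within_eff <- matrix(NA_real_, ns, 2)
  for (i in seq_len(ns)) {
    g <- subjects$group[i]
    for (sess in 1:2) {
      r_w <- config$r_within_by_group[[g]] +
        sqrt(rel) * subj_jit[i] + sqrt(1 - rel) * sess_jit[i, sess]
      r_b <- config$r_between_by_group[[g]]
      r_w <- max(r_w, r_b + 0.01) # keep the planted structure valid
      r_within_eff[i, sess] <- r_w
      sigma <- build_block_covariance(config$module_sizes, r_w, r_b)
      ts <- MASS::mvrnorm(config$n_timepoints,
                          mu = rep(0, config$n_nodes), Sigma = sigma)
      colnames(ts) <- nodes
      key <- paste0(subjects$subject_id[i], ".", sess)
      ts_list[[key]] <- ts
      path <- if (is.null(dir)) NA_character_ else
        file.path(dir, paste0("ts_", key, ".tsv"))
      if (!is.null(dir)) {
        utils::write.table(round(ts, 6), path, sep = "\t",
                           row.names = FALSE, quote = FALSE)
      }
      manifest[[key]] <- data.frame(subject_id = subjects$subject_id[i],
                                    group = g, session = sess,
                                    timeseries_path = path,
                                    motion = motion[i],
                                    stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  # learning curves: early increment coupled to the subject's planted
  # session-1 coupling, standardized within group
  learning <- list()
  early_inc <- numeric(ns)
  for (g in groups) {
    idx <- which(subjects$group == g)
    zc <- if (length(idx) > 1 && sd(r_within_eff[idx, 1]) > 0) {
      as.numeric(scale(r_within_eff[idx, 1]))
    } else {
      rep(0, length(idx))
    }
    base_early <- if (g == groups[1]) 1.2 else 0.8
    early_inc[idx] <- base_early + config$learning_coupling * zc
  }
  sessions <- seq_len(config$n_training_sessions)
  for (i in seq_len(ns)) {
    ramp <- pmin(pmax(sessions - 2, 0),
                 config$plateau_session - 2) * config$late_rate
    scores <- 3 + early_inc[i] * pmin(sessions - 1, 1) + ramp +
      rnorm(length(sessions), 0, config$learning_noise_sd)
    learning[[i]] <- data.frame(subject_id = subjects$subject_id[i],
                                session = sessions, score = scores)
  }
  learning <- do.call(rbind, learning)
  truth <- data.frame(subject_id = subjects$subject_id,
                      group = subjects$group,
                      r_within_s1 = r_within_eff[, 1],
                      r_within_s2 = r_within_eff[, 2],
                      r_between = config$r_between_by_group[subjects$group],
                      motion = motion,
                      early_increment = early_inc,
                      stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    write.csv(learning, file.path(dir, "learning.csv"), row.names = FALSE)
    write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  list(manifest = tibble::as_tibble(manifest),
       timeseries = ts_list,
       learning = tibble::as_tibble(learning),
       truth = tibble::as_tibble(truth),
       module_labels = setNames(labels, nodes))
}
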