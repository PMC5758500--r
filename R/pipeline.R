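#' Pipeline configuration
#'
#' The `"paper"` profile carries the study-fidelity defaults (densities
#' 0.02-0.10 step 0.01, gamma 1.25, tau 0.5, 500 Louvain runs, 5000
#' permutations, FDR q 0.05); the `"reduced"` profile keeps the same grid and
#' resolution but lowers the repetition counts for quick, fully deterministic
#' end-to-end runs.
#'
#' @param profile `"paper"` or `"reduced"`.
#' @param ... overrides for individual fields (thresholds, gamma, tau, runs,
#'   consensus_runs, n_perm, fdr_q, knot, seed).
#' @export
pipeline_config <- function(profile = c("paper", "reduced"), ...) {
  profile <- match.arg(profile)
  cfg <- list(thresholds = seq(0.02, 0.10, by = 0.01),
              gamma = 1.25, tau = 0.5,
              runs = 500, consensus_runs = 500,
              n_perm = 5000, fdr_q = 0.05, knot = 2, seed = 1L,
              profile = profile)
  if (profile == "reduced") {
    cfg$runs <- 20
    cfg$consensus_runs <- 20
    cfg$n_perm <- 200
  }
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  stopifnot(all(cfg$thresholds > 0), all(cfg$thresholds < 1),
            cfg$runs >= 1, cfg$n_perm >= 100, cfg$fdr_q > 0, cfg$fdr_q < 1)
  structure(cfg, class = "pipeline_config")
}

#' Validate a cohort manifest against its files and learning curves
#'
#' Checks file existence, time-series dimensions and finiteness, session
#' completeness (each subject exactly sessions 1 and 2), and subject matching
#' between the manifest and learning curves. Reports issues rather than
#' raising.
#'
#' @param manifest manifest tibble (subject_id, group, session,
#'   timeseries_path, motion).
#' @param learning optional learning-curve tibble (subject_id, session,
#'   score).
#' @param timeseries optional in-memory named list ("subject.session") used
#'   instead of the manifest paths.
#' @return tibble of issues (type, subject_id, message); zero rows when
#'   everything is well formed.
#' @export
validate_inputs <- function(manifest, learning = NULL, timeseries = NULL) {
  issues <- list()
  add <- function(type, subject, msg) {
    issues[[length(issues) + 1]] <<- data.frame(
      type = type, subject_id = subject, message = msg,
      stringsAsFactors = FALSE)
  }
  dup <- duplicated(manifest[c("subject_id", "session")])
  if (any(dup)) {
    for (i in which(dup)) {
      add("duplicate", manifest$subject_id[i],
          paste("duplicated session", manifest$session[i]))
    }
  }
  for (id in unique(manifest$subject_id)) {
    ses <- sort(manifest$session[manifest$subject_id == id])
    if (!identical(as.integer(ses), c(1L, 2L))) {
      add("completeness", id,
          paste("expected sessions 1 and 2, found:",
                paste(ses, collapse = ", ")))
    }
  }
  dims <- NULL
  for (i in seq_len(nrow(manifest))) {
    key <- paste0(manifest$subject_id[i], ".", manifest$session[i])
    ts <- NULL
    if (!is.null(timeseries)) {
      ts <- timeseries[[key]]
      if (is.null(ts)) add("missing", manifest$subject_id[i],
                          paste("no in-memory time series for", key))
    } else {
      path <- manifest$timeseries_path[i]
      if (is.na(path) || !file.exists(path)) {
        add("missing", manifest$subject_id[i],
            paste("time-series file not found:", path))
      } else {
        ts <- read_timeseries(path)
      }
    }
    if (!is.null(ts)) {
      if (is.null(dims)) dims <- dim(ts)
      if (!identical(dim(ts), dims)) {
        add("dimensions", manifest$subject_id[i],
            sprintf("expected %d x %d, found %d x %d for %s",
                    dims[1], dims[2], nrow(ts), ncol(ts), key))
      }
      if (!all(is.finite(ts))) {
        add("finiteness", manifest$subject_id[i],
            paste("non-finite values in", key))
      }
    }
  }
  if (!is.null(learning)) {
    miss <- setdiff(unique(manifest$subject_id), unique(learning$subject_id))
    for (id in miss) add("learning", id, "no learning curve")
    short <- table(learning$subject_id)
    for (id in names(short)[short < 3]) {
      add("learning", id, "fewer than 3 training sessions")
    }
  }
  if (length(issues)) {
    tibble::as_tibble(do.call(rbind, issues))
  } else {
    tibble::tibble(type = character(), subject_id = character(),
                   message = character())
  }
}

#' Highest-modularity partitions per subject, session and threshold
#'
#' For every subject x session and every density threshold, the binarized
#' graph's best-of-`runs` Louvain + fine-tuning partition (the input the
#' partition-similarity tests require).
#'
#' @param conn named list ("subject.session") of connectivity matrices.
#' @param keys character vector of "subject.session" keys to process.
#' @param thresholds density grid.
#' @param gamma,runs,seed optimisation settings.
#' @return named list: key -> list of partitions, one per threshold.
#' @export
subject_threshold_partitions <- function(conn, keys = names(conn),
                                         thresholds = seq(0.02, 0.10,
                                                          by = 0.01),
                                         gamma = 1.25, runs = 500,
                                         seed = NULL) {
  seeds <- derive_seeds(seed, length(keys) * length(thresholds))
  out <- list()
  k <- 0
  for (key in keys) {
    per <- list()
    for (ti in seq_along(thresholds)) {
      k <- k + 1
      g <- threshold_density(conn[[key]], thresholds[ti])
      per[[ti]] <- best_partition(g$adjacency * 1.0, gamma = gamma,
                                  runs = runs, seed = seeds[k])$partition
    }
    out[[key]] <- per
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes every stage in dependency order on a cohort (synthetic or from a
#' manifest): connectivity, subject/group consensus partitions, consistent
#' nodes, metric tables, partition-similarity tests, reliability profile,
#' group comparisons with max-statistic FWE at the module level, and
#' learning-rate associations. All randomness derives from `config$seed`.
#'
#' @param cohort a [sample_cohort()] result, or a list with elements
#'   `manifest`, `learning` and either `timeseries` or readable
#'   `timeseries_path`s.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, tables are written as CSV
#'   and the summary as JSON, each stamped with the config hash and seed.
#' @return a `pipeline_result` list of all stage outputs plus a `summary`
#'   list mirroring the JSON report.
#' @export
run_pipeline <- function(cohort, config = pipeline_config("reduced"),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- cohort$manifest
  issues <- validate_inputs(manifest, cohort$learning, cohort$timeseries)
  if (nrow(issues)) {
    stop("input validation failed at stage 'validate': ",
         paste(head(issues$message, 3), collapse = "; "), call. = FALSE)
  }
  seeds <- derive_seeds(config$seed, 12)
  keys <- paste0(manifest$subject_id, ".", manifest$session)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  conn <- stage("connectivity", {
    out <- list()
    for (i in seq_along(keys)) {
      ts <- if (!is.null(cohort$timeseries)) {
        cohort$timeseries[[keys[i]]]
      } else {
        read_timeseries(manifest$timeseries_path[i])
      }
      out[[keys[i]]] <- correlation_matrix(ts)
    }
    out
  })
  groups_of <- setNames(manifest$group, keys)
  # subject-level weighted consensus partitions, then 4 group-session cells
  params <- consensus_params(gamma = config$gamma, tau = config$tau,
                             runs = config$consensus_runs)
  subj_cons <- stage("subject_consensus", {
    ss <- derive_seeds(seeds[1], length(keys))
    out <- list()
    for (i in seq_along(keys)) {
      p <- params
      p$seed <- ss[i]
      out[[keys[i]]] <- subject_consensus(conn[[keys[i]]], p)
    }
    out
  })
  cells <- expand.grid(group = unique(manifest$group), session = 1:2,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  group_parts <- stage("group_consensus", {
    ss <- derive_seeds(seeds[2], nrow(cells))
    out <- list()
    for (i in seq_len(nrow(cells))) {
      sel <- keys[manifest$group == cells$group[i] &
                    manifest$session == cells$session[i]]
      p <- params
      p$seed <- ss[i]
      out[[paste0(cells$group[i], ".", cells$session[i])]] <-
        group_consensus(subj_cons[sel], p)
    }
    out
  })
  assignment <- stage("consistent_nodes", consistent_nodes(group_parts))
  metric_table <- stage("metrics", {
    compute_metric_tables(conn, manifest, thresholds = config$thresholds,
                          gamma = config$gamma, runs = config$runs,
                          seed = seeds[3])
  })
  module_metrics <- stage("module_metrics", {
    compute_module_metrics(conn, manifest, assignment,
                           thresholds = config$thresholds,
                           fdr_q = config$fdr_q)
  })
  thr_parts <- stage("threshold_partitions", {
    subject_threshold_partitions(conn, keys, thresholds = config$thresholds,
                                 gamma = config$gamma, runs = config$runs,
                                 seed = seeds[4])
  })
  subjects <- unique(manifest$subject_id)
  subj_group <- manifest$group[match(subjects, manifest$subject_id)]
  t1_keys <- paste0(subjects, ".1")
  t2_keys <- paste0(subjects, ".2")
  similarity <- stage("similarity", list(
    between_t1 = between_group_test(thr_parts[t1_keys], subj_group,
                                    n_perm = config$n_perm, seed = seeds[5]),
    between_t2 = between_group_test(thr_parts[t2_keys], subj_group,
                                    n_perm = config$n_perm, seed = seeds[6]),
    within_t1 = within_group_similarity_test(thr_parts[t1_keys], subj_group,
                                             n_perm = config$n_perm,
                                             seed = seeds[7]),
    over_time = within_subject_over_time_test(thr_parts[t1_keys],
                                              thr_parts[t2_keys], subj_group,
                                              n_perm = config$n_perm,
                                              seed = seeds[8])))
  reliability <- stage("reliability", reliability_profile(metric_table))
  group_tests <- stage("group_tests", {
    ss <- derive_seeds(seeds[9], 3 * 2)
    out <- list()
    k <- 0
    for (sess in 1:2) {
      avg <- metric_table[metric_table$density == "mean" &
                            metric_table$session == sess, ]
      for (metric in c("Q", "Eglob", "Eloc")) {
        k <- k + 1
        out[[paste0(metric, "_t", sess)]] <- permutation_group_test(
          avg[[metric]][match(subjects, avg$subject_id)], subj_group,
          n_perm = config$n_perm, seed = ss[k])
      }
    }
    out
  })
  module_tests <- stage("module_tests", {
    ss <- derive_seeds(seeds[10], 2 * 2)
    out <- list()
    k <- 0
    mm <- module_metrics$modules
    for (sess in 1:2) {
      cur <- mm[mm$session == sess, ]
      for (metric in c("participation", "Eloc")) {
        k <- k + 1
        wide <- matrix(NA_real_, length(subjects),
                       length(unique(cur$module)),
                       dimnames = list(subjects,
                                       paste0("M", sort(unique(cur$module)))))
        for (m in sort(unique(cur$module))) {
          sel <- cur[cur$module == m, ]
          wide[, paste0("M", m)] <- sel[[metric]][match(subjects,
                                                        sel$subject_id)]
        }
        out[[paste0(metric, "_t", sess)]] <- max_stat_fwe(
          wide, subj_group, n_perm = config$n_perm, seed = ss[k])
      }
    }
    out
  })
  associations <- stage("associations", {
    slopes <- learning_slopes_table(cohort$learning, knot = config$knot)
    associate_metrics_learning(metric_table, slopes,
                               setNames(manifest$motion, keys)[t1_keys] |>
                                 setNames(subjects),
                               n_perm = config$n_perm, seed = seeds[11])
  })
  summary <- list(
    config_hash = config_hash(unclass(config)),
    seed = config$seed,
    n_subjects = length(subjects),
    groups = as.list(table(subj_group)),
    consistent_nodes = sum(!is.na(assignment$module)),
    n_modules = length(unique(assignment$module[!is.na(assignment$module)])),
    group_mean_Q = lapply(split(
      metric_table$Q[metric_table$density == "mean" &
                       metric_table$session == 1],
      metric_table$group[metric_table$density == "mean" &
                           metric_table$session == 1]), mean),
    similarity = list(
      between_t1 = list(observed = similarity$between_t1$observed,
                        p = similarity$between_t1$p_value),
      between_t2 = list(observed = similarity$between_t2$observed,
                        p = similarity$between_t2$p_value),
      over_time = list(statistic = similarity$over_time$statistic,
                       p = similarity$over_time$p_value)),
    group_tests = lapply(group_tests, function(t) {
      list(statistic = t$statistic, p = t$p_value)
    }),
    reliability = stats::setNames(
      as.list(reliability$icc[reliability$density == "mean" &
                                reliability$grouping == "all"]),
      reliability$metric[reliability$density == "mean" &
                           reliability$grouping == "all"]),
    associations = lapply(seq_len(nrow(associations)), function(i) {
      as.list(associations[i, c("metric", "group", "session", "rho",
                                "p_value", "rho_partial")])
    }))
  result <- structure(list(config = config, manifest = manifest,
                           assignment = assignment,
                           group_partitions = group_parts,
                           metric_table = metric_table,
                           module_metrics = module_metrics,
                           similarity = similarity,
                           reliability = reliability,
                           group_tests = group_tests,
                           module_tests = module_tests,
                           associations = associations,
                           validation = issues,
                           summary = summary),
                      class = "pipeline_result")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.csv(metric_table, file.path(out_dir, "metric_table.csv"),
              row.names = FALSE)
    write.csv(module_metrics$modules,
              file.path(out_dir, "module_metrics.csv"), row.names = FALSE)
    write.csv(reliability, file.path(out_dir, "reliability.csv"),
              row.names = FALSE)
    write.csv(associations, file.path(out_dir, "associations.csv"),
              row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(format_report(result), file.path(out_dir, "report.txt"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

format_report <- function(x) {
  s <- x$summary
  c(sprintf("Pipeline run (profile %s, seed %s, config %s)",
            x$config$profile, s$seed, s$config_hash),
    sprintf("Subjects: %d (%s)", s$n_subjects,
            paste(names(s$groups), unlist(s$groups), collapse = ", ")),
    sprintf("Consistent nodes: %d across %d modules",
            s$consistent_nodes, s$n_modules),
    sprintf("Group mean Q (t1): %s",
            paste(names(s$group_mean_Q),
                  sprintf("%.3f", unlist(s$group_mean_Q)),
                  collapse = ", ")),
    sprintf("Between-group NMI: t1 obs %.3f (p %.3g), t2 obs %.3f (p %.3g)",
            s$similarity$between_t1$observed, s$similarity$between_t1$p,
            s$similarity$between_t2$observed, s$similarity$between_t2$p),
    sprintf("ICC (threshold-averaged, all): %s",
            paste(names(s$reliability),
                  sprintf("%.2f", unlist(s$reliability)), collapse = ", ")))
}
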