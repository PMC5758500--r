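#' Two-way mixed-model intraclass correlation for averaged measurements
#'
#' ICC(A,k): absolute agreement of measurements that are averages of k
#' assessments, from the two-way ANOVA decomposition without replication
#' (rows = subjects, columns = sessions):
#' ICC = (MS_R - MS_E) / (MS_R + (MS_C - MS_E) / n).
#'
#' A table with no variance anywhere (all cells identical) is perfect
#' agreement by convention; it returns 1 with a warning.
#'
#' @param measurements numeric n x k matrix (n subjects, k sessions), no
#'   missing cells.
#' @return an `icc_result` list: icc, ms_r, ms_c, ms_e, n, k, label.
#' @export
icc_a_k <- function(measurements) {
  x <- as.matrix(measurements)
  if (anyNA(x)) stop("no missing cells allowed", call. = FALSE)
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2 || k < 2) stop("need n >= 2 subjects and k >= 2 sessions",
                           call. = FALSE)
  gm <- mean(x)
  rm_ <- rowMeans(x)
  cm <- colMeans(x)
  ms_r <- k * sum((rm_ - gm)^2) / (n - 1)
  ms_c <- n * sum((cm - gm)^2) / (k - 1)
  ms_e <- sum((x - outer(rm_, rep(1, k)) -
                 outer(rep(1, n), cm) + gm)^2) / ((n - 1) * (k - 1))
  if (ms_r == 0 && ms_c == 0 && ms_e == 0) {
    warning("constant table: zero variance everywhere, ICC defined as 1")
    icc <- 1
  } else {
    icc <- (ms_r - ms_e) / (ms_r + (ms_c - ms_e) / n)
  }
  structure(list(icc = icc, ms_r = ms_r, ms_c = ms_c, ms_e = ms_e,
                 n = n, k = k, label = interpret_icc(icc)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat("ICC(A,", x$k, ") = ", round(x$icc, 3), " (", x$label, "), n = ", x$n,
      "\n", sep = "")
  invisible(x)
}

#' Qualitative ICC band
#'
#' Maps an ICC value into the conventional agreement bands: poor (< 0.20),
#' fair (0.21-0.40), moderate (0.41-0.60), strong (0.61-0.80), almost
#' perfect (> 0.80). Values falling in the printed gaps (e.g. 0.205) resolve
#' to the nearer band edge; negative values are "poor".
#'
#' Out-of-range values (possible when the between-subject variance is
#' negligible and the agreement denominator degenerates) are banded by the
#' same cut points; non-finite values give NA.
#'
#' @param value ICC value.
#' @export
interpret_icc <- function(value) {
  cut(value, breaks = c(-Inf, 0.205, 0.405, 0.605, 0.805, Inf),
      labels = c("poor", "fair", "moderate", "strong", "almost perfect"),
      right = TRUE) |> as.character()
}

#' Test-retest reliability profile of brain-wide metrics
#'
#' One ICC(A,2) per metric per density threshold (plus the
#' threshold-averaged rows), for the pooled sample and, optionally, each
#' group separately.
#'
#' @param metric_table a [compute_metric_tables()] result containing both
#'   sessions for every subject.
#' @param metrics metric columns to profile.
#' @param by_group also compute per-group profiles (default TRUE).
#' @return tibble: metric, density, grouping, icc, ms_r, ms_c, ms_e, label.
#' @export
reliability_profile <- function(metric_table, metrics = c("Q", "Eglob", "Eloc"),
                                by_group = TRUE) {
  mt <- metric_table
  groupings <- list(all = unique(mt$subject_id))
  if (by_group) {
    for (g in unique(mt$group)) {
      groupings[[g]] <- unique(mt$subject_id[mt$group == g])
    }
  }
  rows <- list()
  k <- 0
  for (gname in names(groupings)) {
    subj <- groupings[[gname]]
    sub <- mt[mt$subject_id %in% subj, ]
    for (metric in metrics) {
      for (d in unique(sub$density)) {
        s1 <- sub[sub$density == d & sub$session == 1, ]
        s2 <- sub[sub$density == d & sub$session == 2, ]
        if (!setequal(s1$subject_id, s2$subject_id) ||
            nrow(s1) != length(subj)) {
          stop("both sessions are required for every subject in grouping '",
               gname, "'", call. = FALSE)
        }
        m <- cbind(s1[[metric]][match(subj, s1$subject_id)],
                   s2[[metric]][match(subj, s2$subject_id)])
        res <- icc_a_k(m)
        k <- k + 1
        rows[[k]] <- data.frame(metric = metric, density = d,
                                grouping = gname, icc = res$icc,
                                ms_r = res$ms_r, ms_c = res$ms_c,
                                ms_e = res$ms_e, label = res$label,
                                stringsAsFactors = FALSE)
      }
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}
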