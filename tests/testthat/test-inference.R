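test_that("group permutation test handles degenerate and planted cases", {
  # all equal values: statistic 0, p = 1
  res <- permutation_group_test(rep(2, 10), rep(c("a", "b"), 5),
                                n_perm = 200, seed = 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # strong planted shift is detected
  set.seed(2)
  v <- c(rnorm(20), rnorm(20) + 2)
  g <- rep(c("a", "b"), each = 20)
  expect_lt(permutation_group_test(v, g, n_perm = 500, seed = 3)$p_value,
            0.05)
  expect_error(permutation_group_test(1:3, c("a", "a", "b")), "2 subjects")
  expect_error(permutation_group_test(1:4, rep("a", 4)), "two groups")
})

test_that("max-statistic FWE reduces to the plain test for one module", {
  set.seed(4)
  v <- rnorm(20)
  g <- rep(c("a", "b"), each = 10)
  single <- max_stat_fwe(matrix(v, ncol = 1), g, n_perm = 300, seed = 5)
  expect_equal(single$p_fwe, single$p_uncorrected)
  plain <- permutation_group_test(v, g, n_perm = 300, seed = 5)
  expect_equal(single$statistic, plain$statistic)
  expect_equal(single$p_uncorrected, plain$p_value)
})

test_that("max-statistic FWE finds only the shifted module", {
  set.seed(6)
  n <- 40
  g <- rep(c("a", "b"), each = 20)
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("M", 1:5)))
  x[g == "a", 3] <- x[g == "a", 3] + 2.5
  res <- max_stat_fwe(x, g, n_perm = 500, seed = 7)
  expect_lt(res$p_fwe[3], 0.05)
  expect_true(all(res$p_fwe[-3] > 0.05))
  expect_true(all(res$p_fwe >= res$p_uncorrected - 1e-12))
})

test_that("Spearman correlation equals the mid-rank oracle", {
  expect_equal(spearman_cor(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_cor(1:8, -(1:8))$rho, -1)
  set.seed(8)
  for (trial in 1:20) {
    x <- sample(1:5, 12, TRUE) # ties guaranteed
    y <- rnorm(12)
    res <- spearman_cor(x, y)
    expect_equal(res$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
    # monotone-transform invariance
    expect_equal(spearman_cor(exp(x), y)$rho, res$rho, tolerance = 1e-12)
  }
  expect_error(spearman_cor(rep(1, 6), 1:6), "constant")
  expect_error(spearman_cor(1:3, 1:3), "lengths")
})

test_that("partial Spearman removes covariate-driven association", {
  set.seed(9)
  z <- rnorm(60)
  # y is exactly the covariate: nothing left after partialling
  x <- z + rnorm(60, 0, 0.3)
  res <- partial_spearman(x, z, z)
  expect_lt(abs(res$rho), 0.05)
  # independent covariate leaves the correlation (n = 200 limit, averaged
  # over replicates to tame Monte Carlo noise)
  diffs <- replicate(10, {
    x2 <- rnorm(200)
    y2 <- x2 + rnorm(200, 0, 0.8)
    z2 <- rnorm(200)
    abs(partial_spearman(x2, y2, z2)$rho - spearman_cor(x2, y2)$rho)
  })
  expect_lt(mean(diffs), 0.05)
  # residualization oracle
  for (trial in 1:10) {
    a <- rnorm(30)
    b <- rnorm(30)
    cvar <- rnorm(30)
    ra <- rank(a); rb <- rank(b); rc <- rank(cvar)
    ea <- ra - (coef(lm(ra ~ rc))[1] + coef(lm(ra ~ rc))[2] * rc)
    eb <- rb - (coef(lm(rb ~ rc))[1] + coef(lm(rb ~ rc))[2] * rc)
    expect_equal(partial_spearman(a, b, cvar)$rho, cor(ea, eb),
                 tolerance = 1e-10)
  }
  expect_warning(res <- partial_spearman(rnorm(10), rnorm(10), rep(1, 10)),
                 "constant covariate")
})

test_that("learning spline recovers exact and noiseless slopes", {
  # perfectly linear: early = late = slope
  res <- fit_learning_slopes(2 + 0.7 * (1:10))
  expect_equal(res$early_slope, 0.7, tolerance = 1e-10)
  expect_equal(res$late_slope, 0.7, tolerance = 1e-10)
  # exact piecewise: rise 2/session to session 2, then 0.5/session
  s <- 1:10
  scores <- 3 + 2 * pmin(s - 1, 1) + 0.5 * pmax(s - 2, 0)
  res <- fit_learning_slopes(scores)
  expect_equal(res$early_slope, 2, tolerance = 1e-10)
  expect_equal(res$late_slope, 0.5, tolerance = 1e-10)
  expect_equal(res$residual_sd, 0, tolerance = 1e-10)
  expect_error(fit_learning_slopes(c(1, 2)), "3 sessions")
  expect_error(fit_learning_slopes(1:5, knot = 9), "knot")
})

test_that("generator learning slopes track the planted increments", {
  coh <- sample_cohort(tiny_config(seed = 50, n_subjects_per_group = 15))
  slopes <- learning_slopes_table(coh$learning)
  merged <- merge(slopes, coh$truth, by = "subject_id")
  expect_gt(cor(merged$early_slope, merged$early_increment), 0.9)
})

test_that("metric-learning association finds coupling and nothing after shuffling", {
  set.seed(11)
  # synthetic metric table directly coupled to slopes through a latent trait
  n <- 18
  subj <- sprintf("s%02d", 1:n)
  trait <- rnorm(n)
  mt <- do.call(rbind, lapply(c("0.05", "mean"), function(d) {
    data.frame(subject_id = subj, group = "older", session = 1, density = d,
               Q = 0.5 + 0.1 * trait + rnorm(n, 0, 0.02),
               Eglob = 0.5 + rnorm(n, 0, 0.05),
               Eloc = 0.6 + rnorm(n, 0, 0.05))
  }))
  slopes <- data.frame(subject_id = subj,
                       early_slope = 1 + 0.8 * trait + rnorm(n, 0, 0.2),
                       late_slope = 0.4, residual_sd = 0.1)
  motion <- setNames(runif(n, 0.1, 0.2), subj)
  res <- associate_metrics_learning(mt, slopes, motion, n_perm = 200,
                                    seed = 12)
  q_row <- res[res$metric == "Q", ]
  expect_gt(q_row$rho, 0.5)
  expect_lt(q_row$p_value, 0.05)
  # motion is independent here, so partialling barely changes rho
  expect_lt(abs(q_row$rho_partial - q_row$rho), 0.2)
  curves <- attr(res, "per_threshold")
  expect_equal(length(curves[["Q.older.1"]]), 1)
  # shuffled slopes break the linkage
  set.seed(13)
  shuffled <- slopes
  shuffled$early_slope <- sample(shuffled$early_slope)
  res2 <- associate_metrics_learning(mt, shuffled, motion, n_perm = 200,
                                     seed = 14)
  expect_lt(abs(res2$rho[res2$metric == "Q"]), abs(q_row$rho))
  # unmatched subjects are reported
  expect_error(associate_metrics_learning(mt, slopes[-1, ], motion),
               "s01")
})

test_that("module-level association follow-up controls the family", {
  set.seed(15)
  n <- 20
  subj <- sprintf("s%02d", 1:n)
  trait <- rnorm(n)
  mt <- do.call(rbind, lapply(c("0.05", "mean"), function(d) {
    data.frame(subject_id = subj, group = "older", session = 1, density = d,
               Q = 0.5 + 0.12 * trait + rnorm(n, 0, 0.02),
               Eglob = 0.5, Eloc = 0.6)
  }))
  mt$Eglob <- mt$Eglob + rnorm(nrow(mt), 0, 0.04)
  mt$Eloc <- mt$Eloc + rnorm(nrow(mt), 0, 0.04)
  slopes <- data.frame(subject_id = subj,
                       early_slope = 1 + 0.9 * trait + rnorm(n, 0, 0.15))
  motion <- setNames(runif(n, 0.1, 0.2), subj)
  mv <- matrix(rnorm(n * 3), n, 3,
               dimnames = list(subj, paste0("M", 1:3)))
  mv[, 2] <- 0.8 * trait + rnorm(n, 0, 0.3) # only module 2 is coupled
  res <- associate_metrics_learning(mt, slopes, motion,
                                    module_values = list(Q = mv),
                                    n_perm = 300, seed = 16)
  fu <- attr(res, "module_followup")[["Q.older.1"]]
  expect_false(is.null(fu))
  expect_lt(fu$p_fwe[2], 0.05)
  expect_true(all(fu$p_fwe[-2] > 0.05))
})
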