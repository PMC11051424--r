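test_that("friedman_rank_test: degenerate, concordant and oracle cases", {
  m_id <- matrix(rep(1:10, 4), 10, 4)
  r <- friedman_rank_test(m_id)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # perfect within-row concordance attains the maximum n * (k - 1)
  m_inc <- t(replicate(12, c(1, 2, 3, 4))) + matrix(rnorm(48, 0, 1e-6), 12)
  m_inc <- t(apply(m_inc, 1, sort))
  rc <- friedman_rank_test(m_inc)
  expect_equal(rc$statistic, 12 * 3, tolerance = 1e-9)

  # matches base R (independent implementation) on random matrices
  for (s in 1:20) {
    set.seed(s)
    m <- matrix(stats::rnorm(80), 20, 4)
    mine <- friedman_rank_test(m)
    ref <- stats::friedman.test(m)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    # and the textbook-formula oracle
    expect_equal(mine$statistic, oracle_friedman(m), tolerance = 1e-12)
  }
  # with ties
  set.seed(77)
  mt <- matrix(sample(1:3, 60, TRUE), 15, 4)
  expect_equal(friedman_rank_test(mt)$statistic,
               unname(stats::friedman.test(mt)$statistic), tolerance = 1e-12)

  expect_error(friedman_rank_test(matrix(rnorm(8), 2, 4)), "at least 5")
})

test_that("kruskal_wallis_test: oracle equality and degenerate cases", {
  for (s in 1:20) {
    set.seed(s + 40)
    g <- split(stats::rnorm(90), sample(1:3, 90, TRUE))
    mine <- kruskal_wallis_test(g)
    ref <- stats::kruskal.test(g)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$statistic, oracle_kruskal(g), tolerance = 1e-12)
  }
  # all values identical
  same <- list(rep(1, 10), rep(1, 8))
  r <- kruskal_wallis_test(same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # a single group duplicated: H = 0 up to rounding
  set.seed(3)
  x <- stats::rnorm(20)
  expect_lt(kruskal_wallis_test(list(x, x))$statistic, 1e-12)
  expect_error(kruskal_wallis_test(list(1:3)), "at least 2")
})

test_that("two-group Kruskal-Wallis equals the squared rank-sum z", {
  set.seed(11)
  a <- stats::rnorm(15); b <- stats::rnorm(20, 0.5)
  H <- kruskal_wallis_test(list(a, b))$statistic
  # standardized Wilcoxon rank-sum statistic, no continuity correction
  r <- rank(c(a, b))
  Ra <- sum(r[1:15])
  na <- 15; nb <- 20; N <- na + nb
  z <- (Ra - na * (N + 1) / 2) / sqrt(na * nb * (N + 1) / 12)
  expect_equal(H, z^2, tolerance = 1e-12)
})

test_that("dunn_posthoc matches hand computation and orders p-values", {
  # 3 groups x 2 observations, hand-checkable
  g <- list(a = c(1, 2), b = c(3, 4), c = c(5, 6))
  d <- dunn_posthoc(g, design = "unpaired")
  expect_equal(nrow(d), 3L)
  # pooled ranks 1..6, mean ranks 1.5, 3.5, 5.5; sigma = sqrt(3.5)
  expect_equal(d$z[1], (1.5 - 3.5) / sqrt(6 * 7 / 12 * (1 / 2 + 1 / 2)),
               tolerance = 1e-12)
  expect_equal(d$z, vapply(1:3, function(i) {
    oracle_dunn_z(g, c(1, 1, 2)[i], c(2, 3, 3)[i])
  }, 0), tolerance = 1e-12)
  expect_true(all(d$p_adj >= d$p_raw - 1e-15))
  expect_true(all(d$p_adj <= 1))

  # identical groups: all adjusted p = 1
  gi <- list(rep(1, 6), rep(1, 6), rep(1, 6))
  expect_true(all(dunn_posthoc(gi, design = "unpaired")$p_adj == 1))

  # paired design: 6 contrasts for 4 conditions, z of 0 for identical columns
  m <- matrix(stats::rnorm(40), 10, 4, dimnames = list(NULL, paste0("c", 1:4)))
  dp <- dunn_posthoc(m, design = "paired")
  expect_equal(nrow(dp), 6L)
  m2 <- cbind(m[, 1], m[, 1], m[, 3], m[, 4])
  dp2 <- dunn_posthoc(m2, design = "paired")
  expect_equal(dp2$z[1], 0)
})

test_that("cohens_d_bootstrap: nulls, known effects, antisymmetry", {
  set.seed(2)
  x <- stats::rnorm(57)
  same <- cohens_d_bootstrap(x, x, paired = FALSE, n_boot = 2000, seed = 1)
  expect_lt(abs(same$mean_d), 0.1)
  expect_lt(same$ci[1], 0)
  expect_gt(same$ci[2], 0)
  # paired with identical samples: zero-variance differences -> missing
  expect_true(is.na(cohens_d_bootstrap(x, x, paired = TRUE)$mean_d))

  # known unpaired effect of 1 pooled SD, n = 57, 20 seeds
  ds <- vapply(1:20, function(s) {
    set.seed(s)
    a <- stats::rnorm(57, 1); b <- stats::rnorm(57, 0)
    cohens_d_bootstrap(a, b, paired = FALSE, n_boot = 500, seed = s)$mean_d
  }, 0)
  expect_gt(mean(ds), 0.8)
  expect_lt(mean(ds), 1.2)

  # paired antisymmetry is exact under the same seed
  set.seed(9)
  a <- stats::rnorm(30, 0.3); b <- stats::rnorm(30)
  f <- cohens_d_bootstrap(a, b, paired = TRUE, n_boot = 1000, seed = 7)
  r <- cohens_d_bootstrap(b, a, paired = TRUE, n_boot = 1000, seed = 7)
  expect_equal(f$mean_d, -r$mean_d, tolerance = 1e-12)
  expect_equal(f$ci, -rev(r$ci), tolerance = 1e-12)

  # reproducibility
  expect_identical(cohens_d_bootstrap(a, b, n_boot = 200, seed = 3),
                   cohens_d_bootstrap(a, b, n_boot = 200, seed = 3))
})

test_that("null calibration of the omnibus tests at the study group sizes", {
  # unpaired: the day-wise morphology group sizes, 1000 null replicates
  set.seed(123)
  rej_kw <- mean(vapply(1:1000, function(i) {
    g <- lapply(c(8, 60, 60, 56, 53), stats::rnorm)
    kruskal_wallis_test(g)$p_value < 0.05
  }, logical(1)))
  expect_gt(rej_kw, 0.025)
  expect_lt(rej_kw, 0.075)

  # paired: 57 x 4 null matrices, 1000 replicates
  set.seed(321)
  rej_fr <- mean(vapply(1:1000, function(i) {
    friedman_rank_test(matrix(stats::rnorm(57 * 4), 57, 4))$p_value < 0.05
  }, logical(1)))
  expect_gt(rej_fr, 0.025)
  expect_lt(rej_fr, 0.075)
})

test_that("run_paired_hrv_analysis applies design rules on feature tables", {
  # synthetic feature table: 20 participants, days 1-4 (baseline = day 4)
  set.seed(6)
  tbl <- expand.grid(participant_id = sprintf("P%02d", 1:20), day = 1:4,
                     stringsAsFactors = FALSE)
  tbl$hr <- stats::rnorm(nrow(tbl), 80, 5) + ifelse(tbl$day == 1, 10, 0)
  tbl$flat <- 1
  res <- run_paired_hrv_analysis(tbl, features = c("hr", "flat"),
                                 n_boot = 200, seed = 2)
  expect_equal(nrow(res$omnibus), 2L)
  expect_equal(nrow(res$pairwise), 12L)
  om_flat <- res$omnibus[res$omnibus$feature == "flat", ]
  expect_equal(om_flat$p_value, 1)
  om_hr <- res$omnibus[res$omnibus$feature == "hr", ]
  expect_lt(om_hr$p_value, 0.01)
  pw <- res$pairwise
  expect_true(all(pw$p_adj >= pw$p_raw - 1e-15, na.rm = TRUE))
  d1 <- pw[pw$feature == "hr" & pw$group_a == "baseline" &
             pw$group_b == "day1", ]
  expect_lt(d1$p_adj, 0.05)
  expect_lt(d1$mean_d, 0)  # baseline below the shifted day 1

  # fewer than 5 complete participants aborts
  small <- tbl[tbl$participant_id %in% sprintf("P%02d", 1:3), ]
  expect_error(run_paired_hrv_analysis(small, features = "hr"),
               "fewer than 5")
})

test_that("monotone power: larger shifts never reduce detection", {
  shifts <- c(0.3, 0.8, 1.6)
  rates <- vapply(shifts, function(sh) {
    mean(vapply(1:20, function(s) {
      set.seed(s * 100 + round(sh * 10))
      m <- matrix(stats::rnorm(57 * 4), 57, 4)
      m[, 2] <- m[, 2] + sh
      friedman_rank_test(m)$p_value < 0.05
    }, logical(1)))
  }, 0)
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.9)
})

test_that("run_unpaired_morph_analysis handles day groups and exclusions", {
  set.seed(8)
  tbl <- expand.grid(participant_id = sprintf("P%02d", 1:12), day = 0:4,
                     stringsAsFactors = FALSE)
  tbl$pwa <- stats::rnorm(nrow(tbl), 1, 0.1) - 0.05 * tbl$day
  res <- run_unpaired_morph_analysis(tbl, features = "pwa", n_boot = 200,
                                     seed = 4)
  expect_equal(nrow(res$pairwise), 10L)
  expect_true(all(res$pairwise$group_a != res$pairwise$group_b))
  # a day with n < 2 is excluded from the post hoc contrasts
  tbl2 <- tbl[!(tbl$day == 0 & tbl$participant_id != "P01"), ]
  res2 <- run_unpaired_morph_analysis(tbl2, features = "pwa", n_boot = 200,
                                      seed = 4)
  expect_equal(nrow(res2$pairwise), 6L)
})
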