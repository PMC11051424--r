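test_that("time_domain handles the enumerated cases and edge conditions", {
  td <- time_domain(rep(0.75, 400))
  expect_equal(td$hr, 80)
  expect_equal(td$sdnn, 0)
  expect_equal(td$rmssd, 0)
  expect_equal(td$pnn50, 0)

  alt <- rep(c(0.80, 0.86), 50)
  ta <- time_domain(alt)
  expect_equal(ta$rmssd, 60, tolerance = 1e-9)
  expect_equal(ta$pnn50, 100)

  expect_true(is.na(time_domain(0.8)$hr))
  expect_true(is.na(time_domain(c(0.8, 0.81))$rmssd))

  # rejected-gap pairs are excluded from successive differences
  ip <- c(0.8, 0.8, 1.4, 0.8, 0.8)  # middle value will be invalid
  pair_ok <- c(TRUE, FALSE, FALSE, TRUE)
  td2 <- time_domain(ip[-3], pair_ok = c(TRUE, FALSE, TRUE))
  expect_equal(td2$rmssd, 0)
})

test_that("time-domain and Poincare match brute-force oracles on random series", {
  for (s in 1:20) {
    set.seed(s)
    ip <- stats::rnorm(200 + s * 10, 0.8, 0.05)
    td <- time_domain(ip)
    or <- oracle_time_domain(ip)
    expect_equal(td$hr, or$hr, tolerance = 1e-9)
    expect_equal(td$sdnn, or$sdnn, tolerance = 1e-9)
    expect_equal(td$rmssd, or$rmssd, tolerance = 1e-9)
    expect_equal(td$pnn50, or$pnn50, tolerance = 1e-9)
    pc <- poincare(ip)
    op <- oracle_poincare(ip)
    expect_equal(pc$sd1, op$sd1, tolerance = 1e-9)
    expect_equal(pc$sd2, op$sd2, tolerance = 1e-9)
    expect_equal(pc$sd1_sd2, op$sd1_sd2, tolerance = 1e-9)
  }
})

test_that("Poincare identity and degenerate cases", {
  set.seed(4)
  ip <- stats::rnorm(300, 0.8, 0.04)
  pc <- poincare(ip)
  td <- time_domain(ip)
  expect_equal(pc$sd1^2 + pc$sd2^2, 2 * td$sdnn^2, tolerance = 1e-9)

  alt <- rep(c(0.80, 0.86), 100)
  pa <- poincare(alt)
  expect_equal(pa$sd1, sqrt(0.5) * 60, tolerance = 0.5)
  expect_lt(pa$sd2, pa$sd1 / 5)

  cst <- poincare(rep(0.8, 100))
  expect_equal(cst$sd1, 0)
  expect_equal(cst$sd2, 0)
  expect_true(is.na(cst$sd1_sd2))
})

test_that("frequency_domain recovers sinusoidal band power", {
  n <- 400
  tt <- cumsum(c(0, rep(0.75, n)))
  t_open <- tt[-(n + 1)]
  # 0.25 Hz, amplitude 25 ms -> power 312.5 ms^2, all in HF
  y_hf <- 0.75 + 0.025 * sin(2 * pi * 0.25 * t_open)
  fd <- frequency_domain(y_hf, tt)
  expect_gte(fd$hf, 0.9 * 0.5 * 25^2)
  expect_lte(abs(fd$hf - 0.5 * 25^2), 0.1 * 0.5 * 25^2)
  expect_lt(fd$lf, 0.1 * fd$hf)

  # mirror case at 0.10 Hz: LF dominant
  y_lf <- 0.75 + 0.025 * sin(2 * pi * 0.10 * t_open)
  fl <- frequency_domain(y_lf, tt)
  expect_gte(fl$lf, 0.9 * 0.5 * 25^2)
  expect_lt(fl$hf, 0.1 * fl$lf)

  # constant series: all powers below 1 ms^2
  fc <- frequency_domain(rep(0.75, n), tt)
  expect_lt(fc$tp, 1)
  expect_lt(fc$lf, 1)
  expect_lt(fc$hf, 1)
})

test_that("sample_entropy matches an O(n^2) brute-force oracle exactly", {
  for (s in 1:20) {
    set.seed(100 + s)
    x <- stats::rnorm(200, 0.8, 0.05)
    r <- 0.2 * stats::sd(x)
    expect_equal(sample_entropy(x), oracle_sampen(x, 2, r), tolerance = 1e-12)
  }
})

test_that("sample_entropy conventions: constant, periodic, short series", {
  expect_equal(sample_entropy(rep(0.8, 100)), 0)
  # strict 2-state alternation: every m-match extends, so A/B = 1
  expect_equal(sample_entropy(rep(c(0.8, 0.9), 50)), 0, tolerance = 1e-12)
  expect_true(is.na(sample_entropy(stats::rnorm(30))))
})

test_that("dfa_alpha1 calibrates on white noise and detects trends", {
  a <- vapply(1:50, function(s) {
    set.seed(s)
    dfa_alpha1(stats::rnorm(300, 0.8, 0.03))
  }, 0)
  expect_gt(mean(a), 0.4)
  expect_lt(mean(a), 0.6)

  set.seed(1)
  trend <- seq(0, 1, length.out = 300) + stats::rnorm(300, 0, 0.01)
  expect_gt(dfa_alpha1(trend), 1)

  # invariant to adding a constant
  set.seed(2)
  x <- stats::rnorm(300, 0.8, 0.03)
  expect_equal(dfa_alpha1(x), dfa_alpha1(x + 5), tolerance = 1e-12)

  expect_true(is.na(dfa_alpha1(stats::rnorm(50))))
})

test_that("feature scaling covariances hold", {
  set.seed(9)
  ip <- stats::rnorm(300, 0.8, 0.04)
  c_ <- 1.3
  td1 <- time_domain(ip); td2 <- time_domain(c_ * ip)
  expect_equal(td2$sdnn, c_ * td1$sdnn, tolerance = 1e-9)
  expect_equal(td2$rmssd, c_ * td1$rmssd, tolerance = 1e-9)
  expect_equal(td2$hr, td1$hr / c_, tolerance = 1e-9)
  pc1 <- poincare(ip); pc2 <- poincare(c_ * ip)
  expect_equal(pc2$sd1, c_ * pc1$sd1, tolerance = 1e-9)
  expect_equal(pc2$sd2, c_ * pc1$sd2, tolerance = 1e-9)
  expect_equal(dfa_alpha1(c_ * ip), dfa_alpha1(ip), tolerance = 1e-9)
  # band powers scale with c^2 (spectral estimator: 1% class tolerance)
  tt <- cumsum(c(0, ip))
  f1 <- frequency_domain(ip, tt)
  f2 <- frequency_domain(c_ * ip, tt)
  expect_equal(f2$hf, c_^2 * f1$hf, tolerance = 0.01)
  expect_equal(f2$lf, c_^2 * f1$lf, tolerance = 0.01)
})

test_that("hrv_features assembles the 13-column row", {
  fx <- modulated_recording(duration = 300, seed = 12)
  h <- hrv_features(ipi_series(fx$recording))
  expect_named(h, c("hr_bpm", "sdnn_ms", "rmssd_ms", "pnn50_pct", "tp_ms2",
                    "lf_ms2", "hf_ms2", "lf_hf", "sd1_ms", "sd2_ms",
                    "sd1_sd2", "sampen", "dfa_alpha1"))
  expect_true(all(is.finite(unlist(h))))
  expect_equal(h$hr_bpm, 80, tolerance = 2)
  expect_equal(h$lf_hf, h$lf_ms2 / h$hf_ms2, tolerance = 1e-9)
})
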