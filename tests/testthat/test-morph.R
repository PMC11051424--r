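test_that("segment_pulses excludes rejected intervals", {
  fx <- clean_recording(duration = 31)
  ip <- ipi_series(fx$recording)
  spans <- segment_pulses(fx$recording, ip)
  expect_equal(nrow(spans), sum(ip$valid_mask))
  # rejecting one interior interval drops exactly one span
  ip2 <- ip
  ip2$valid_mask[10] <- FALSE
  expect_equal(nrow(segment_pulses(fx$recording, ip2)), nrow(spans) - 1L)
  ip3 <- ip
  ip3$valid_mask[] <- FALSE
  expect_equal(nrow(segment_pulses(fx$recording, ip3)), 0L)
})

test_that("locate_fiducials matches the analytic template at 32 Hz", {
  orc <- template_oracle()
  p <- template_pulse(fs = 32)
  fid <- locate_fiducials(p, 32)
  expect_true(fid$complete)
  tol <- 2 / 32 + 1e-9  # two samples
  expect_lte(abs((fid$sp - 1) / 32 - orc$times$sp), tol)
  expect_lte(abs((fid$a1 - 1) / 32 - orc$times$a1), tol)
  expect_lte(abs((fid$b1 - 1) / 32 - orc$times$b1), tol)
  expect_lte(abs((fid$b2 - 1) / 32 - orc$times$b2), tol)

  # monotone ramp: no interior maximum, incomplete
  expect_false(locate_fiducials(seq(0, 1, length.out = 30), 32)$complete)
  # too short
  expect_false(locate_fiducials(c(0, 1, 0), 32)$complete)
})

test_that("triangle-pulse geometry features are exact", {
  fs <- 1000
  # unit-height triangle, base 1 s, apex at 0.3 s
  t <- seq(0, 1, by = 1 / fs)
  y <- ifelse(t <= 0.3, t / 0.3, (1 - t) / 0.7)
  n <- length(y)
  fid <- list(it = 1L, sp = which.max(y), ft = n, a1 = 50L, b1 = 400L,
              a2 = 20L, b2 = 310L, e2 = 500L, edv = 0,
              sm = y, d1 = ppghrv:::.cdiff(y, fs),
              d2 = ppghrv:::.cdiff(ppghrv:::.cdiff(y, fs), fs),
              complete = TRUE)
  f <- pulse_features(y, fid, fs)
  expect_equal(f$auc_total, 0.5, tolerance = 1e-3)
  expect_equal(f$auc1, 0.15, tolerance = 1e-3)
  expect_equal(f$auc2, 0.35, tolerance = 1e-3)
  expect_equal(f$spd, 0.3, tolerance = 1e-3)
  expect_equal(f$dpd, 0.7, tolerance = 1e-3)
  expect_equal(f$auc_total, f$auc1 + f$auc2, tolerance = 1e-12)
  expect_equal(f$pwd, f$spd + f$dpd, tolerance = 1e-12)

  # symmetric triangle: all width ratios 1, spd/pwd = 1/2, slope symmetry
  ys <- ifelse(t <= 0.5, t / 0.5, (1 - t) / 0.5)
  fids <- fid
  fids$sp <- which.max(ys)
  fids$sm <- ys
  fids$d1 <- ppghrv:::.cdiff(ys, fs)
  fids$d2 <- ppghrv:::.cdiff(fids$d1, fs)
  g <- pulse_features(ys, fids, fs)
  for (w in c("dw10_sw10", "dw25_sw25", "dw50_sw50", "dw60_sw60")) {
    expect_equal(g[[w]], 1, tolerance = 5e-3)
  }
  expect_equal(g$spd_pwd, 0.5, tolerance = 1e-3)
  expect_equal(g$slope_it_sp, -g$slope_sp_ft, tolerance = 1e-9)
})

test_that("all 35 features match the symbolic oracle on the analytic pulse", {
  tpl <- pulse_template()
  orc <- template_oracle(tpl)
  fs <- 1000
  p <- template_pulse(tpl, fs = fs)
  fid <- locate_fiducials(p, fs)
  expect_true(fid$complete)
  f <- pulse_features(p, fid, fs)
  # time-difference features join two fiducials, each located to within two
  # samples, so the discretisation band is two samples per endpoint
  four_samples <- 4 / fs
  for (nm in setdiff(names(f), "times")) {
    expected <- orc[[nm]]
    got <- f[[nm]]
    ok <- abs(got - expected) <= 2e-2 * max(abs(expected), 1e-8) ||
      abs(got - expected) <= four_samples + 2e-4
    expect_true(ok, info = sprintf("%s: got %.6g expected %.6g", nm, got,
                                   expected))
  }
})

test_that("morphology scaling and dilation covariances", {
  fs <- 250
  p <- template_pulse(fs = fs)
  fid <- locate_fiducials(p, fs)
  f1 <- pulse_features(p, fid, fs)
  # amplitude scaling by c
  c_ <- 0.5
  fid2 <- locate_fiducials(c_ * p, fs)
  f2 <- pulse_features(c_ * p, fid2, fs)
  for (nm in c("pwa", "auc_total", "auc1", "auc2", "msv", "sfv",
               "slope_it_sp", "slope_sp_ft", "b2_amplitude", "mean_v",
               "idr_v")) {
    expect_equal(f2[[nm]], c_ * f1[[nm]], tolerance = 1e-6, label = nm)
  }
  for (nm in c("pwd", "spd", "dpd", "t_a1", "dw10_sw10", "dw25_sw25",
               "dw50_sw50", "dw60_sw60", "spd_pwd", "angle_alpha",
               "angle_gamma", "b2_a2", "e2_a2", "pulsatility_index")) {
    expect_equal(f2[[nm]], f1[[nm]], tolerance = 1e-6, label = nm)
  }
  # time dilation: same samples, halved sampling rate = stretched by 2
  f3 <- pulse_features(p, locate_fiducials(p, fs / 2), fs / 2)
  for (nm in c("pwd", "spd", "dpd", "t_a1", "t_a1b1")) {
    expect_equal(f3[[nm]], 2 * f1[[nm]], tolerance = 1e-6, label = nm)
  }
  for (nm in c("spd_pwd", "t_a1_pwd", "dw10_sw10", "dw50_sw50", "pwa")) {
    expect_equal(f3[[nm]], f1[[nm]], tolerance = 1e-6, label = nm)
  }
})

test_that("aggregate_segment is a per-feature median", {
  p <- template_pulse(fs = 125)
  fid <- locate_fiducials(p, 125)
  one <- pulse_features(p, fid, 125)
  many <- one[rep(1, 50), ]
  agg <- aggregate_segment(many)
  expect_equal(agg$pwa, one$pwa)
  expect_equal(agg$n_pulses_used, 50L)
  # one outlier among 50 identical leaves the aggregate unchanged
  out <- one; out$pwa <- 100
  agg2 <- aggregate_segment(rbind(many, out))
  expect_equal(agg2$pwa, one$pwa)
  # mixed pulses equal the direct median
  mixed <- rbind(one, one * 2, one * 5)
  agg3 <- aggregate_segment(mixed)
  expect_equal(agg3$pwd, median(mixed$pwd))
  expect_error(aggregate_segment(one[0, ]), "no complete pulses")
})

test_that("ensemble_average preserves amplitude and handles single pulses", {
  p <- template_pulse(fs = 32)
  e1 <- ensemble_average(list(p, p, p), day_index = 1L)
  expect_equal(e1$n_pulses, 3L)
  expect_equal(max(e1$mean), max(p), tolerance = 0.02)
  e2 <- ensemble_average(list(p))
  expect_equal(e2$mean, ensemble_average(list(p, p))$mean, tolerance = 1e-12)
  # halved amplitude halves the ensemble peak
  eh <- ensemble_average(list(0.5 * p))
  expect_equal(max(eh$mean), 0.5 * max(e2$mean), tolerance = 1e-9)
  expect_error(ensemble_average(list()), "no pulses")
})

test_that("morph_features aggregates a clean segment", {
  fx <- clean_recording(duration = 60)
  ip <- ipi_series(fx$recording)
  mf <- morph_features(fx$recording, ip)
  expect_false(is.null(mf$features))
  expect_gt(mf$features$n_pulses_used, 70)
  expect_equal(mf$features$pwd, mf$features$spd + mf$features$dpd,
               tolerance = 1e-9)
  expect_equal(mf$features$auc_total, mf$features$auc1 + mf$features$auc2,
               tolerance = 1e-9)
})
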