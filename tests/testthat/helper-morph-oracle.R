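# analytic fine-grid oracle for the two-lobe template: every feature computed
# from the closed-form signal and derivatives at dt = 1e-4 s
template_oracle <- function(tpl = pulse_template(), ipi = 0.75) {
  dt <- 1e-4
  tau <- seq(0, ipi, by = dt)
  y <- eval_pulse(tpl, tau)
  v <- eval_pulse(tpl, tau, 1)
  a <- eval_pulse(tpl, tau, 2)
  n <- length(tau)
  sp <- which.max(y)
  it <- 1L; ft <- n
  pwa <- y[sp] - y[it]
  pwd <- tau[ft] - tau[it]
  spd <- tau[sp]; dpd <- pwd - spd
  a1 <- which.max(v[1:sp])
  # first local min of v after a1
  b1 <- a1 + which(v[(a1 + 1):(n - 1)] < v[a1:(n - 2)] &
                     v[(a1 + 1):(n - 1)] <= v[(a1 + 2):n])[1]
  # first local max of a after onset
  a2 <- 1 + which(a[2:(n - 1)] >= a[1:(n - 2)] & a[2:(n - 1)] > a[3:n])[1]
  hi <- min(n, sp + round(0.25 * (n - 1)))
  b2 <- a2 + which.min(a[(a2 + 1):hi])
  hi_e <- round(0.8 * (n - 1)) + 1
  emax <- which(a[2:(n - 1)] >= a[1:(n - 2)] & a[2:(n - 1)] > a[3:n]) + 1
  emax <- emax[emax > b2 & emax <= hi_e]
  e2 <- emax[which.max(a[emax])]
  base <- y[it] + (y[ft] - y[it]) * (tau - tau[it]) / pwd
  z <- y - base
  trap <- function(i1, i2) sum((z[i1:(i2 - 1)] + z[(i1 + 1):i2]) / 2) * dt
  width_ratio <- function(frac) {
    lev <- y[it] + frac * pwa
    cs <- which(y[1:(sp - 1)] < lev & y[2:sp] >= lev)[1]
    cd <- sp - 1 + which(y[sp:(n - 1)] >= lev & y[(sp + 1):n] < lev)[1]
    ((cd - sp) * dt) / ((sp - cs) * dt)
  }
  list(pwa = pwa, b2_amplitude = abs(a[b2]), pwd = pwd, spd = spd, dpd = dpd,
       t_a1 = tau[a1], t_a1b1 = tau[b1] - tau[a1], t_a2b2 = tau[b2] - tau[a2],
       t_b2e2 = tau[e2] - tau[b2],
       auc_total = trap(1, n), auc1 = trap(1, sp), auc2 = trap(sp, n),
       mean_v = mean(v), idr_v = unname(diff(quantile(v, c(0.1, 0.9)))),
       mean_acc = mean(a), msv = v[a1], sfv = v[1],
       dw10_sw10 = width_ratio(0.10), dw25_sw25 = width_ratio(0.25),
       dw50_sw50 = width_ratio(0.50), dw60_sw60 = width_ratio(0.60),
       t_s_pwd = (tau[sp] - tau[a1]) / pwd, t_a1_pwd = tau[a1] / pwd,
       t_a1b1_pwd = (tau[b1] - tau[a1]) / pwd,
       t_a2b2_pwd = (tau[b2] - tau[a2]) / pwd,
       t_b2e2_pwd = (tau[e2] - tau[b2]) / pwd,
       b2_a2 = abs(a[b2]) / a[a2], e2_a2 = a[e2] / a[a2],
       spd_pwd = spd / pwd, sp_spd = y[sp] / spd,
       pulsatility_index = (v[a1] - v[n]) / mean(v),
       slope_it_sp = (y[sp] - y[it]) / spd,
       slope_sp_ft = (y[ft] - y[sp]) / dpd,
       angle_alpha = atan2((y[sp] - y[it]) / pwa, spd) * 180 / pi,
       angle_gamma = atan2((y[ft] - y[sp]) / pwa, dpd) * 180 / pi,
       times = list(sp = tau[sp], a1 = tau[a1], b1 = tau[b1], a2 = tau[a2],
                    b2 = tau[b2], e2 = tau[e2]))
}

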