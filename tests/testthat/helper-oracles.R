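# Independent brute-force oracles. These deliberately re-derive every quantity
# from its definition with naive loops, sharing no code with the package.

oracle_time_domain <- function(ipis_s) {
  ms <- ipis_s * 1000
  n <- length(ms)
  d <- numeric(n - 1)
  for (i in 1:(n - 1)) d[i] <- ms[i + 1] - ms[i]
  list(hr = 60 / (sum(ipis_s) / n),
       sdnn = sqrt(sum((ms - mean(ms))^2) / (n - 1)),
       rmssd = sqrt(sum(d^2) / (n - 1)),
       pnn50 = 100 * sum(abs(d) > 50) / (n - 1))
}

oracle_poincare <- function(ipis_s) {
  ms <- ipis_s * 1000
  d <- diff(ms)
  vd <- sum((d - mean(d))^2) / (length(d) - 1)
  sdnn2 <- sum((ms - mean(ms))^2) / (length(ms) - 1)
  sd1 <- sqrt(vd / 2)
  sd2 <- sqrt(max(2 * sdnn2 - vd / 2, 0))
  list(sd1 = sd1, sd2 = sd2, sd1_sd2 = sd1 / sd2)
}

# O(n^2) double-loop sample entropy, Chebyshev distance, self-matches excluded
oracle_sampen <- function(x, m = 2, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      dmax <- 0
      for (k in 0:(m - 1)) dmax <- max(dmax, abs(x[i + k] - x[j + k]))
      if (dmax <= r) {
        B <- B + 1
        if (max(dmax, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
      }
    }
  }
  -log(A / B)
}

# textbook Friedman chi-square with tie correction (Conover formulation)
oracle_friedman <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  R <- matrix(0, n, k)
  for (i in 1:n) R[i, ] <- rank(mat[i, ])
  Rj <- colSums(R)
  correction <- 0
  for (i in 1:n) {
    tb <- table(R[i, ])
    correction <- correction + sum(tb^3 - tb)
  }
  num <- 12 * sum((Rj - n * (k + 1) / 2)^2)
  den <- n * k * (k + 1) - correction / (k - 1)
  num / den
}

# textbook Kruskal-Wallis H with tie correction
oracle_kruskal <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  N <- length(x)
  r <- rank(x)
  H <- 0
  for (j in seq_along(groups)) {
    H <- H + sum(r[g == j])^2 / sum(g == j)
  }
  H <- 12 / (N * (N + 1)) * H - 3 * (N + 1)
  tb <- table(x)
  H / (1 - sum(tb^3 - tb) / (N^3 - N))
}

# Dunn z for one unpaired pair (a, b) inside the pooled data, textbook formula
oracle_dunn_z <- function(groups, ia, ib) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  N <- length(x)
  r <- rank(x)
  tb <- table(x)
  sigma2 <- (N * (N + 1) / 12 - sum(tb^3 - tb) / (12 * (N - 1))) *
    (1 / sum(g == ia) + 1 / sum(g == ib))
  (mean(r[g == ia]) - mean(r[g == ib])) / sqrt(sigma2)
}
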