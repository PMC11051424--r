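#' Friedman rank test for a paired participants-by-conditions matrix
#'
#' Tie-corrected chi-square statistic on within-row mid-ranks with
#' `ncol(mat) - 1` degrees of freedom. Rows with missing cells are dropped
#' (and logged) before testing.
#'
#' @param mat numeric matrix, participants in rows, conditions in columns.
#' @return list with `statistic`, `df`, `p_value`, `n` (complete rows).
#' @export
friedman_rank_test <- function(mat) {
  mat <- as.matrix(mat)
  complete <- stats::complete.cases(mat)
  if (any(!complete)) {
    ppg_log(sprintf("friedman: dropping %d incomplete row(s)", sum(!complete)))
    mat <- mat[complete, , drop = FALSE]
  }
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 5L) stop("need at least 5 complete participants", call. = FALSE)
  r <- t(apply(mat, 1L, rank))
  ties <- apply(r, 1L, function(row) {
    tb <- table(row)
    sum(tb^3 - tb)
  })
  num <- 12 * sum((colSums(r) - n * (k + 1) / 2)^2)
  den <- n * k * (k + 1) - sum(ties) / (k - 1)
  if (den <= 0) {
    return(list(statistic = 0, df = k - 1L, p_value = 1, n = n))
  }
  stat <- num / den
  list(statistic = stat, df = k - 1L,
       p_value = stats::pchisq(stat, k - 1L, lower.tail = FALSE), n = n)
}

#' Kruskal-Wallis test for unpaired groups
#'
#' Tie-corrected H statistic on pooled mid-ranks, `length(groups) - 1`
#' degrees of freedom.
#'
#' @param groups list of numeric vectors (missing values dropped per group).
#' @return list with `statistic`, `df`, `p_value`, `n_per_group`.
#' @export
kruskal_wallis_test <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- groups[vapply(groups, length, integer(1)) > 0L]
  g <- length(groups)
  if (g < 2L) stop("need at least 2 non-empty groups", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  n <- vapply(groups, length, integer(1))
  N <- length(x)
  r <- rank(x)
  grp <- rep(seq_len(g), n)
  Rj <- tapply(r, grp, sum)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / n) - 3 * (N + 1)
  tb <- table(x)
  tie_corr <- 1 - sum(tb^3 - tb) / (N^3 - N)
  if (tie_corr <= 0) {
    return(list(statistic = 0, df = g - 1L, p_value = 1, n_per_group = n))
  }
  H <- H / tie_corr
  list(statistic = H, df = g - 1L,
       p_value = stats::pchisq(H, g - 1L, lower.tail = FALSE),
       n_per_group = n)
}

#' Dunn's post hoc pairwise contrasts with Bonferroni correction
#'
#' For the unpaired design, z-statistics on pooled mid-ranks with tie
#' correction (classic Dunn after Kruskal-Wallis). For the paired design,
#' z-statistics on mean within-row ranks with standard error
#' `sqrt(k (k + 1) / (6 n))` (Dunn after Friedman). Two-sided p-values,
#' Bonferroni-multiplied by the number of contrasts within the feature.
#'
#' @param data for `design = "unpaired"` a list of numeric vectors, for
#'   `design = "paired"` a complete numeric matrix (rows = participants).
#' @param design `"paired"` or `"unpaired"`.
#' @param m_comparisons Bonferroni multiplier; defaults to the number of
#'   pairwise contrasts actually formed.
#' @return data frame: group_a, group_b, n_a, n_b, z, p_raw, p_adj.
#' @export
dunn_posthoc <- function(data, design = c("paired", "unpaired"),
                         m_comparisons = NULL) {
  design <- match.arg(design)
  if (design == "unpaired") {
    groups <- lapply(data, function(g) g[!is.na(g)])
    labs <- if (!is.null(names(groups))) names(groups)
            else as.character(seq_along(groups))
    keep <- vapply(groups, length, integer(1)) >= 2L
    if (any(!keep)) {
      ppg_log(sprintf("dunn: skipping group(s) with n < 2: %s",
                      paste(labs[!keep], collapse = ", ")))
    }
    groups <- groups[keep]; labs <- labs[keep]
    g <- length(groups)
    n <- vapply(groups, length, integer(1))
    N <- sum(n)
    x <- unlist(groups, use.names = FALSE)
    r <- rank(x)
    grp <- rep(seq_len(g), n)
    Rbar <- tapply(r, grp, mean)
    tb <- table(x)
    tie_term <- sum(tb^3 - tb) / (12 * (N - 1))
    pairs <- utils::combn(g, 2)
    res <- data.frame(
      group_a = labs[pairs[1, ]], group_b = labs[pairs[2, ]],
      n_a = n[pairs[1, ]], n_b = n[pairs[2, ]])
    sigma2 <- (N * (N + 1) / 12 - tie_term) *
      (1 / n[pairs[1, ]] + 1 / n[pairs[2, ]])
    res$z <- as.numeric(ifelse(sigma2 > 0,
                               (Rbar[pairs[1, ]] - Rbar[pairs[2, ]]) /
                                 sqrt(pmax(sigma2, 1e-300)),
                               0))
  } else {
    mat <- as.matrix(data)
    mat <- mat[stats::complete.cases(mat), , drop = FALSE]
    n <- nrow(mat)
    k <- ncol(mat)
    labs <- if (!is.null(colnames(mat))) colnames(mat)
            else as.character(seq_len(k))
    r <- t(apply(mat, 1L, rank))
    Rbar <- colMeans(r)
    pairs <- utils::combn(k, 2)
    res <- data.frame(
      group_a = labs[pairs[1, ]], group_b = labs[pairs[2, ]],
      n_a = n, n_b = n)
    res$z <- as.numeric((Rbar[pairs[1, ]] - Rbar[pairs[2, ]]) /
                          sqrt(k * (k + 1) / (6 * n)))
  }
  m <- if (is.null(m_comparisons)) nrow(res) else m_comparisons
  res$p_raw <- 2 * stats::pnorm(-abs(res$z))
  res$p_adj <- pmin(1, res$p_raw * m)
  rownames(res) <- NULL
  res
}

#' Bootstrap Cohen's d with percentile confidence interval
#'
#' Each bootstrap replicate resamples participants with replacement and
#' computes Cohen's d: `mean(difference) / sd(difference)` for paired samples
#' (aligned by participant), or the mean difference over the pooled standard
#' deviation for unpaired samples. Reports the mean of the replicates and the
#' 2.5/97.5 percentile interval.
#'
#' @param a,b numeric samples (aligned when `paired = TRUE`; `NA` pairs or
#'   values dropped).
#' @param paired logical.
#' @param n_boot number of bootstrap iterations (10,000 by default).
#' @param seed RNG seed; results are reproducible under a fixed seed.
#' @return list with `d` (point estimate), `mean_d`, `ci` (length 2) and
#'   `n`; all `NA` when the relevant standard deviation is zero or a sample
#'   is smaller than 5.
#' @export
cohens_d_bootstrap <- function(a, b, paired = TRUE, n_boot = 10000L,
                               seed = 1L) {
  empty <- list(d = NA_real_, mean_d = NA_real_, ci = c(NA_real_, NA_real_),
                n = NA_integer_)
  if (paired) {
    ok <- !is.na(a) & !is.na(b)
    d0 <- a[ok] - b[ok]
    n <- length(d0)
    if (n < 5L || stats::sd(d0) == 0) return(empty)
    reps <- with_seed(seed, {
      idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
      dm <- matrix(d0[idx], nrow = n)
      mu <- colMeans(dm)
      ss <- sqrt((colSums(dm^2) - n * mu^2) / (n - 1))
      mu / ss
    })
    point <- mean(d0) / stats::sd(d0)
  } else {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    na <- length(a); nb <- length(b)
    sp0 <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
                  (na + nb - 2))
    if (na < 5L || nb < 5L || sp0 == 0) return(empty)
    reps <- with_seed(seed, {
      ia <- matrix(sample.int(na, na * n_boot, replace = TRUE), nrow = na)
      ib <- matrix(sample.int(nb, nb * n_boot, replace = TRUE), nrow = nb)
      am <- matrix(a[ia], nrow = na)
      bm <- matrix(b[ib], nrow = nb)
      mua <- colMeans(am); mub <- colMeans(bm)
      va <- (colSums(am^2) - na * mua^2) / (na - 1)
      vb <- (colSums(bm^2) - nb * mub^2) / (nb - 1)
      sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
      (mua - mub) / sp
    })
    point <- (mean(a) - mean(b)) / sp0
    n <- c(na, nb)
  }
  reps <- reps[is.finite(reps)]
  if (length(reps) == 0L) return(empty)
  list(d = point, mean_d = mean(reps),
       ci = unname(stats::quantile(reps, c(0.025, 0.975))), n = n)
}

# internal: tidy pairwise results for one feature
.pairwise_with_d <- function(dunn, get_samples, paired, n_boot, seed) {
  out <- dunn
  out$mean_d <- NA_real_
  out$ci_low <- NA_real_
  out$ci_high <- NA_real_
  for (i in seq_len(nrow(out))) {
    s <- get_samples(out$group_a[i], out$group_b[i])
    bs <- cohens_d_bootstrap(s$a, s$b, paired = paired, n_boot = n_boot,
                             seed = derive_seed(seed, out$group_a[i],
                                                out$group_b[i]))
    out$mean_d[i] <- bs$mean_d
    out$ci_low[i] <- bs$ci[1]
    out$ci_high[i] <- bs$ci[2]
  }
  out
}

#' Paired four-condition HRV comparison
#'
#' Implements the within-subject design: for each feature, participants
#' complete in \{baseline, day 1, day 2, day 3\} enter a Friedman omnibus
#' test, all 6 Dunn contrasts with Bonferroni correction, and a paired
#' bootstrap Cohen's d per contrast. The baseline column is each
#' participant's day-0 measurement when available, else day 4.
#'
#' @param tbl cohort feature table: data frame with `participant_id`, `day`
#'   and one column per feature.
#' @param features character vector of feature columns to analyse; defaults
#'   to all non-id columns.
#' @param n_boot bootstrap iterations for the effect sizes.
#' @param seed RNG seed for the bootstrap.
#' @return list with `omnibus` (feature, statistic, df, p_value, n) and
#'   `pairwise` (feature, group_a, group_b, n, z, p_raw, p_adj, mean_d,
#'   ci_low, ci_high) data frames, conditions ordered baseline, day1, day2,
#'   day3.
#' @export
run_paired_hrv_analysis <- function(tbl, features = NULL, n_boot = 10000L,
                                    seed = 1L) {
  stopifnot(all(c("participant_id", "day") %in% names(tbl)))
  if (is.null(features)) {
    features <- setdiff(names(tbl), c("participant_id", "day"))
  }
  # baseline day per participant from the days present in the table
  parts <- unique(tbl$participant_id)
  cond_of <- function(pid) {
    days <- tbl$day[tbl$participant_id == pid]
    assign_baseline(days)$baseline_day
  }
  base_day <- vapply(parts, cond_of, integer(1))
  conds <- c("baseline", "day1", "day2", "day3")

  omnibus <- list()
  pairwise <- list()
  for (f in features) {
    mat <- matrix(NA_real_, nrow = length(parts), ncol = 4,
                  dimnames = list(parts, conds))
    for (i in seq_along(parts)) {
      sub <- tbl[tbl$participant_id == parts[i], ]
      if (!is.na(base_day[i])) {
        v <- sub[[f]][sub$day == base_day[i]]
        if (length(v) == 1L) mat[i, "baseline"] <- v
      }
      for (d in 1:3) {
        v <- sub[[f]][sub$day == d]
        if (length(v) == 1L) mat[i, d + 1L] <- v
      }
    }
    mat <- mat[stats::complete.cases(mat), , drop = FALSE]
    if (nrow(mat) < 5L) {
      stop(sprintf("feature %s: fewer than 5 complete participants", f),
           call. = FALSE)
    }
    om <- friedman_rank_test(mat)
    omnibus[[f]] <- data.frame(feature = f, statistic = om$statistic,
                               df = om$df, p_value = om$p_value, n = om$n)
    dn <- dunn_posthoc(mat, design = "paired")
    pw <- .pairwise_with_d(
      dn,
      get_samples = function(a, b) list(a = mat[, a], b = mat[, b]),
      paired = TRUE, n_boot = n_boot, seed = derive_seed(seed, f))
    pw <- cbind(feature = f, pw)
    pairwise[[f]] <- pw
  }
  list(omnibus = do.call(rbind, c(omnibus, list(make.row.names = FALSE))),
       pairwise = do.call(rbind, c(pairwise, list(make.row.names = FALSE))))
}

#' Unpaired five-day morphology comparison
#'
#' For each feature, the per-day samples (days 0-4, unpaired: day 0 and day 4
#' are *not* pooled into a baseline) enter a Kruskal-Wallis omnibus test, all
#' 10 Dunn contrasts with Bonferroni correction, and an unpaired bootstrap
#' Cohen's d per contrast. Days with fewer than 2 observations are excluded
#' from the post hoc contrasts.
#'
#' @inheritParams run_paired_hrv_analysis
#' @return list with `omnibus` and `pairwise` data frames as in
#'   [run_paired_hrv_analysis()], groups labelled `day0` .. `day4`.
#' @export
run_unpaired_morph_analysis <- function(tbl, features = NULL,
                                        n_boot = 10000L, seed = 1L) {
  stopifnot(all(c("participant_id", "day") %in% names(tbl)))
  if (is.null(features)) {
    features <- setdiff(names(tbl), c("participant_id", "day", "n_pulses_used"))
  }
  days <- sort(unique(tbl$day))
  omnibus <- list()
  pairwise <- list()
  for (f in features) {
    groups <- lapply(days, function(d) tbl[[f]][tbl$day == d])
    names(groups) <- paste0("day", days)
    om <- kruskal_wallis_test(groups)
    omnibus[[f]] <- data.frame(feature = f, statistic = om$statistic,
                               df = om$df, p_value = om$p_value,
                               n = sum(om$n_per_group))
    dn <- dunn_posthoc(groups, design = "unpaired")
    pw <- .pairwise_with_d(
      dn,
      get_samples = function(a, b) list(a = groups[[a]], b = groups[[b]]),
      paired = FALSE, n_boot = n_boot, seed = derive_seed(seed, f))
    pw <- cbind(feature = f, pw)
    pairwise[[f]] <- pw
  }
  list(omnibus = do.call(rbind, c(omnibus, list(make.row.names = FALSE))),
       pairwise = do.call(rbind, c(pairwise, list(make.row.names = FALSE))))
}
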