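#' Two-way mixed-effects absolute-agreement intraclass correlation
#'
#' Computes the agreement ICC of an n-subjects x k-trials matrix from the
#' two-way ANOVA decomposition (between-subjects mean square `MSR`,
#' between-trials `MSC`, residual `MSE`):
#' single-measurement form
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` and average-of-k
#' form `(MSR - MSE) / (MSR + (MSC - MSE)/n)`, with 95% confidence
#' intervals by the F-based construction for agreement ICCs (McGraw & Wong).
#' Absolute agreement penalizes systematic trial-to-trial shifts, unlike the
#' consistency forms. Rows with missing trials are dropped and counted.
#'
#' @param mat Numeric matrix (or data frame), subjects in rows, repeated
#'   trials in columns. Needs n >= 3 complete rows and k >= 2 columns.
#' @param form `"single"` (rates one measurement) or `"average"` (rates the
#'   mean of the k trials).
#' @param conf Confidence level. Default 0.95.
#' @return A list of class `icc_result`: `estimate`, `lower`, `upper`,
#'   `form`, `model` (`"two-way mixed, absolute agreement"`), `n`, `k`,
#'   `n_dropped`, `label` (see [classify_icc()]), and the mean squares.
#' @export
icc_agreement <- function(mat, form = c("single", "average"), conf = 0.95) {
  form <- match.arg(form)
  mat <- as.matrix(mat)
  complete <- stats::complete.cases(mat)
  n_dropped <- sum(!complete)
  mat <- mat[complete, , drop = FALSE]
  n <- nrow(mat)
  k <- ncol(mat)
  if (k < 2L || n < 3L) {
    stop("insufficient data: need >= 3 complete subjects and >= 2 trials",
         call. = FALSE)
  }
  g <- mean(mat)
  if (sum((mat - g)^2) == 0) {
    stop("undefined ICC: zero total variance", call. = FALSE)
  }
  rm_ <- rowMeans(mat)
  cm <- colMeans(mat)
  SSR <- k * sum((rm_ - g)^2)
  SSC <- n * sum((cm - g)^2)
  SSE <- sum((mat - g)^2) - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))

  est1 <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  estk <- (MSR - MSE) / (MSR + (MSC - MSE) / n)

  alpha <- 1 - conf
  ci1 <- c(NA_real_, NA_real_)
  if (est1 < 1 && MSE > 0) {
    a <- k * est1 / (n * (1 - est1))
    b <- 1 + k * est1 * (n - 1) / (n * (1 - est1))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    up <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    ci1 <- c(lo, up)
  } else if (est1 >= 1) {
    ci1 <- c(1, 1)  # degenerate: perfect agreement
  }
  to_k <- function(r) k * r / (1 + (k - 1) * r)
  est <- if (form == "single") est1 else estk
  ci <- if (form == "single") ci1 else to_k(ci1)

  structure(list(estimate = est, lower = ci[1L], upper = ci[2L],
                 form = form, model = "two-way mixed, absolute agreement",
                 n = n, k = k, n_dropped = n_dropped, conf = conf,
                 label = classify_icc(est),
                 MSR = MSR, MSC = MSC, MSE = MSE),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "ICC(A,%s) = %.3f, %d%% CI [%.3f, %.3f] (%s; n = %d, k = %d%s)\n",
    if (x$form == "single") "1" else "k", x$estimate, round(100 * x$conf),
    x$lower, x$upper, x$label, x$n, x$k,
    if (x$n_dropped) sprintf(", %d dropped", x$n_dropped) else ""))
  invisible(x)
}

#' Classify an ICC estimate
#'
#' Reliability labels: poor below 0.5, moderate in [0.5, 0.75), good in
#' [0.75, 0.9), excellent at 0.9 and above. Boundaries are left-closed, so
#' an estimate of exactly 0.90 is labeled excellent.
#'
#' @param estimate Finite ICC estimate (vectorized).
#' @param cutoffs Strictly increasing cutoffs, default `c(0.5, 0.75, 0.9)`.
#' @return Character vector of labels.
#' @export
classify_icc <- function(estimate, cutoffs = c(0.5, 0.75, 0.9)) {
  stopifnot(all(diff(cutoffs) > 0), length(cutoffs) == 3L)
  labels <- c("poor", "moderate", "good", "excellent")
  labels[findInterval(estimate, cutoffs) + 1L]
}

#' Choose the omnibus test by a normality gate
#'
#' Applies a Shapiro-Wilk test to each condition column; if any column
#' departs from normality at the gate level, the Friedman test is used,
#' otherwise the repeated-measures ANOVA. A constant (degenerate) column is
#' treated as failing the gate.
#'
#' @param mat n x m matrix of values, conditions in columns (complete
#'   cases only).
#' @param gate_alpha Gate level for the per-column Shapiro-Wilk tests.
#'   Default 0.05.
#' @return A list with `test` (`"rm_anova"` or `"friedman"`) and
#'   `shapiro_p` (per-column p-values; `NA` for degenerate columns).
#' @export
choose_omnibus <- function(mat, gate_alpha = 0.05) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 5L) {
    stop("normality gate needs at least 5 subjects", call. = FALSE)
  }
  p <- apply(mat, 2L, function(col) {
    tryCatch(stats::shapiro.test(col)$p.value, error = function(e) NA_real_)
  })
  fail <- is.na(p) | p < gate_alpha
  list(test = if (any(fail)) "friedman" else "rm_anova", shapiro_p = p)
}

orthonormal_contrasts <- function(m) {
  C <- stats::contr.helmert(m)
  sweep(C, 2L, sqrt(colSums(C^2)), `/`)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subjects ANOVA of an n x m complete-case matrix (subjects x
#' conditions): F on (m-1, (n-1)(m-1)) degrees of freedom, partial eta
#' squared `SS_condition / (SS_condition + SS_error)`, Mauchly's sphericity
#' test, and the Greenhouse-Geisser corrected p-value (reported alongside;
#' flagged for use when the sphericity p is below 0.05).
#'
#' @param mat n x m numeric matrix, m >= 2 (sphericity is meaningful for
#'   m >= 3).
#' @return A list of class `omnibus_result` with `test = "rm_anova"`,
#'   `statistic` (F), `df`, `p`, `effect_size` (partial eta squared),
#'   `effect_size_name`, `mauchly_w`, `mauchly_p`, `gg_epsilon`, `gg_p`,
#'   `sphericity_violated`, `degenerate`, `cond_mean`, `cond_sd`, `n`.
#' @export
rm_anova <- function(mat) {
  mat <- as.matrix(mat)
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  n <- nrow(mat)
  m <- ncol(mat)
  stopifnot(n >= 2L, m >= 2L)
  g <- mean(mat)
  SSR <- m * sum((rowMeans(mat) - g)^2)
  SSC <- n * sum((colMeans(mat) - g)^2)
  SSE <- sum((mat - g)^2) - SSR - SSC
  df1 <- m - 1L
  df2 <- (n - 1L) * (m - 1L)
  MSC <- SSC / df1
  MSE <- SSE / df2
  degenerate <- MSE == 0
  F_stat <- if (degenerate) {
    if (MSC == 0) 0 else Inf
  } else MSC / MSE
  p <- if (degenerate) {
    if (MSC == 0) 1 else 0
  } else stats::pf(F_stat, df1, df2, lower.tail = FALSE)
  etap2 <- if (SSC + SSE == 0) 0 else SSC / (SSC + SSE)

  mauchly_w <- mauchly_p <- gg_eps <- gg_p <- NA_real_
  if (m >= 3L && !degenerate && n > m) {
    mt <- tryCatch(
      stats::mauchly.test(stats::lm(mat ~ 1), X = ~1),
      error = function(e) NULL)
    if (!is.null(mt)) {
      mauchly_w <- unname(mt$statistic)
      mauchly_p <- mt$p.value
    }
  }
  if (m >= 3L && !degenerate) {
    C <- orthonormal_contrasts(m)
    S <- t(C) %*% stats::cov(mat) %*% C
    gg_eps <- sum(diag(S))^2 / ((m - 1) * sum(S^2))
    gg_p <- stats::pf(F_stat, gg_eps * df1, gg_eps * df2, lower.tail = FALSE)
  }

  structure(list(
    test = "rm_anova", statistic = F_stat, df = c(df1, df2), p = p,
    effect_size = etap2, effect_size_name = "partial_eta_squared",
    mauchly_w = mauchly_w, mauchly_p = mauchly_p,
    gg_epsilon = gg_eps, gg_p = gg_p,
    sphericity_violated = isTRUE(mauchly_p < 0.05),
    degenerate = degenerate,
    cond_mean = colMeans(mat), cond_sd = apply(mat, 2L, stats::sd), n = n
  ), class = "omnibus_result")
}

#' Friedman test with Kendall's W
#'
#' Nonparametric repeated-measures omnibus: the Friedman rank-sum chi-square
#' (with average-rank tie correction, via [stats::friedman.test()]) and the
#' Kendall concordance effect size `W = chi^2 / (n (m - 1))`. A fully tied
#' matrix (zero rank variance in every row) yields chi-square 0, W 0, p 1.
#'
#' @param mat n x m numeric matrix, complete cases, m >= 2, n >= 2.
#' @return A list of class `omnibus_result` with `test = "friedman"`,
#'   `statistic` (chi-square), `df`, `p`, `effect_size` (Kendall W),
#'   `cond_mean`, `cond_sd`, `n`.
#' @export
friedman_rm <- function(mat) {
  mat <- as.matrix(mat)
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  n <- nrow(mat)
  m <- ncol(mat)
  if (n < 2L) stop("Friedman test needs at least 2 subjects", call. = FALSE)
  ft <- tryCatch(stats::friedman.test(mat), error = function(e) NULL)
  chisq <- if (is.null(ft) || !is.finite(ft$statistic)) 0 else
    unname(ft$statistic)
  df <- m - 1L
  p <- if (chisq == 0) 1 else unname(ft$p.value)
  structure(list(
    test = "friedman", statistic = chisq, df = df, p = p,
    effect_size = chisq / (n * (m - 1)), effect_size_name = "kendall_w",
    degenerate = is.null(ft) || !is.finite(ft$statistic),
    cond_mean = colMeans(mat), cond_sd = apply(mat, 2L, stats::sd), n = n
  ), class = "omnibus_result")
}

#' Normality-gated omnibus test
#'
#' Runs [choose_omnibus()] and dispatches to [rm_anova()] or
#' [friedman_rm()], recording the gate decision and per-column normality
#' p-values on the result.
#'
#' @inheritParams choose_omnibus
#' @return An `omnibus_result` with `shapiro_p` attached.
#' @export
omnibus_test <- function(mat, gate_alpha = 0.05) {
  choice <- choose_omnibus(mat, gate_alpha)
  res <- if (choice$test == "rm_anova") rm_anova(mat) else friedman_rm(mat)
  res$shapiro_p <- choice$shapiro_p
  res
}

#' @export
print.omnibus_result <- function(x, ...) {
  if (x$test == "rm_anova") {
    cat(sprintf("RM-ANOVA: F(%d, %d) = %.3f, p = %.4g, eta_p^2 = %.3f\n",
                x$df[1L], x$df[2L], x$statistic, x$p, x$effect_size))
    if (!is.na(x$mauchly_p)) {
      cat(sprintf("  Mauchly W = %.3f (p = %.3f); GG eps = %.3f, GG p = %.4g%s\n",
                  x$mauchly_w, x$mauchly_p, x$gg_epsilon, x$gg_p,
                  if (x$sphericity_violated) " [sphericity violated]" else ""))
    }
  } else {
    cat(sprintf("Friedman: chi^2(%d) = %.3f, p = %.4g, Kendall W = %.3f\n",
                x$df[1L], x$statistic, x$p, x$effect_size))
  }
  invisible(x)
}

#' Paired comparison of fast versus comfortable pace
#'
#' Paired t-test on differences `fast - comfortable`: t statistic on n-1
#' degrees of freedom, two-sided p, mean difference with SD and confidence
#' interval, Cohen's d, and a significance flag at the Bonferroni-corrected
#' level. Cohen's d is the paired-design `d_z = mean(d) / SD(d)` by
#' default; an average-variance pooled d (`mean(d)` over the pooled SD of
#' the two conditions) is available via `effect = "pooled"`.
#'
#' @param comfortable,fast Paired numeric vectors (same length, matched by
#'   subject). Pairs with any missing value are dropped; n >= 3 required.
#' @param alpha Corrected per-test significance level. Default 0.004.
#' @param effect `"dz"` (default) or `"pooled"`.
#' @param conf Confidence level for the mean-difference CI. Default 0.95.
#' @return A list of class `paired_result`: `t`, `df`, `p`, `mean_diff`,
#'   `sd_diff`, `ci`, `cohens_d`, `effect`, `n`, `significant`, `alpha`,
#'   `degenerate`, plus per-condition means/SDs.
#' @export
paired_comparison <- function(comfortable, fast, alpha = 0.004,
                              effect = c("dz", "pooled"), conf = 0.95) {
  effect <- match.arg(effect)
  stopifnot(length(comfortable) == length(fast))
  ok <- stats::complete.cases(comfortable, fast)
  comfortable <- comfortable[ok]
  fast <- fast[ok]
  n <- length(fast)
  if (n < 3L) stop("paired comparison needs at least 3 complete pairs",
                   call. = FALSE)
  d <- fast - comfortable
  md <- mean(d)
  sdd <- stats::sd(d)
  degenerate <- sdd == 0
  if (degenerate) {
    t_stat <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
    ci <- c(md, md)
    dz <- if (md == 0) 0 else sign(md) * Inf
  } else {
    tt <- stats::t.test(fast, comfortable, paired = TRUE, conf.level = conf)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
    ci <- as.numeric(tt$conf.int)
    dz <- md / sdd
  }
  cd <- if (effect == "dz") dz else {
    sp <- sqrt((stats::var(comfortable) + stats::var(fast)) / 2)
    if (sp == 0) dz else md / sp
  }
  structure(list(
    t = t_stat, df = n - 1L, p = p, mean_diff = md, sd_diff = sdd,
    ci = ci, cohens_d = cd, effect = effect, n = n,
    significant = isTRUE(p < alpha), alpha = alpha, degenerate = degenerate,
    comfortable_mean = mean(comfortable), comfortable_sd = stats::sd(comfortable),
    fast_mean = mean(fast), fast_sd = stats::sd(fast)
  ), class = "paired_result")
}

#' @export
print.paired_result <- function(x, ...) {
  cat(sprintf(
    "paired t(%d) = %.2f, p = %.4g; mean diff %.2f (SD %.2f), %s CI [%.2f, %.2f], d = %.2f%s\n",
    x$df, x$t, x$p, x$mean_diff, x$sd_diff, "95%", x$ci[1L], x$ci[2L],
    x$cohens_d, if (x$significant) " *" else ""))
  invisible(x)
}

#' Paired t statistic from printed summaries
#'
#' Recovers the paired t statistic, degrees of freedom and mean-difference
#' confidence interval from the summary statistics a report prints (mean
#' difference, its SD, and n): `t = mean_diff / (sd_diff / sqrt(n))`.
#' Useful for verifying published paired-comparison tables.
#'
#' @param mean_diff Mean of the paired differences.
#' @param sd_diff Standard deviation of the paired differences (> 0).
#' @param n Number of pairs (>= 2).
#' @param conf Confidence level. Default 0.95.
#' @return A list with `t`, `df`, `ci`.
#' @export
paired_t_from_summary <- function(mean_diff, sd_diff, n, conf = 0.95) {
  if (sd_diff <= 0) stop("sd_diff must be > 0", call. = FALSE)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  se <- sd_diff / sqrt(n)
  tcrit <- stats::qt(1 - (1 - conf) / 2, n - 1)
  list(t = mean_diff / se, df = n - 1,
       ci = c(mean_diff - tcrit * se, mean_diff + tcrit * se))
}

#' Bonferroni-corrected per-test level
#'
#' Divides the familywise level by the number of tests; the reported value
#' is rounded to three decimals (0.05 over 12 tests is reported as 0.004).
#'
#' @param family_alpha Familywise level. Default 0.05.
#' @param m_tests Number of tests in the family (>= 1).
#' @return A list with `alpha` (exact) and `reported` (3-decimal rounding).
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, m_tests) {
  stopifnot(m_tests >= 1)
  a <- family_alpha / m_tests
  list(alpha = a, reported = round(a, 3))
}
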