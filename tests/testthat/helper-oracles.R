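# Independent brute-force oracles for the statistical layer.
# These deliberately take different computational routes from the package:
# aov() model fits for the mean-square decompositions and hand rank
# arithmetic for the Friedman statistic.

# Agreement ICC via an aov() two-way decomposition (subject + trial),
# McGraw-Wong formulas applied to the aov mean squares.
oracle_icc <- function(mat, form = "single", conf = 0.95) {
  n <- nrow(mat); k <- ncol(mat)
  long <- data.frame(
    y = as.vector(mat),
    subj = factor(rep(seq_len(n), k)),
    trial = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ subj + trial, data = long))[[1]][["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  est1 <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  estk <- (MSR - MSE) / (MSR + (MSC - MSE) / n)
  alpha <- 1 - conf
  a <- k * est1 / (n * (1 - est1))
  b <- 1 + k * est1 * (n - 1) / (n * (1 - est1))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (MSR - FL * MSE) / (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  up <- n * (FU * MSR - MSE) / (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  if (form == "single") {
    list(estimate = est1, lower = lo, upper = up)
  } else {
    to_k <- function(r) k * r / (1 + (k - 1) * r)
    list(estimate = estk, lower = to_k(lo), upper = to_k(up))
  }
}

# Consistency (two-way mixed) single-measure ICC, for contrast with the
# agreement form: (MSR - MSE) / (MSR + (k-1) MSE) where MSE is the
# residual after removing the trial main effect.
oracle_icc_consistency <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  long <- data.frame(
    y = as.vector(mat),
    subj = factor(rep(seq_len(n), k)),
    trial = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ subj + trial, data = long))[[1]][["Mean Sq"]]
  (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3])
}

# One-way repeated-measures ANOVA via aov() with an Error() stratum.
oracle_rm_anova <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  long <- data.frame(
    y = as.vector(mat),
    subj = factor(rep(seq_len(n), m)),
    cond = factor(rep(seq_len(m), each = n))
  )
  fit <- stats::aov(y ~ cond + Error(subj), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  ssc <- tab["cond", "Sum Sq"]; sse <- tab["Residuals", "Sum Sq"]
  list(F = tab["cond", "F value"], p = tab["cond", "Pr(>F)"],
       etap2 = ssc / (ssc + sse))
}

# Friedman chi-square by the rank-variance formula with the standard
# tie correction.
oracle_friedman <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  R <- t(apply(mat, 1, rank))
  Rj <- colSums(R)
  stat <- 12 * sum((Rj - n * (m + 1) / 2)^2) / (n * m * (m + 1))
  ties <- apply(mat, 1, function(row) {
    tt <- table(row)
    sum(tt^3 - tt)
  })
  corr <- 1 - sum(ties) / (n * m * (m^2 - 1))
  chisq <- stat / corr
  list(chisq = chisq, W = chisq / (n * (m - 1)),
       p = stats::pchisq(chisq, m - 1, lower.tail = FALSE))
}

# Textbook paired t from first principles.
oracle_paired_t <- function(x, y, conf = 0.95) {
  d <- y - x
  n <- length(d)
  se <- stats::sd(d) / sqrt(n)
  t <- mean(d) / se
  tcrit <- stats::qt(1 - (1 - conf) / 2, n - 1)
  list(t = t, p = 2 * stats::pt(-abs(t), n - 1),
       ci = c(mean(d) - tcrit * se, mean(d) + tcrit * se),
       dz = mean(d) / stats::sd(d))
}
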