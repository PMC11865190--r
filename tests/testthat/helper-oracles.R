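# Independent brute-force oracles, coded separately from the package paths
# they check: scalar step-by-step formula evaluation, full hypergeometric
# enumeration for the exact test, and the step-up FDR adjustment by hand.

oracle_ror <- function(a, b, c, d) {
  odds_exposed <- a / b
  odds_unexposed <- c / d
  or <- odds_exposed / odds_unexposed
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(ror = or, low = or * exp(-1.96 * se), high = or * exp(1.96 * se))
}

oracle_prr <- function(a, b, c, d) {
  rate_exposed <- a / (a + b)
  rate_unexposed <- c / (c + d)
  prr <- rate_exposed / rate_unexposed
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  c(prr = prr, low = prr * exp(-1.96 * se), high = prr * exp(1.96 * se))
}

# Yates-corrected chi-square, each cell's |O-E|-0.5 floored at zero
oracle_chi2_yates <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  sum(pmax(abs(obs - expd) - 0.5, 0)^2 / expd)
}

# Bate BCPNN with gamma11 = 1, alpha1 = beta1 = 1, alpha = beta = 2
oracle_ic <- function(a, b, c, d) {
  N <- a + b + c + d
  gamma11 <- 1; alpha1 <- 1; beta1 <- 1; alpha <- 2; beta <- 2
  row1 <- a + b + alpha1
  col1 <- a + c + beta1
  gam <- gamma11 * (N + alpha) * (N + beta) / (row1 * col1)
  eic <- log((a + gamma11) * (N + alpha) * (N + beta) /
               ((N + gam) * row1 * col1)) / log(2)
  vic <- (1 / log(2))^2 *
    ((N - a + gam - gamma11) / ((a + gamma11) * (1 + N + gam)) +
       (N - a - b + alpha - alpha1) / (row1 * (1 + N + alpha)) +
       (N - a - c + beta - beta1) / (col1 * (1 + N + beta)))
  c(ic = eic, ic025 = eic - 1.96 * sqrt(vic))
}

# two-sided Fisher exact p by enumerating the full hypergeometric support
oracle_fisher_two_sided <- function(a, b, c, d) {
  support <- max(0, a - d):(a + min(b, c))
  probs <- dhyper(support, a + b, c + d, a + c)
  p_obs <- dhyper(a, a + b, c + d, a + c)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg by the step-up definition: sort, scale by m/rank,
# enforce monotonicity from the largest down, cap at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
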