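# Multi-item gamma-Poisson shrinker (MGPS). The observed count a of a
# drug-event pair is modeled as Poisson(lambda * E) with the relative
# reporting ratio lambda drawn from a two-component gamma mixture prior
#   lambda ~ w Gamma(alpha1, beta1) + (1-w) Gamma(alpha2, beta2)
# (shape/rate). Marginally a is a mixture of negative binomials,
#   a ~ w NB(size=alpha1, prob=beta1/(beta1+E))
#     + (1-w) NB(size=alpha2, prob=beta2/(beta2+E)),
# whose summed log-likelihood over all pairs is maximized to fit the five
# hyperparameters. The posterior for one pair is again a two-component gamma
# mixture with weights Qn; EBGM = 2^{E[log2 lambda]} uses
# E[ln lambda | component j] = digamma(alpha_j + a) - ln(beta_j + E), and
# EBGM05 is the 5th percentile of the posterior mixture found by root
# finding on its CDF.

#' Default two-gamma mixture prior
#'
#' The classical starting hyperparameters
#' `(alpha1, beta1, alpha2, beta2, w) = (0.2, 0.1, 2.0, 4.0, 1/3)`: a
#' diffuse component for elevated pairs and a concentrated component near
#' lambda = 0.5 for the unremarkable mass.
#'
#' @return an `mgps_prior` list with a `converged` flag (`NA`: not fitted).
#' @export
default_mgps_prior <- function() {
  structure(list(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2.0, beta2 = 4.0,
                 w = 1 / 3, converged = NA, loglik = NA_real_,
                 fallback = FALSE),
            class = "mgps_prior")
}

#' Construct an MGPS prior from explicit hyperparameters
#'
#' @param alpha1,beta1,alpha2,beta2 positive shape/rate parameters of the two
#'   gamma components.
#' @param w mixture weight of the first component in `[0, 1]` (the boundary
#'   values give a degenerate single-gamma prior).
#' @return an `mgps_prior`.
#' @export
mgps_prior <- function(alpha1, beta1, alpha2 = alpha1, beta2 = beta1, w = 1) {
  stopifnot(alpha1 > 0, beta1 > 0, alpha2 > 0, beta2 > 0, w >= 0, w <= 1)
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 beta2 = beta2, w = w, converged = NA, loglik = NA_real_,
                 fallback = FALSE),
            class = "mgps_prior")
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat(sprintf("mgps_prior: alpha1=%.4g beta1=%.4g alpha2=%.4g beta2=%.4g w=%.4g",
              x$alpha1, x$beta1, x$alpha2, x$beta2, x$w))
  if (!is.na(x$loglik)) cat(sprintf("  (loglik %.4f)", x$loglik))
  if (isTRUE(x$fallback)) cat("  [fallback: default prior]")
  cat("\n")
  invisible(x)
}

#' Marginal mixture log-likelihood of counts under an MGPS prior
#'
#' @param a observed counts.
#' @param E expected counts under independence (> 0).
#' @param prior an `mgps_prior`.
#' @return total log-likelihood (sum over pairs).
#' @export
mgps_loglik <- function(a, E, prior) {
  sum(.mgps_loglik_vec(a, E, prior$alpha1, prior$beta1, prior$alpha2,
                       prior$beta2, prior$w))
}

.mgps_loglik_vec <- function(a, E, a1, b1, a2, b2, w) {
  l1 <- stats::dnbinom(a, size = a1, prob = b1 / (b1 + E), log = TRUE)
  l2 <- stats::dnbinom(a, size = a2, prob = b2 / (b2 + E), log = TRUE)
  if (w >= 1) return(l1)
  if (w <= 0) return(l2)
  m <- pmax(l1, l2)
  m + log(w * exp(l1 - m) + (1 - w) * exp(l2 - m))
}

# deterministic multiplicative jitters applied to the default start
.mgps_starts <- function(w_fixed) {
  base <- c(log(0.2), log(0.1), log(2), log(4), stats::qlogis(1 / 3))
  jit <- rbind(0,
               c(0.7, -0.7, 0.4, 0.4, 0.8),
               c(-0.7, 0.7, -0.4, -0.4, -0.8),
               c(1.2, 0.5, -0.8, 0.6, 0),
               c(-0.5, -1.2, 0.8, -0.6, 0.5))
  starts <- sweep(jit, 2, base, "+")
  if (!is.null(w_fixed)) starts <- starts[, 1:4, drop = FALSE]
  starts
}

#' Fit the MGPS prior by marginal maximum likelihood
#'
#' Maximizes the summed negative-binomial-mixture log-likelihood over the
#' five hyperparameters, on log (shapes/rates) and logit (weight) scales.
#' Mixture likelihoods are multimodal, so optimization is multi-start: the
#' default prior plus four deterministically jittered starts, each polished
#' with Nelder-Mead and then BFGS to a 1e-8 relative tolerance on the
#' log-likelihood. The attained log-likelihood is never below the default
#' prior's (the default is always a candidate). With fewer than `min_tables`
#' usable tables, or on optimizer failure, the default prior is returned
#' with its `fallback` flag set (and a warning).
#'
#' @param tables a [build_contingency()] result, or any data.frame with
#'   columns `a` and `E`; rows with `E <= 0` are dropped.
#' @param w_fixed optionally fix the mixture weight (e.g. `w_fixed = 1`
#'   reduces the model to a single gamma component).
#' @param min_tables minimum number of usable tables to attempt a fit.
#' @return an `mgps_prior` with `converged`, `loglik` and `fallback` fields.
#' @export
fit_mgps_prior <- function(tables, w_fixed = NULL, min_tables = 50) {
  a <- as.numeric(tables$a)
  E <- as.numeric(tables$E)
  keep <- is.finite(a) & is.finite(E) & E > 0
  a <- a[keep]; E <- E[keep]
  fallback <- default_mgps_prior()
  fallback$fallback <- TRUE
  fallback$converged <- FALSE
  if (length(a) < min_tables) {
    warning(sprintf("only %d tables with E > 0 (< %d): using default prior",
                    length(a), min_tables))
    fallback$loglik <- if (length(a)) mgps_loglik(a, E, fallback) else NA_real_
    return(fallback)
  }
  negll <- function(theta) {
    a1 <- exp(theta[1]); b1 <- exp(theta[2])
    a2 <- exp(theta[3]); b2 <- exp(theta[4])
    w <- if (is.null(w_fixed)) stats::plogis(theta[5]) else w_fixed
    if (!all(is.finite(c(a1, b1, a2, b2)))) return(1e12)
    ll <- sum(.mgps_loglik_vec(a, E, a1, b1, a2, b2, w))
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  best <- NULL
  for (i in seq_len(nrow(.mgps_starts(w_fixed)))) {
    par0 <- .mgps_starts(w_fixed)[i, ]
    fit <- tryCatch({
      nm <- stats::optim(par0, negll, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-10))
      stats::optim(nm$par, negll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10))
    }, error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  default_ll <- sum(.mgps_loglik_vec(
    a, E, 0.2, 0.1, 2, 4, if (is.null(w_fixed)) 1 / 3 else w_fixed))
  if (is.null(best) || -best$value < default_ll) {
    if (is.null(best)) {
      warning("MGPS optimizer failed: using default prior")
      fallback$loglik <- default_ll
      if (!is.null(w_fixed)) fallback$w <- w_fixed
      return(fallback)
    }
    # optimizer did not beat the default start; keep the default parameters
    prior <- default_mgps_prior()
    prior$converged <- TRUE
    prior$loglik <- default_ll
    if (!is.null(w_fixed)) prior$w <- w_fixed
    return(prior)
  }
  th <- best$par
  structure(list(alpha1 = exp(th[1]), beta1 = exp(th[2]),
                 alpha2 = exp(th[3]), beta2 = exp(th[4]),
                 w = if (is.null(w_fixed)) stats::plogis(th[5]) else w_fixed,
                 converged = best$convergence == 0,
                 loglik = -best$value, fallback = FALSE),
            class = "mgps_prior")
}

#' Posterior EBGM and EBGM05 under an MGPS prior
#'
#' For each pair the posterior over the relative reporting ratio lambda is
#' `Qn Gamma(alpha1 + a, beta1 + E) + (1 - Qn) Gamma(alpha2 + a, beta2 + E)`
#' with `Qn` the posterior component weight (from the marginal negative
#' binomial densities). `EBGM = 2^{E[log2 lambda]}` and `EBGM05` is the 5th
#' percentile of the posterior mixture, obtained by root finding on its CDF
#' (bracket widened geometrically if needed).
#'
#' @param a observed counts (vector).
#' @param E expected counts under independence (> 0).
#' @param prior an `mgps_prior`.
#' @return `data.table` with columns `EBGM`, `EBGM05`.
#' @export
compute_ebgm <- function(a, E, prior = default_mgps_prior()) {
  stopifnot(inherits(prior, "mgps_prior"), length(a) == length(E))
  if (length(a) == 0) return(data.table(EBGM = numeric(), EBGM05 = numeric()))
  if (any(!is.finite(E) | E <= 0)) stop("all E must be finite and > 0")
  a1 <- prior$alpha1; b1 <- prior$beta1
  a2 <- prior$alpha2; b2 <- prior$beta2; w <- prior$w
  l1 <- stats::dnbinom(a, size = a1, prob = b1 / (b1 + E), log = TRUE) + log(w)
  l2 <- stats::dnbinom(a, size = a2, prob = b2 / (b2 + E), log = TRUE) + log1p(-w)
  if (w >= 1) { qn <- rep(1, length(a)) } else if (w <= 0) {
    qn <- rep(0, length(a))
  } else {
    m <- pmax(l1, l2)
    qn <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
  }
  elog <- qn * (digamma(a1 + a) - log(b1 + E)) +
    (1 - qn) * (digamma(a2 + a) - log(b2 + E))
  ebgm <- 2^(elog / log(2))
  ebgm05 <- vapply(seq_along(a), function(i) {
    .mixture_gamma_quantile(0.05, qn[i], a1 + a[i], b1 + E[i],
                            a2 + a[i], b2 + E[i])
  }, numeric(1))
  data.table(EBGM = ebgm, EBGM05 = ebgm05)
}

# p-quantile of q*Gamma(s1,r1) + (1-q)*Gamma(s2,r2) by root finding on the
# CDF; the bracket starts at the component quantiles and widens geometrically
.mixture_gamma_quantile <- function(p, q, s1, r1, s2, r2) {
  cdf <- function(x) {
    q * stats::pgamma(x, shape = s1, rate = r1) +
      (1 - q) * stats::pgamma(x, shape = s2, rate = r2)
  }
  q1 <- stats::qgamma(p, shape = s1, rate = r1)
  q2 <- stats::qgamma(p, shape = s2, rate = r2)
  lo <- min(q1, q2); hi <- max(q1, q2)
  if (lo <= 0) lo <- .Machine$double.xmin
  tries <- 0
  while (cdf(lo) > p && tries < 600) { lo <- lo / 2; tries <- tries + 1 }
  tries <- 0
  while (cdf(hi) < p && tries < 600) { hi <- hi * 2; tries <- tries + 1 }
  if (cdf(lo) > p || cdf(hi) < p)
    stop("EBGM05 root finding failed: could not bracket the quantile")
  if (abs(hi - lo) < .Machine$double.eps) return(lo)
  stats::uniroot(function(x) cdf(x) - p, lower = lo, upper = hi,
                 tol = 1e-10)$root
}

#' Ratio-based EBGM variant
#'
#' The simplified formulation common in spontaneous-report screening:
#' `EBGM = aN/((a+b)(a+c)) = a/E` and
#' `EBGM05 = exp(ln EBGM - 1.645 sqrt(1/a + 1/b + 1/c + 1/d))`. Suppressed
#' (NA) when any cell is zero.
#'
#' @inheritParams compute_ror
#' @return `data.table` with columns `EBGM`, `EBGM05`.
#' @export
compute_ebgm_simple <- function(a, b = NULL, c = NULL, d = NULL) {
  x <- .cells(a, b, c, d)
  N <- x$a + x$b + x$c + x$d
  ok <- x$a > 0 & x$b > 0 & x$c > 0 & x$d > 0
  ebgm <- se <- rep(NA_real_, length(x$a))
  ebgm[ok] <- x$a[ok] * N[ok] / ((x$a[ok] + x$b[ok]) * (x$a[ok] + x$c[ok]))
  se[ok] <- sqrt(1 / x$a[ok] + 1 / x$b[ok] + 1 / x$c[ok] + 1 / x$d[ok])
  data.table(EBGM = ebgm, EBGM05 = exp(log(ebgm) - 1.645 * se))
}
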