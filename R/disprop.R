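# The four disproportionality statistics of spontaneous-report signal
# detection, computed on 2x2 tables (a,b,c,d):
#
#   ROR  = ad/bc, Wald 95% CI on the log scale;
#   PRR  = [a/(a+b)]/[c/(c+d)], Wald CI, with a Yates-corrected chi-square;
#   IC   = BCPNN information component (Bate's formulation, in bits) with
#          its 2.5th-percentile bound IC025;
#   EBGM = empirical Bayes geometric mean under the two-component
#          gamma-Poisson mixture prior (see mgps.R), with EBGM05.
#
# A pair is a signal when all four criteria are jointly met:
# ROR >= 3 with CI lower bound > 1, PRR >= 2 with CI lower bound > 1,
# IC025 > 1, EBGM05 > 2, at a minimum count a >= 3.

.cells <- function(a, b, c, d) {
  if (is.data.frame(a)) {
    stopifnot(all(c("a", "b", "c", "d") %in% names(a)))
    list(a = as.numeric(a$a), b = as.numeric(a$b),
         c = as.numeric(a$c), d = as.numeric(a$d))
  } else {
    list(a = as.numeric(a), b = as.numeric(b),
         c = as.numeric(c), d = as.numeric(d))
  }
}

#' Reporting odds ratio with Wald 95% confidence interval
#'
#' `ROR = ad/(bc)`; `CI = exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.
#' No continuity correction is applied: when any cell is zero the estimate
#' is suppressed (`NA`) rather than silently biased.
#'
#' @param a,b,c,d cell counts (vectors), or a data.frame with those columns
#'   as first argument (e.g. [build_contingency()] output).
#' @return `data.table` with columns `ROR`, `ror_low`, `ror_high`.
#' @export
#' @examples
#' compute_ror(25, 75, 100, 9800)
compute_ror <- function(a, b = NULL, c = NULL, d = NULL) {
  x <- .cells(a, b, c, d)
  ok <- x$a > 0 & x$b > 0 & x$c > 0 & x$d > 0
  ror <- se <- rep(NA_real_, length(x$a))
  ror[ok] <- (x$a[ok] * x$d[ok]) / (x$b[ok] * x$c[ok])
  se[ok] <- sqrt(1 / x$a[ok] + 1 / x$b[ok] + 1 / x$c[ok] + 1 / x$d[ok])
  data.table(ROR = ror,
             ror_low = exp(log(ror) - 1.96 * se),
             ror_high = exp(log(ror) + 1.96 * se))
}

#' Proportional reporting ratio, Wald 95% CI, and Yates-corrected chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`;
#' `CI = exp(ln PRR +/- 1.96 sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`.
#' The chi-square statistic uses the Yates continuity correction with each
#' cell's contribution `max(|O - E| - 0.5, 0)^2 / E` (floored at zero so tiny
#' deviations are not inflated).
#'
#' @inheritParams compute_ror
#' @return `data.table` with columns `PRR`, `prr_low`, `prr_high`, `chi2`.
#' @export
#' @examples
#' compute_prr(10, 90, 90, 9810)
compute_prr <- function(a, b = NULL, c = NULL, d = NULL) {
  x <- .cells(a, b, c, d)
  ok <- x$a > 0 & x$b > 0 & x$c > 0 & x$d > 0
  prr <- se <- rep(NA_real_, length(x$a))
  prr[ok] <- (x$a[ok] / (x$a[ok] + x$b[ok])) / (x$c[ok] / (x$c[ok] + x$d[ok]))
  se[ok] <- sqrt(1 / x$a[ok] - 1 / (x$a[ok] + x$b[ok]) +
                   1 / x$c[ok] - 1 / (x$c[ok] + x$d[ok]))
  n <- x$a + x$b + x$c + x$d
  chi2 <- rep(NA_real_, length(x$a))
  pos <- n > 0
  if (any(pos)) {
    ea <- (x$a + x$b) * (x$a + x$c) / n
    eb <- (x$a + x$b) * (x$b + x$d) / n
    ec <- (x$c + x$d) * (x$a + x$c) / n
    ed <- (x$c + x$d) * (x$b + x$d) / n
    yc <- function(o, e) ifelse(e > 0, pmax(abs(o - e) - 0.5, 0)^2 / e, 0)
    chi2[pos] <- (yc(x$a, ea) + yc(x$b, eb) + yc(x$c, ec) + yc(x$d, ed))[pos]
  }
  data.table(PRR = prr,
             prr_low = exp(log(prr) - 1.96 * se),
             prr_high = exp(log(prr) + 1.96 * se),
             chi2 = chi2)
}

#' BCPNN information component and its lower credibility bound
#'
#' Bate's closed-form Bayesian confidence propagation neural network, in
#' bits (log base 2), with hyperparameters `gamma11 = 1`,
#' `alpha1 = beta1 = 1`, `alpha = beta = 2`:
#'
#' `gamma = gamma11 (N+alpha)(N+beta) / ((a+b+alpha1)(a+c+beta1))`
#'
#' `E(IC) = log2[(a+gamma11)(N+alpha)(N+beta) /
#'               ((N+gamma)(a+b+alpha1)(a+c+beta1))]`
#'
#' `V(IC) = (1/ln 2)^2 [ (N-a+gamma-gamma11)/((a+gamma11)(1+N+gamma))`
#' ` + (N-a-b+alpha-alpha1)/((a+b+alpha1)(1+N+alpha))`
#' ` + (N-a-c+beta-beta1)/((a+c+beta1)(1+N+beta)) ]`
#'
#' `IC025 = E(IC) - 1.96 sqrt(V(IC))`. The smoothing makes every quantity
#' finite for any table with `N > 0`, including `a = 0`.
#'
#' @inheritParams compute_ror
#' @return `data.table` with columns `IC`, `IC025`.
#' @export
compute_bcpnn <- function(a, b = NULL, c = NULL, d = NULL) {
  x <- .cells(a, b, c, d)
  N <- x$a + x$b + x$c + x$d
  g11 <- 1; a1 <- 1; b1 <- 1; al <- 2; be <- 2
  row1 <- x$a + x$b + a1
  col1 <- x$a + x$c + b1
  gam <- g11 * (N + al) * (N + be) / (row1 * col1)
  ic <- log2((x$a + g11) * (N + al) * (N + be) / ((N + gam) * row1 * col1))
  vic <- (1 / log(2))^2 *
    ((N - x$a + gam - g11) / ((x$a + g11) * (1 + N + gam)) +
       (N - x$a - x$b + al - a1) / (row1 * (1 + N + al)) +
       (N - x$a - x$c + be - b1) / (col1 * (1 + N + be)))
  data.table(IC = ic, IC025 = ic - 1.96 * sqrt(vic))
}

#' Joint signal thresholds
#'
#' The positivity criteria applied jointly to the four statistics: a pair is
#' a signal when `ROR >= ror_min` with its CI lower bound `> ror_ci_low_min`,
#' `PRR >= prr_min` with lower bound `> prr_ci_low_min`, `IC025 > ic025_min`,
#' `EBGM05 > ebgm05_min`, and `a >= min_count`. The default `ic025_min = 1`
#' is deliberately stricter than the conventional `IC025 > 0` screen; set it
#' to 0 to recover the conventional rule.
#'
#' @param ror_min,ror_ci_low_min,prr_min,prr_ci_low_min,ic025_min,ebgm05_min,min_count
#'   nonnegative numbers.
#' @return a `signal_thresholds` list.
#' @export
signal_thresholds <- function(ror_min = 3, ror_ci_low_min = 1,
                              prr_min = 2, prr_ci_low_min = 1,
                              ic025_min = 1, ebgm05_min = 2, min_count = 3) {
  th <- list(ror_min = ror_min, ror_ci_low_min = ror_ci_low_min,
             prr_min = prr_min, prr_ci_low_min = prr_ci_low_min,
             ic025_min = ic025_min, ebgm05_min = ebgm05_min,
             min_count = min_count)
  if (any(!vapply(th, function(v) is.numeric(v) && length(v) == 1 && v >= 0,
                  logical(1))))
    stop("all thresholds must be single nonnegative numbers")
  structure(th, class = "signal_thresholds")
}

#' Evaluate the joint signal criteria
#'
#' @param stats data.frame with columns `a`, `ROR`, `ror_low`, `PRR`,
#'   `prr_low`, `IC025`, `EBGM05` (as produced by [compute_signal_stats()]).
#' @param thresholds a [signal_thresholds()] object.
#' @return `data.table` of per-criterion logical flags (`ror_ok`, `prr_ok`,
#'   `ic_ok`, `ebgm_ok`, `count_ok`) and their conjunction `signal`;
#'   missing estimates fail their criterion.
#' @export
evaluate_signal <- function(stats, thresholds = signal_thresholds()) {
  stopifnot(inherits(thresholds, "signal_thresholds"))
  ok <- function(x) !is.na(x) & x
  flags <- data.table(
    ror_ok = ok(stats$ROR >= thresholds$ror_min &
                  stats$ror_low > thresholds$ror_ci_low_min),
    prr_ok = ok(stats$PRR >= thresholds$prr_min &
                  stats$prr_low > thresholds$prr_ci_low_min),
    ic_ok = ok(stats$IC025 > thresholds$ic025_min),
    ebgm_ok = ok(stats$EBGM05 > thresholds$ebgm05_min),
    count_ok = ok(stats$a >= thresholds$min_count))
  flags[, signal := ror_ok & prr_ok & ic_ok & ebgm_ok & count_ok]
  flags
}

#' Compute all four disproportionality statistics for a table set
#'
#' Runs ROR, PRR (+ chi-square), BCPNN IC and EBGM over every contingency
#' table and applies the joint signal criteria. Estimates are suppressed
#' (NA, with a reason code) for tables with `a < min_count` or, for the
#' frequentist statistics, any zero cell; the Bayesian statistics are
#' defined for all tables but follow the same `min_count` reporting floor.
#'
#' @param tables a [build_contingency()] result (columns `event`, `level`,
#'   `a`, `b`, `c`, `d`, `N`, `E`).
#' @param thresholds a [signal_thresholds()] object.
#' @param ebgm_mode `"mgps"` (two-component gamma-Poisson shrinker with a
#'   prior fitted on these tables by [fit_mgps_prior()]) or `"simple"` (the
#'   ratio-based variant `EBGM = aN/((a+b)(a+c))` with
#'   `EBGM05 = exp(ln EBGM - 1.645 sqrt(1/a+1/b+1/c+1/d))`).
#' @param prior optional `mgps_prior` to use instead of fitting.
#' @return a `data.table` of class `signal_stats` with fixed column order
#'   `event, level, a, ROR, ror_low, ror_high, PRR, prr_low, prr_high, chi2,`
#'   `IC, IC025, EBGM, EBGM05, signal`, then the per-criterion flags and a
#'   `suppressed` reason column; attribute `prior` holds the fitted prior.
#' @export
compute_signal_stats <- function(tables, thresholds = signal_thresholds(),
                                 ebgm_mode = c("mgps", "simple"),
                                 prior = NULL) {
  ebgm_mode <- match.arg(ebgm_mode)
  stopifnot(all(c("event", "level", "a", "b", "c", "d", "N", "E") %in%
                  names(tables)))
  tab <- as.data.table(tables)
  out <- data.table(event = tab$event, level = tab$level, a = as.numeric(tab$a))
  out <- cbind(out, compute_ror(tab), compute_prr(tab), compute_bcpnn(tab))

  if (ebgm_mode == "mgps") {
    if (is.null(prior)) prior <- fit_mgps_prior(tab)
    eb <- compute_ebgm(tab$a, tab$E, prior)
  } else {
    prior <- NULL
    eb <- compute_ebgm_simple(tab)
  }
  out <- cbind(out, eb)

  zero_cell <- tab$a == 0 | tab$b == 0 | tab$c == 0 | tab$d == 0
  small <- tab$a < thresholds$min_count
  suppressed <- ifelse(small, "a<min_count", ifelse(zero_cell, "zero_cell", ""))
  est_cols <- c("ROR", "ror_low", "ror_high", "PRR", "prr_low", "prr_high",
                "chi2", "IC", "IC025", "EBGM", "EBGM05")
  for (cc in est_cols) data.table::set(out, which(small), cc, NA_real_)

  flags <- evaluate_signal(out, thresholds)
  out <- cbind(out, flags[, c("signal", "ror_ok", "prr_ok", "ic_ok", "ebgm_ok",
                              "count_ok")])
  out[, suppressed := suppressed]
  setattr(out, "class", c("signal_stats", class(out)))
  setattr(out, "prior", prior)
  setattr(out, "ebgm_mode", ebgm_mode)
  setattr(out, "target", attr(tables, "target"))
  out
}

#' Rank a signal table
#'
#' Stable descending sort by the chosen key; ties broken by `a` (descending)
#' then event label (lexicographically ascending).
#'
#' @param stats a [compute_signal_stats()] table.
#' @param sort_key `"ROR"`, `"a"` or `"EBGM"`.
#' @param signals_only keep only rows with `signal == TRUE`.
#' @return the reordered table.
#' @export
rank_signals <- function(stats, sort_key = c("ROR", "a", "EBGM"),
                         signals_only = FALSE) {
  sort_key <- match.arg(sort_key)
  out <- as.data.table(stats)
  if (signals_only) out <- out[out$signal %in% TRUE]
  key <- out[[sort_key]]
  key[is.na(key)] <- -Inf
  out[order(-key, -out$a, out$event, method = "radix")]
}

#' Write a signal table to a tab-separated file
#'
#' Column order is fixed: `event, level, a, ROR, ror_low, ror_high, PRR,`
#' `prr_low, prr_high, chi2, IC, IC025, EBGM, EBGM05, signal`.
#'
#' @param stats a [compute_signal_stats()] table.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_signal_table <- function(stats, path) {
  keep_cols <- c("event", "level", "a", "ROR", "ror_low", "ror_high",
                 "PRR", "prr_low", "prr_high", "chi2", "IC", "IC025",
                 "EBGM", "EBGM05", "signal")
  fwrite(as.data.table(stats)[, ..keep_cols], path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @export
print.signal_stats <- function(x, ...) {
  cat(sprintf("signal_stats: %d events (%s), %d signal(s), ebgm_mode=%s\n",
              nrow(x), if (nrow(x)) x$level[1] else "?",
              sum(x$signal, na.rm = TRUE), attr(x, "ebgm_mode")))
  print(as.data.table(x), topn = 5)
  invisible(x)
}
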