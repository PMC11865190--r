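# ROR, PRR + chi-square, BCPNN IC: frozen worked examples (computed with the
# scalar oracles in helper-oracles.R), algebraic identities, monotonicity,
# and the joint signal criteria.

test_that("ROR matches its frozen worked example and identities", {
  r <- compute_ror(25, 75, 100, 9800)
  expect_equal(r$ROR, 32.6666666667, tolerance = 1e-9)
  expect_equal(r$ror_low, 19.9394890623, tolerance = 1e-9)
  expect_equal(r$ror_high, 53.5174751859, tolerance = 1e-9)
  # balanced and independent tables give ROR exactly 1
  expect_equal(compute_ror(10, 10, 10, 10)$ROR, 1)
  expect_equal(compute_ror(6, 3, 40, 20)$ROR, 1)   # ad = bc
  # CI brackets the point estimate
  expect_true(r$ror_low <= r$ROR && r$ROR <= r$ror_high)
})

test_that("PRR and Yates chi-square match their worked examples", {
  p <- compute_prr(10, 90, 90, 9810)
  expect_equal(p$PRR, 11)
  expect_true(p$prr_low <= p$PRR && p$PRR <= p$prr_high)
  # perfectly balanced table: no association, correction floors chi2 at 0
  b <- compute_prr(10, 10, 10, 10)
  expect_equal(b$PRR, 1)
  expect_equal(b$chi2, 0)
})

test_that("zero cells suppress ROR/PRR instead of biasing them", {
  r <- compute_ror(5, 0, 3, 100)
  expect_true(is.na(r$ROR))
  p <- compute_prr(0, 10, 3, 100)
  expect_true(is.na(p$PRR))
  # BCPNN is smoothed and stays finite even at a = 0 or a = N
  ic0 <- compute_bcpnn(0, 10, 10, 100)
  expect_true(is.finite(ic0$IC) && is.finite(ic0$IC025))
  icN <- compute_bcpnn(50, 0, 0, 0)
  expect_true(is.finite(icN$IC))
})

test_that("ROR/PRR/chi2/IC agree with brute-force oracles on random tables", {
  set.seed(404)
  n <- 250
  a <- sample(1:500, n, TRUE); b <- sample(1:500, n, TRUE)
  c_ <- sample(1:500, n, TRUE); d <- sample(1:500, n, TRUE)
  r <- compute_ror(a, b, c_, d)
  p <- compute_prr(a, b, c_, d)
  ic <- compute_bcpnn(a, b, c_, d)
  for (i in seq_len(n)) {
    o_r <- oracle_ror(a[i], b[i], c_[i], d[i])
    o_p <- oracle_prr(a[i], b[i], c_[i], d[i])
    o_i <- oracle_ic(a[i], b[i], c_[i], d[i])
    expect_equal(r$ROR[i], unname(o_r["ror"]), tolerance = 1e-9)
    expect_equal(r$ror_low[i], unname(o_r["low"]), tolerance = 1e-9)
    expect_equal(p$PRR[i], unname(o_p["prr"]), tolerance = 1e-9)
    expect_equal(p$chi2[i], oracle_chi2_yates(a[i], b[i], c_[i], d[i]),
                 tolerance = 1e-9)
    expect_equal(ic$IC[i], unname(o_i["ic"]), tolerance = 1e-9)
    expect_equal(ic$IC025[i], unname(o_i["ic025"]), tolerance = 1e-9)
  }
})

test_that("ROR >= PRR exactly when ROR >= 1", {
  set.seed(77)
  a <- sample(1:50, 500, TRUE); b <- sample(1:50, 500, TRUE)
  c_ <- sample(1:50, 500, TRUE); d <- sample(1:50, 500, TRUE)
  ror <- compute_ror(a, b, c_, d)$ROR
  prr <- compute_prr(a, b, c_, d)$PRR
  expect_identical(ror >= prr, ror >= 1)
})

test_that("IC is near zero at independence and increases in a at fixed margins", {
  # margins 100/100 in N=10000 with a = 1 = E: frozen oracle value
  ind <- compute_bcpnn(1, 99, 99, 9801)
  expect_equal(ind$IC, -0.01413536, tolerance = 1e-7)
  expect_lt(abs(ind$IC), 0.05)
  # increasing a with margins a+b = a+c = 100, N = 10000 fixed
  aa <- 1:99
  grid <- compute_bcpnn(aa, 100 - aa, 100 - aa, 9800 + aa)
  expect_true(all(diff(grid$IC) > 0))
  expect_true(all(grid$IC025 < grid$IC))
})

test_that("joint criteria and threshold semantics behave as specified", {
  s <- data.table::data.table(
    a = c(5, 5, 5),
    ROR = c(3.5, 2.9, 3.5), ror_low = c(1.2, 1.2, 1.2),
    PRR = c(2.5, 2.5, 2.5), prr_low = c(1.1, 1.1, 1.1),
    IC025 = c(1.3, 1.3, 1.3), EBGM05 = c(2.4, 2.4, NA))
  f <- evaluate_signal(s)
  expect_identical(f$signal, c(TRUE, FALSE, FALSE))
  expect_identical(f$ror_ok, c(TRUE, FALSE, TRUE))
  # all-zero thresholds flag every pair with a >= min_count
  zero <- signal_thresholds(ror_min = 0, ror_ci_low_min = 0, prr_min = 0,
                            prr_ci_low_min = 0, ic025_min = 0, ebgm05_min = 0)
  s2 <- data.table::data.table(a = c(3, 2), ROR = 1, ror_low = 0.5, PRR = 1,
                               prr_low = 0.5, IC025 = 0.1, EBGM05 = 0.1)
  expect_identical(evaluate_signal(s2, zero)$signal, c(TRUE, FALSE))
})

test_that("ranking is descending with count and label tie-breaks", {
  s <- data.table::data.table(
    event = c("B", "A", "C", "D"), level = "PT", a = c(3, 7, 7, 10),
    ROR = c(5, 10, 10, 10), EBGM = c(1, 2, 3, 4))
  r <- rank_signals(s, "ROR")
  # equal ROR: larger a first; equal a would fall back to label
  expect_identical(r$event, c("D", "A", "C", "B"))
  s2 <- data.table::data.table(event = c("Z", "Y"), level = "PT",
                               a = c(7, 7), ROR = c(10, 10), EBGM = 1)
  expect_identical(rank_signals(s2, "ROR")$event, c("Y", "Z"))
})

test_that("small counts are reported without estimates", {
  tabs <- data.table::data.table(
    event = c("A", "B"), level = "PT", a = c(2L, 30L), b = c(98L, 70L),
    c = c(50L, 40L), d = c(9850L, 9860L), N = 10000L)
  tabs$E <- (tabs$a + tabs$b) * (tabs$a + tabs$c) / tabs$N
  ss <- compute_signal_stats(tabs, ebgm_mode = "simple")
  expect_true(is.na(ss$ROR[ss$event == "A"]))
  expect_identical(ss$suppressed[ss$event == "A"], "a<min_count")
  expect_false(is.na(ss$ROR[ss$event == "B"]))
  expect_identical(ss$a[ss$event == "A"], 2)
})
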