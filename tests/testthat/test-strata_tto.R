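# Time to onset (computation, exclusions, binning) and gender-stratified
# volcano screening with FDR control.

test_that("onset is event minus earliest target start, with exclusions logged", {
  dir <- write_tiny_faers(
    withr::local_tempdir(),
    DEMO = c(demo_rec(11, 1, event_dt = "20230101"),   # same-day onset
             demo_rec(21, 2, event_dt = "20221225"),   # negative: excluded
             demo_rec(31, 3, event_dt = "202301"),     # partial event date
             demo_rec(41, 4, event_dt = "20230110")),  # earliest of two starts
    DRUG = c(drug_rec(11, 1), drug_rec(21, 2), drug_rec(31, 3),
             drug_rec(41, 4, seq = 1), drug_rec(41, 4, seq = 2)),
    REAC = c("11$1$A", "21$2$A", "31$3$A", "41$4$A"),
    THER = c("11$1$1$20230101", "21$2$1$20230101", "31$3$1$20230101",
             "41$4$1$20230108", "41$4$2$20230102"))
  fd <- deduplicate(read_ascii_tables(dir))
  fdt <- filter_primary_suspect(fd, "TARGET", tiny_synonyms())
  rec <- compute_onsets(fdt)
  expect_identical(nrow(rec), 2L)
  expect_identical(rec$onset_days[rec$primaryid == "11"], 0L)
  expect_identical(as.character(rec$bin[rec$primaryid == "11"]), "<3 d")
  # report 41: earliest start 2023-01-02 -> 8 days
  expect_identical(rec$onset_days[rec$primaryid == "41"], 8L)
  ex <- attr(rec, "exclusions")
  expect_identical(unname(ex["negative_onset"]), 1L)
  expect_identical(unname(ex["partial_event_date"]), 1L)
})

test_that("bin edges follow the documented day ranges", {
  days <- c(0, 2, 3, 7, 8, 14, 15, 30, 31, 400)
  expect_identical(as.character(tto_bin(days)),
                   c("<3 d", "<3 d", "3-7 d", "3-7 d", "1-2 wk", "1-2 wk",
                     "2 wk-1 mo", "2 wk-1 mo", ">1 mo", ">1 mo"))
})

test_that("pyramid counts are exhaustive, disjoint and conserved", {
  fd <- gen_fd(synthetic_config(n_reports = 3000, seed = 41,
                                onset_mean_days = 4))
  fdt <- filter_primary_suspect(deduplicate(fd), "DRUG_001", canon_synonyms(50))
  rec <- compute_onsets(fdt)
  pyr <- bin_onsets(rec)
  expect_identical(sum(pyr$total), nrow(rec))
  expect_identical(sum(pyr$Female) + sum(pyr$Male) + sum(pyr$Unknown),
                   nrow(rec))
  # geometric onset with mean 4 days: the first two bins dominate
  expect_gt(sum(pyr$total[1:2]), 0.6 * sum(pyr$total))
})

test_that("Fisher p-values match hypergeometric enumeration on small tables", {
  expect_equal(fisher.test(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))$p.value,
               oracle_fisher_two_sided(3, 1, 1, 3), tolerance = 1e-10)
  expect_equal(oracle_fisher_two_sided(3, 1, 1, 3), 0.4857143,
               tolerance = 1e-7)
  set.seed(55)
  for (i in 1:150) {
    cells <- as.vector(rmultinom(1, sample(8:40, 1), rep(0.25, 4)))
    expect_equal(
      fisher.test(matrix(cells, 2, byrow = TRUE))$p.value,
      oracle_fisher_two_sided(cells[1], cells[2], cells[3], cells[4]),
      tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the step-up hand computation and is stable", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  expect_equal(oracle_bh(p), rep(0.04, 4))
  # a fully tied adjusted vector is a fixed point of the step-up procedure
  expect_equal(p.adjust(p.adjust(p, "BH"), "BH"), p.adjust(p, "BH"))
  set.seed(66)
  for (i in 1:20) {
    pv <- runif(sample(3:50, 1))
    adj <- p.adjust(pv, "BH")
    expect_equal(adj, oracle_bh(pv))
    # recomputation from the same input is stable
    expect_identical(p.adjust(pv, "BH"), adj)
    # monotone in raw-p rank, bounded by raw p and 1
    expect_true(all(diff(adj[order(pv)]) >= -1e-12))
    expect_true(all(adj >= pv & adj <= 1))
  }
})

test_that("stratified universes partition the full universe", {
  fd <- gen_fd(synthetic_config(n_reports = 4000, seed = 43))
  fd <- normalize_drug_names(deduplicate(fd), canon_synonyms(50))
  demo <- fd$tables$demo
  n_m <- sum(demo$sex == "M"); n_f <- sum(demo$sex == "F")
  expect_identical(n_m + n_f + sum(!demo$sex %in% c("M", "F")), nrow(demo))
  v <- stratified_volcano(fd, "DRUG_001")
  expect_true(all(v$stratum %in% c("male", "female")))
  expect_true(all(v$p_adj >= v$p_value - 1e-12))
  expect_true(all(v$p_adj <= 1))
})

test_that("a sex-biased planted signal is flagged only in the biased stratum", {
  wd <- c(0.02, rep(0.98 / 49, 49))
  we <- c(0.004, rep(0.996 / 99, 99))
  cfg <- synthetic_config(
    n_reports = 40000, seed = 47, duplicate_rate = 0,
    background_drug_weights = wd, background_event_weights = we,
    drugs_per_report = list(mean = 1, max = 1),
    planted_signals = data.frame(drug = 1, event = 1, rr = 12),
    biased_event = 1, biased_event_female_prob = 0.98)
  fd <- gen_fd(cfg)
  fd <- normalize_drug_names(deduplicate(fd), canon_synonyms(50))
  v <- stratified_volcano(fd, "DRUG_001")
  f_row <- v[v$event == "PT_001" & v$stratum == "female"]
  m_row <- v[v$event == "PT_001" & v$stratum == "male"]
  expect_true(f_row$significant)
  expect_true(nrow(m_row) == 0 || !m_row$significant)
})

test_that("an empty stratum yields a warning and no rows", {
  dir <- write_tiny_faers(
    withr::local_tempdir(),
    DEMO = c(demo_rec(11, 1, sex = "F"), demo_rec(21, 2, sex = "F")),
    DRUG = c(drug_rec(11, 1), drug_rec(21, 2, name = "OTHERDRUG")),
    REAC = c("11$1$A", "21$2$B"))
  fd <- normalize_drug_names(deduplicate(read_ascii_tables(dir)),
                             tiny_synonyms())
  expect_warning(v <- stratified_volcano(fd, "TARGET"), "empty")
  expect_true(all(v$stratum == "female"))
})
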