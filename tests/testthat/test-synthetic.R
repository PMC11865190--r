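# Synthetic report-database generator: structure, determinism, and the
# planted-signal mechanism recovered by direct tabulation.

test_that("zero-report config yields well-formed header-only files", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_reports = 0, seed = 1)
  info <- generate_dataset(cfg, dir)
  for (nm in c("DEMO", "DRUG", "REAC", "THER", "OUTC", "RPSR")) {
    lines <- readLines(info$files[[nm]])
    expect_length(lines, 1)
    expect_match(lines[1], "\\$")
  }
  fd <- read_ascii_tables(dir)
  expect_identical(nrow(fd$tables$demo), 0L)
  expect_identical(sum(fd$log$malformed), 0L)
})

test_that("fixed seed gives byte-identical files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- synthetic_config(n_reports = 300, seed = 7)
  generate_dataset(cfg, d1)
  generate_dataset(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  d3 <- withr::local_tempdir()
  generate_dataset(synthetic_config(n_reports = 300, seed = 8), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "DEMO.txt"))),
                         unname(tools::md5sum(file.path(d3, "DEMO.txt")))))
})

test_that("duplicate versions are emitted at exactly the configured rate", {
  tabs <- gen_tables(synthetic_config(n_reports = 1000, duplicate_rate = 0.1,
                                      seed = 3))
  expect_identical(tabs$n_duplicates, 100L)
  expect_identical(nrow(tabs$demo), 1100L)
  # each duplicated case: same caseid twice, superseding version later
  dup_cases <- tabs$demo$caseid[duplicated(tabs$demo$caseid)]
  expect_length(dup_cases, 100)
  for (cs in dup_cases[1:5]) {
    v <- tabs$demo[tabs$demo$caseid == cs]
    expect_identical(nrow(v), 2L)
    expect_true(max(v$fda_dt) > min(v$fda_dt) ||
                  max(v$primaryid) > min(v$primaryid))
  }
})

test_that("null marginal drug/event frequencies match background weights", {
  n <- 20000
  cfg <- synthetic_config(n_reports = n, seed = 11, duplicate_rate = 0)
  tabs <- gen_tables(cfg)
  # drug mentions are multinomial draws from the configured weights
  dm <- table(factor(sub(" INJECTION", "", toupper(tabs$drug$drugname)),
                     levels = sprintf("DRUG_%03d", 1:cfg$n_drugs)))
  tot <- sum(dm)
  p <- cfg$background_drug_weights
  z <- (as.numeric(dm) - tot * p) / sqrt(tot * p * (1 - p))
  expect_lt(max(abs(z)), 3.6)          # 50 simultaneous 3-sigma checks
  em <- table(factor(tabs$reac$pt, levels = sprintf("PT_%03d", 1:cfg$n_events)))
  tote <- sum(em)
  pe <- cfg$background_event_weights
  ze <- (as.numeric(em) - tote * pe) / sqrt(tote * pe * (1 - pe))
  expect_lt(max(abs(ze)), 3.6)
})

test_that("planted truth table mirrors the configuration", {
  cfg0 <- synthetic_config(n_reports = 10, seed = 1)
  expect_identical(nrow(planted_truth(cfg0)), 0L)
  cfg1 <- synthetic_config(n_reports = 10, seed = 1,
                           planted_signals = data.frame(drug = 3, event = 7,
                                                        rr = 10))
  tr <- planted_truth(cfg1)
  expect_identical(nrow(tr), 1L)
  expect_identical(tr$drug, "DRUG_003")
  expect_identical(tr$event, "PT_007")
  expect_identical(tr$rr, 10)
})

test_that("a planted relative risk of 10 is recovered by direct tabulation", {
  n_drugs <- 50; n_events <- 100
  wd <- rep(NA_real_, n_drugs); wd[1] <- 0.03; wd[-1] <- 0.97 / (n_drugs - 1)
  we <- rep(NA_real_, n_events); we[1] <- 0.004; we[-1] <- 0.996 / (n_events - 1)
  cfg <- synthetic_config(
    n_reports = 50000, seed = 19, duplicate_rate = 0,
    background_drug_weights = wd, background_event_weights = we,
    planted_signals = data.frame(drug = 1, event = 1, rr = 10))
  tabs <- gen_tables(cfg)
  rr_hat <- empirical_rr(tabs, "DRUG_001", "PT_001")
  expect_gt(rr_hat, 8)
  expect_lt(rr_hat, 12)
})

test_that("empirical relative risks rank-correlate with planted truth", {
  n_drugs <- 50; n_events <- 100
  wd <- c(rep(0.7 / 30, 30), rep(0.3 / 20, 20))
  we <- c(rep(0.6 / 80, 80), rep(0.4 / 20, 20))
  truth <- data.frame(drug = 31:50, event = 81:100,
                      rr = seq(1, 20, length.out = 20))
  cfg <- synthetic_config(
    n_reports = 50000, seed = 23, duplicate_rate = 0,
    background_drug_weights = wd, background_event_weights = we,
    planted_signals = truth)
  tabs <- gen_tables(cfg)
  rr_hat <- vapply(seq_len(nrow(truth)), function(i) {
    empirical_rr(tabs, sprintf("DRUG_%03d", truth$drug[i]),
                 sprintf("PT_%03d", truth$event[i]))
  }, numeric(1))
  expect_gt(cor(rr_hat, truth$rr, method = "spearman"), 0.9)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(background_drug_weights = rep(0.5, 50)),
               "sum to 1")
  expect_error(synthetic_config(sex_probs = c(F = 0.5, M = 0.6, UNK = -0.1)),
               "nonnegative")
  expect_error(
    synthetic_config(planted_signals = data.frame(drug = 99, event = 1, rr = 2)),
    "drug index")
  expect_error(
    synthetic_config(planted_signals = data.frame(drug = 1, event = 1, rr = -1)),
    ">= 0")
  # planted probability mass over 1 makes renormalization meaningless
  we <- c(0.5, rep(0.5 / 99, 99))
  expect_error(
    synthetic_config(background_event_weights = we,
                     planted_signals = data.frame(drug = 1, event = 1, rr = 5)),
    "mass")
})
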