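# Parsing the "$"-delimited dialect, case-version deduplication,
# drug-name normalization and primary-suspect filtering.

test_that("malformed lines are counted and skipped, not fatal", {
  dir <- write_tiny_faers(
    withr::local_tempdir(),
    DEMO = c(demo_rec(11, 1), "too$few$fields", demo_rec(21, 2)),
    DRUG = c(drug_rec(11, 1), drug_rec(21, 2)),
    REAC = c("11$1$Epilepsy", "21$2$Rash"),
    THER = c("11$1$1$20200101", "21$2$1$20200101"),
    OUTC = c("11$1$HO", "21$2$OT"),
    RPSR = c("11$1$HP", "21$2$HP"))
  fd <- read_ascii_tables(dir)
  expect_identical(nrow(fd$tables$demo), 2L)
  expect_identical(unname(fd$log$malformed["DEMO"]), 1L)
  expect_identical(sum(fd$log$malformed), 1L)
})

test_that("a missing mandatory column is a hard error naming file and column", {
  dir <- write_tiny_faers(withr::local_tempdir())
  writeLines("primaryid$caseid$sex", file.path(dir, "DEMO.txt"))
  expect_error(read_ascii_tables(dir), "DEMO")
  expect_error(read_ascii_tables(dir), "fda_dt")
})

test_that("legacy ISR/CASE headers are aliased to primaryid/caseid", {
  dir <- write_tiny_faers(withr::local_tempdir(),
                          DRUG = drug_rec(11, 1),
                          REAC = "11$1$Epilepsy",
                          THER = "11$1$1$20200101",
                          OUTC = "11$1$HO", RPSR = "11$1$HP")
  writeLines(c("ISR$CASE$FDA_DT$SEX$AGE$AGE_COD$OCCP_COD$REPORTER_COUNTRY$EVENT_DT",
               demo_rec(11, 1)), file.path(dir, "DEMO.txt"))
  fd <- read_ascii_tables(dir)
  expect_true(all(c("primaryid", "caseid") %in% names(fd$tables$demo)))
})

test_that("deduplication keeps the latest receipt date, largest primaryid on ties", {
  dir <- write_tiny_faers(
    withr::local_tempdir(),
    DEMO = c(demo_rec(11, 1, fda_dt = "20230101"),
             demo_rec(12, 1, fda_dt = "20230301"),
             demo_rec(21, 2, fda_dt = "20220601"),
             demo_rec(29, 2, fda_dt = "20220601"),
             demo_rec(31, 3)),
    DRUG = c(drug_rec(11, 1), drug_rec(12, 1), drug_rec(21, 2),
             drug_rec(29, 2), drug_rec(31, 3)),
    REAC = c("11$1$A", "12$1$A", "21$2$B", "29$2$B", "31$3$C"),
    THER = character(0), OUTC = character(0), RPSR = character(0))
  fd <- deduplicate(read_ascii_tables(dir))
  expect_identical(sort(fd$tables$demo$primaryid), c("12", "29", "31"))
  expect_identical(fd$log$dedup,
                   list(retrieved = 5L, removed = 2L, retained = 3L))
  # other tables are filtered to the retained versions
  expect_identical(sort(fd$tables$reac$primaryid), c("12", "29", "31"))
  # idempotent
  fd2 <- deduplicate(fd)
  expect_identical(fd2$tables$demo, fd$tables$demo)
  expect_identical(fd2$log$dedup$removed, 0L)
})

test_that("dedup removes exactly the generator's planted duplicates", {
  fd <- gen_fd(synthetic_config(n_reports = 1000, duplicate_rate = 0.1,
                                seed = 5))
  fd <- deduplicate(fd)
  expect_identical(fd$log$dedup$removed, 100L)
  expect_identical(fd$log$dedup$retained, 1000L)
  expect_identical(fd$log$dedup$retrieved - fd$log$dedup$removed,
                   fd$log$dedup$retained)
})

test_that("primary-suspect filtering matches role and normalized name", {
  dir <- write_tiny_faers(
    withr::local_tempdir(),
    DEMO = c(demo_rec(11, 1), demo_rec(21, 2), demo_rec(31, 3),
             demo_rec(41, 4)),
    DRUG = c(drug_rec(11, 1, role = "PS", name = "  target  injection "),
             drug_rec(21, 2, role = "SS", name = "TARGET"),
             drug_rec(31, 3, role = "PS", name = "OTHERDRUG"),
             drug_rec(41, 4, role = "PS", name = "TaRgEt")),
    REAC = c("11$1$A", "21$2$A", "31$3$A", "41$4$A"),
    THER = character(0), OUTC = character(0), RPSR = character(0))
  fd <- deduplicate(read_ascii_tables(dir))
  fdt <- filter_primary_suspect(fd, "target", tiny_synonyms())
  expect_identical(sort(fdt$tables$demo$primaryid), c("11", "41"))
  expect_identical(fdt$log$ps_filtered, 2L)
  expect_identical(fdt$target, "TARGET")
  expect_error(filter_primary_suspect(fd, "target", tiny_synonyms()[0]),
               "empty synonym table")
})

test_that("PS filter retains exactly the generator's PS-marked cases", {
  cfg <- synthetic_config(n_reports = 2000, seed = 9)
  fd <- gen_fd(cfg)
  truth_ps <- attr(fd, "bookkeeping")$ps_counts
  fd <- deduplicate(fd)
  fdt <- filter_primary_suspect(fd, "DRUG_004", canon_synonyms(cfg$n_drugs))
  expect_identical(fdt$log$ps_filtered, unname(truth_ps["DRUG_004"]))
})

test_that("parse -> re-serialize -> re-parse is stable", {
  dir <- withr::local_tempdir()
  generate_dataset(synthetic_config(n_reports = 200, seed = 13), dir)
  fd1 <- read_ascii_tables(dir)
  dir2 <- file.path(dir, "roundtrip")
  dir.create(dir2)
  for (nm in c("demo", "drug", "reac", "ther", "outc", "rpsr"))
    data.table::fwrite(fd1$tables[[nm]], file.path(dir2, paste0(toupper(nm), ".txt")),
                       sep = "$", quote = FALSE)
  fd2 <- read_ascii_tables(dir2)
  for (nm in c("demo", "drug", "reac", "ther", "outc", "rpsr"))
    expect_identical(fd2$tables[[nm]], fd1$tables[[nm]], info = nm)
})

test_that("age conversion handles FAERS unit codes", {
  expect_identical(age_in_years(c("60", "720", "6", "30", "-5", "x"),
                                c("YR", "MON", "DEC", "DY", "YR", "YR")),
                   c(60, 60, 60, 30 / 365.25, NA, NA))
})

test_that("partial and malformed dates parse with the right precision", {
  p <- parse_faers_date(c("20230115", "202301", "2023", "", "20231399"))
  expect_identical(p$precision, c("day", "month", "year", "missing", "missing"))
  expect_identical(p$date[1], as.Date("2023-01-15"))
  expect_true(all(is.na(p$date[-1])))
})
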