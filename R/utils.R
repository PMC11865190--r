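#' @importFrom data.table data.table as.data.table setDT setorder setorderv
#'   setnames setattr fwrite fread rbindlist setkey copy :=
#' @importFrom stats setNames
NULL

# silence R CMD check notes for data.table NSE column names
utils::globalVariables(c(
  ".", ".N", ".SD", "a", "b", "caseid", "chi2", "d", "drug_seq", "drugname",
  "drugname_norm", "dsg_drug_seq", "event", "event_dt", "fda_dt", "level",
  "onset_days", "outc_cod", "primaryid", "pt", "role_cod", "route", "rownum",
  "soc", "start_dt", "sex", "stratum", "year", "EBGM", "ROR", "IC",
  "..keep_cols", "N", "E", "n_reports", "prr_low", "ror_low", "p_adj",
  "n_event", "category", "lvl", "universe_n", "mult", "rr",
  "total", "Female", "Male", "Unknown", "bin", "significant",
  "neg_log10_p_adj", "ror_ok", "prr_ok", "ic_ok", "ebgm_ok", "count_ok",
  "suppressed"
))

#' Normalize a drug-name string
#'
#' Trims leading/trailing whitespace, collapses internal whitespace runs to a
#' single space, and upper-cases. This is the canonical form used for synonym
#' lookup and target matching throughout the package.
#'
#' @param x character vector of raw drug names.
#' @return character vector of normalized names.
#' @export
#' @examples
#' normalize_drug_name("  imipenem/cilastatin  ")
normalize_drug_name <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  toupper(x)
}

#' Parse FAERS-style dates with partial-date support
#'
#' FAERS date fields are plain digit strings: `YYYYMMDD` (full), `YYYYMM`
#' (month precision) or `YYYY` (year precision); anything else (including
#' blanks) is missing. Only full dates are convertible to a calendar `Date`.
#'
#' @param x character vector of raw date strings.
#' @return a `data.table` with columns `raw`, `precision` (`"day"`, `"month"`,
#'   `"year"` or `"missing"`) and `date` (`Date`, `NA` unless full precision).
#' @export
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x)] <- ""
  precision <- rep("missing", length(x))
  precision[grepl("^\\d{4}$", x)] <- "year"
  precision[grepl("^\\d{6}$", x)] <- "month"
  precision[grepl("^\\d{8}$", x)] <- "day"
  date <- rep(as.Date(NA), length(x))
  full <- precision == "day"
  if (any(full)) {
    parsed <- as.Date(x[full], format = "%Y%m%d")
    precision[full][is.na(parsed)] <- "missing"   # e.g. 20231350
    date[full] <- parsed
  }
  data.table(raw = x, precision = precision, date = date)
}

# Numeric sort key for possibly-partial date strings: pads YYYY -> YYYY0000,
# YYYYMM -> YYYYMM00 so later dates order later; missing sorts first.
date_sort_key <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x)] <- ""
  key <- rep(0, length(x))
  key[grepl("^\\d{4}$", x)] <- as.numeric(paste0(x[grepl("^\\d{4}$", x)], "0000"))
  key[grepl("^\\d{6}$", x)] <- as.numeric(paste0(x[grepl("^\\d{6}$", x)], "00"))
  key[grepl("^\\d{8}$", x)] <- as.numeric(x[grepl("^\\d{8}$", x)])
  key
}

#' Recompute category percentages from counts
#'
#' The percentage convention used in every demographic panel: each count over
#' an explicit denominator, rounded to 2 decimals. For the sex/age/reporter/
#' country/route panels the denominator is the total report count; for the
#' outcome panel it is the total number of outcome entries (a report may carry
#' several outcomes), which is what makes the panel's shares sum to 100%.
#'
#' @param counts named numeric vector of category counts.
#' @param denominator positive number; defaults to `sum(counts)`.
#' @return named numeric vector of percentages rounded to 2 decimals;
#'   `NA` when the denominator is 0.
#' @export
#' @examples
#' category_percentages(c(female = 1026, male = 1490, unknown = 58))
category_percentages <- function(counts, denominator = sum(counts)) {
  if (length(counts) == 0) return(setNames(numeric(0), character(0)))
  if (!is.numeric(denominator) || length(denominator) != 1 || denominator < 0)
    stop("denominator must be a single nonnegative number")
  if (denominator == 0) return(setNames(rep(NA_real_, length(counts)), names(counts)))
  round(100 * counts / denominator, 2)
}

# Evaluate code with a private RNG state seeded from `seed`, restoring the
# caller's state afterwards: generators are reproducible without clobbering
# the session RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_prob_vector <- function(p, what) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0))
    stop(sprintf("%s must be a nonnegative numeric vector", what))
  if (abs(sum(p) - 1) > 1e-9)
    stop(sprintf("%s must sum to 1 (got %.12f)", what, sum(p)))
  invisible(p)
}
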