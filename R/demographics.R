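# Descriptive summaries of a deduplicated, primary-suspect-filtered report
# set: per-category counts and percentages for sex, age bands, reporter
# occupation, country, administration route and outcome codes, plus yearly
# report counts for the reporting-trend curve.

# FAERS age unit codes, as multiples of one year
.age_unit_years <- c(YR = 1, YEAR = 1, DEC = 10, MON = 1 / 12,
                     WK = 7 / 365.25, DY = 1 / 365.25, HR = 1 / 8766)

#' Convert FAERS age values to years
#'
#' @param age character/numeric vector of age values.
#' @param age_cod FAERS age unit codes (`DEC`, `YR`, `MON`, `WK`, `DY`,
#'   `HR`); unparseable values or unknown codes give `NA`.
#' @return numeric vector of ages in years (`NA` when unknown); negative
#'   ages are treated as unknown.
#' @export
age_in_years <- function(age, age_cod) {
  val <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(as.character(age_cod)))
  cod[cod == ""] <- "YR"          # blank unit with a numeric value: assume years
  mult <- .age_unit_years[cod]
  yr <- val * as.numeric(mult)
  yr[!is.finite(yr) | yr < 0] <- NA_real_
  yr
}

.age_bin_labels <- c("<20", "20-40", "40-60", ">=60", "Unknown")

# half-open bands [0,20) [20,40) [40,60) [60,Inf)
age_bin <- function(years) {
  lab <- rep("Unknown", length(years))
  ok <- is.finite(years)
  lab[ok] <- as.character(cut(years[ok], breaks = c(0, 20, 40, 60, Inf),
                              labels = .age_bin_labels[1:4], right = FALSE,
                              include.lowest = TRUE))
  lab
}

.occp_labels <- c(MD = "Physician", PH = "Pharmacist",
                  OT = "Other health-professional", CN = "Consumer",
                  LW = "Lawyer")
.outc_labels <- c(DE = "Death", LT = "Life threatening", HO = "Hospitalization",
                  DS = "Disability", CA = "Congenital anomaly",
                  RI = "Required intervention", OT = "Other serious")

panel_table <- function(x, denominator) {
  if (length(x) == 0)
    return(data.table(category = character(0), count = integer(0),
                      percentage = numeric(0)))
  tab <- sort(table(x), decreasing = TRUE)
  data.table(category = names(tab), count = as.integer(tab),
             percentage = category_percentages(as.integer(tab), denominator))
}

#' Summarize demographics of a report set
#'
#' Produces the per-category counts and percentages of the standard
#' descriptive table: sex, age bands (`<20`, `20-40`, `40-60`, `>=60`,
#' unknown; half-open on the right), reporter occupation, reporting country,
#' administration route, and outcome codes, plus yearly report counts keyed
#' by receipt year. The sex/age/reporter/country/route panels use the total
#' report count as denominator (every report falls in exactly one category,
#' with an explicit unknown class, so each panel sums to the total). The
#' outcome panel uses the total number of outcome entries, since one report
#' may carry several outcomes. Percentages are rounded to 2 decimals and
#' rendered blank when there are no reports.
#'
#' @param fd a deduplicated (and typically primary-suspect-filtered)
#'   `faers_data` object.
#' @param country_aliases optional named character vector collapsing raw
#'   country spellings (e.g. `c("USA" = "United States")`).
#' @return a `demographic_summary`: list of panel data.tables (`category`,
#'   `count`, `percentage`), `yearly` counts, `total_reports` and
#'   `total_outcome_entries`.
#' @export
summarize_demographics <- function(fd, country_aliases = character()) {
  stopifnot(inherits(fd, "faers_data"))
  demo <- fd$tables$demo
  n <- nrow(demo)

  sex <- ifelse(demo$sex == "F", "Female",
                ifelse(demo$sex == "M", "Male", "Unknown"))
  age <- age_bin(age_in_years(demo$age, demo$age_cod))
  occp <- toupper(trimws(demo$occp_cod))
  reporter <- ifelse(occp %in% names(.occp_labels), .occp_labels[occp], "Unknown")
  country <- trimws(demo$reporter_country)
  country[country == ""] <- "Unknown"
  hit <- country %in% names(country_aliases)
  country[hit] <- country_aliases[country[hit]]

  # route: one per report, taken from its first primary-suspect drug entry
  # (the target's entry when the set has been PS-filtered)
  drug <- fd$tables$drug
  ps <- drug[drug$role_cod == "PS"]
  if (!is.null(fd$target) && "drugname_norm" %in% names(ps))
    ps <- ps[ps$drugname_norm == fd$target]
  route <- rep("Unknown", n)
  if (nrow(ps) > 0 && "route" %in% names(ps)) {
    seq_num <- suppressWarnings(as.numeric(ps$drug_seq))
    seq_num[is.na(seq_num)] <- Inf
    ps <- ps[order(seq_num)]
    first <- ps[!duplicated(ps$primaryid)]
    idx <- match(demo$primaryid, first$primaryid)
    r <- trimws(first$route[idx])
    route[!is.na(idx) & !is.na(r) & nzchar(r)] <-
      r[!is.na(idx) & !is.na(r) & nzchar(r)]
  }

  outc <- fd$tables$outc
  oc <- toupper(trimws(outc$outc_cod))
  outcome <- ifelse(oc %in% names(.outc_labels), .outc_labels[oc], oc)
  n_outc <- length(outcome)

  year <- substr(demo$fda_dt, 1, 4)
  yearly <- panel_table(year, n)[order(category)]
  setnames(yearly, "category", "year")

  structure(list(
    sex = panel_table(sex, n),
    age = panel_table(age, n),
    reporter = panel_table(reporter, n),
    country = panel_table(country, n),
    route = panel_table(route, n),
    outcomes = panel_table(outcome, n_outc),
    yearly = yearly,
    total_reports = n,
    total_outcome_entries = n_outc), class = "demographic_summary")
}

fmt_pct <- function(p) ifelse(is.na(p), "", sprintf("%.2f%%", p))

#' @export
print.demographic_summary <- function(x, ...) {
  cat("Reports:", x$total_reports,
      " Outcome entries:", x$total_outcome_entries, "\n")
  for (panel in c("sex", "age", "reporter", "country", "route", "outcomes")) {
    cat("\n", toupper(substring(panel, 1, 1)), substring(panel, 2), "\n", sep = "")
    tab <- x[[panel]]
    if (nrow(tab) == 0) { cat("  (none)\n"); next }
    for (i in seq_len(nrow(tab)))
      cat(sprintf("  %-32s %6d  %s\n", tab$category[i], tab$count[i],
                  fmt_pct(tab$percentage[i])))
  }
  invisible(x)
}

#' Write a demographic summary to tab-separated files
#'
#' One file per panel (`<prefix>_sex.tsv`, ...) plus `<prefix>_yearly.tsv`;
#' percentages are blank when undefined (zero reports).
#'
#' @param x a `demographic_summary`.
#' @param prefix output path prefix.
#' @return invisibly, the written file paths.
#' @export
write_demographic_summary <- function(x, prefix) {
  stopifnot(inherits(x, "demographic_summary"))
  paths <- character()
  for (panel in c("sex", "age", "reporter", "country", "route", "outcomes", "yearly")) {
    tab <- copy(x[[panel]])
    if ("percentage" %in% names(tab))
      tab$percentage <- ifelse(is.na(tab$percentage), "",
                               sprintf("%.2f", tab$percentage))
    p <- paste0(prefix, "_", panel, ".tsv")
    fwrite(tab, p, sep = "\t", quote = FALSE)
    paths[panel] <- p
  }
  invisible(paths)
}
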