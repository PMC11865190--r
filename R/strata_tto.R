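# Time to onset (days from the earliest target-drug therapy start to the
# event date) with clinical binning, and gender-stratified disproportionality
# screening with false-discovery-rate control (the volcano table).

.tto_bin_labels <- c("<3 d", "3-7 d", "1-2 wk", "2 wk-1 mo", ">1 mo")
# day edges: 0-2, 3-7, 8-14, 15-30, >=31 (labels inclusive of their endpoints)
.tto_breaks <- c(0, 3, 8, 15, 31, Inf)

#' Bin onset days into the standard clinical intervals
#'
#' @param days nonnegative integer vector.
#' @return factor with levels `<3 d`, `3-7 d`, `1-2 wk`, `2 wk-1 mo`,
#'   `>1 mo` (day edges 0-2, 3-7, 8-14, 15-30, >=31).
#' @export
tto_bin <- function(days) {
  cut(days, breaks = .tto_breaks, labels = .tto_bin_labels, right = FALSE,
      include.lowest = TRUE)
}

#' Compute time to onset for each report
#'
#' Onset is the event date minus the earliest therapy-start date among the
#' report's target-drug entries, in whole days. Only full-precision
#' (`YYYYMMDD`) dates are used: records with missing or partial start/event
#' dates, with no target therapy entry, or with a negative onset are
#' excluded, and the exclusion tallies are kept in the `exclusions`
#' attribute rather than silently dropped.
#'
#' @param fd a deduplicated, primary-suspect-filtered `faers_data` (with
#'   `$target` set by [filter_primary_suspect()]).
#' @return `onset_records` data.table: `primaryid`, `caseid`, `sex`,
#'   `onset_days`, `bin`; attribute `exclusions` (named counts).
#' @export
compute_onsets <- function(fd) {
  stopifnot(inherits(fd, "faers_data"))
  if (is.null(fd$target)) stop("no target set: run filter_primary_suspect() first")
  drug <- fd$tables$drug
  ther <- fd$tables$ther
  demo <- fd$tables$demo
  tgt <- drug[drug$drugname_norm == fd$target,
              c("primaryid", "drug_seq")]
  th <- merge(tgt, ther, by.x = c("primaryid", "drug_seq"),
              by.y = c("primaryid", "dsg_drug_seq"))
  sd <- parse_faers_date(th$start_dt)
  starts <- data.table(primaryid = th$primaryid[sd$precision == "day"],
                       start = sd$date[sd$precision == "day"])
  starts <- starts[, .(start = min(start)), by = "primaryid"]

  ed <- parse_faers_date(demo$event_dt)
  rec <- data.table(primaryid = demo$primaryid, caseid = demo$caseid,
                    sex = ifelse(demo$sex == "F", "Female",
                                 ifelse(demo$sex == "M", "Male", "Unknown")),
                    event = ed$date, event_ok = ed$precision == "day")
  rec <- merge(rec, starts, by = "primaryid", all.x = TRUE, sort = FALSE)
  n_no_start <- sum(is.na(rec$start))          # no full-precision target start
  n_partial_event <- sum(!is.na(rec$start) & !rec$event_ok)
  rec <- rec[rec$event_ok & !is.na(rec$start)]
  onset <- as.integer(rec$event - rec$start)
  n_negative <- sum(onset < 0)
  keep <- onset >= 0
  out <- data.table(primaryid = rec$primaryid[keep], caseid = rec$caseid[keep],
                    sex = rec$sex[keep], onset_days = onset[keep])
  out[, bin := tto_bin(onset_days)]
  setattr(out, "class", c("onset_records", class(out)))
  setattr(out, "exclusions",
          c(no_full_start_date = as.integer(n_no_start),
            partial_event_date = as.integer(n_partial_event),
            negative_onset = as.integer(n_negative)))
  out
}

#' Pyramid table of onset bins by sex
#'
#' @param records an [compute_onsets()] result.
#' @return `data.table` with one row per bin (all five bins always present,
#'   in order) and one count column per sex plus `total`; bins are
#'   exhaustive and disjoint, so the totals sum to `nrow(records)`.
#' @export
bin_onsets <- function(records) {
  records <- as.data.table(records)
  sexes <- c("Female", "Male", "Unknown")
  out <- data.table(bin = factor(.tto_bin_labels, levels = .tto_bin_labels))
  for (s in sexes) {
    tab <- table(factor(records$bin[records$sex == s], levels = .tto_bin_labels))
    data.table::set(out, j = s, value = as.integer(tab))
  }
  out[, total := Female + Male + Unknown]
  out[]
}

.subset_by_sex <- function(fd, sex_code) {
  keep <- fd$tables$demo$primaryid[fd$tables$demo$sex == sex_code]
  .filter_to_primaryids(fd, keep)
}

#' Gender-stratified volcano table
#'
#' Within each sex stratum the contingency tables are rebuilt against that
#' stratum's own report universe; each PT gets a two-sided Fisher exact
#' p-value on its 2x2 table and a reporting odds ratio (log2 for the
#' volcano x-axis). P-values are Benjamini-Hochberg adjusted across all PTs
#' within the stratum, and a PT is flagged significant when the adjusted p
#' is below `alpha` and `a >= min_count`.
#'
#' @param fd the full deduplicated `faers_data` universe with normalized drug
#'   names (run [normalize_drug_names()] or pass `synonyms`).
#' @param target target drug name.
#' @param synonyms optional synonym table or path.
#' @param alpha FDR significance level (default 0.05).
#' @param min_count minimum observed count `a` for the significant flag.
#' @return `data.table` with columns `event`, `stratum` (`male`/`female`),
#'   `a`, `log2_ror`, `p_value`, `p_adj`, `neg_log10_p_adj`, `significant`.
#'   Empty strata yield no rows (with a warning).
#' @export
stratified_volcano <- function(fd, target, synonyms = NULL, alpha = 0.05,
                               min_count = 3) {
  stopifnot(inherits(fd, "faers_data"))
  if (!"drugname_norm" %in% names(fd$tables$drug)) {
    if (is.null(synonyms))
      stop("drug names not normalized yet: provide a synonym table")
    fd <- normalize_drug_names(fd, synonyms)
  }
  rows <- list()
  for (code in c("M", "F")) {
    s <- if (code == "M") "male" else "female"
    sub <- .subset_by_sex(fd, code)
    if (nrow(sub$tables$demo) == 0) {
      warning(sprintf("stratum %s is empty", s))
      next
    }
    tab <- build_contingency(sub, target, synonyms = synonyms, level = "PT")
    if (nrow(tab) == 0) next
    p <- vapply(seq_len(nrow(tab)), function(i) {
      stats::fisher.test(matrix(c(tab$a[i], tab$b[i], tab$c[i], tab$d[i]),
                                nrow = 2, byrow = TRUE))$p.value
    }, numeric(1))
    ror <- compute_ror(tab)
    res <- data.table(event = tab$event, stratum = s, a = tab$a,
                      log2_ror = log2(ror$ROR), p_value = p,
                      p_adj = stats::p.adjust(p, method = "BH"))
    res[, neg_log10_p_adj := -log10(p_adj)]
    res[, significant := p_adj < alpha & a >= min_count]
    rows[[s]] <- res
  }
  if (length(rows) == 0)
    return(data.table(event = character(), stratum = character(),
                      a = numeric(), log2_ror = numeric(), p_value = numeric(),
                      p_adj = numeric(), neg_log10_p_adj = numeric(),
                      significant = logical()))
  rbindlist(rows)
}
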