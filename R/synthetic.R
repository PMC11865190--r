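# Synthetic spontaneous-report database generator.
#
# Emulates the FAERS quarterly-extract structure closely enough to exercise
# every downstream stage: multi-table cases keyed by caseid/primaryid,
# duplicate case versions, drug role codes, several reactions per report,
# demographics, therapy/event dates with partial-date truncation, outcome
# codes, and configurable planted relative-risk elevations for chosen
# drug-event pairs so recovery is testable against known truth.

#' Configuration for the synthetic report-database generator
#'
#' Builds and validates the generator configuration. Defaults emulate the
#' scale and composition of a single-drug pharmacovigilance extract: the
#' demographic category probabilities are taken from the marginal composition
#' of a published imipenem/cilastatin report series (sex, age bands, reporter
#' occupation, country, route, outcome codes), duplicate case versions occur
#' at the rate seen in full-database deduplication (~0.18 per retained case),
#' reports carry 2.5 reactions on average, and onset times are geometric with
#' a 4-day mean so that most events fall within the first 3 days.
#'
#' @param n_reports number of unique cases to generate (0 allowed).
#' @param n_drugs,n_events size of the drug and event vocabularies.
#' @param background_drug_weights,background_event_weights probability
#'   vectors (sum to 1) for drug and reaction mentions under the null.
#'   Defaults are gently decaying (Zipf-like) frequencies.
#' @param planted_signals `data.frame` with columns `drug`, `event`
#'   (1-based vocabulary indices) and `rr` (relative risk >= 0). For a report
#'   containing a planted drug, each planted event's mention weight is
#'   multiplied by the maximum planted `rr` across the report's drugs and the
#'   weight vector renormalized, which makes `rr` the asymptotic reporting
#'   ratio of the pair.
#' @param drugs_per_report,events_per_report lists `list(mean=, max=)`; counts
#'   are `min(1 + Poisson(mean - 1), max)`, so every report has at least one
#'   drug and one reaction.
#' @param duplicate_rate fraction in `[0, 1)` of cases additionally emitted as
#'   a second, superseding version (same caseid, later receipt date, larger
#'   primaryid). Exactly `round(duplicate_rate * n_reports)` cases are
#'   duplicated.
#' @param sex_probs,age_bin_probs,reporter_probs,country_probs,route_probs,outcome_probs
#'   named probability vectors over the demographic category sets.
#' @param onset_mean_days mean of the geometric onset-day distribution
#'   (event date = therapy start + onset).
#' @param missing_date_rate probability that a therapy-start or event date is
#'   truncated to month (`YYYYMM`) or year (`YYYY`) precision; receipt dates
#'   are always full because deduplication orders on them.
#' @param biased_event optional event index whose reports get a sex
#'   distribution of their own (for stratified-analysis tests).
#' @param biased_event_female_prob probability that a report mentioning
#'   `biased_event` is female (remainder male).
#' @param outcome_second_prob probability a report carries a second outcome
#'   entry (FAERS reports may list several outcomes).
#' @param seed integer RNG seed; fixed seed gives byte-identical output files.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reports = 10000,
                             n_drugs = 50,
                             n_events = 100,
                             background_drug_weights = NULL,
                             background_event_weights = NULL,
                             planted_signals = NULL,
                             drugs_per_report = list(mean = 2, max = 5),
                             events_per_report = list(mean = 2.5, max = 10),
                             duplicate_rate = 0.18,
                             sex_probs = c(F = 1026, M = 1490, UNK = 58) / 2574,
                             age_bin_probs = c(`<20` = 98, `20-40` = 265, `40-60` = 527,
                                               `>=60` = 1517, unknown = 167) / 2574,
                             reporter_probs = c(PH = 1422, OT = 716, MD = 268,
                                                CN = 160, UNK = 7, LW = 1) / 2574,
                             country_probs = c(China = 1764, Other = 432,
                                               France = 272, Japan = 106) / 2574,
                             route_probs = c(`Intravenous drip` = 1547, Intravenous = 541,
                                             Other = 460, Parenteral = 15,
                                             Intraperitoneal = 11) / 2574,
                             outcome_probs = c(OT = 1984, HO = 823, LT = 209, DE = 207,
                                               DS = 62, RI = 12, CA = 2) / 3299,
                             onset_mean_days = 4,
                             missing_date_rate = 0.2,
                             biased_event = NULL,
                             biased_event_female_prob = NULL,
                             outcome_second_prob = 0.28,
                             seed = 1L) {
  stopifnot(length(n_reports) == 1, n_reports >= 0, n_reports == floor(n_reports),
            n_drugs >= 1, n_events >= 1,
            duplicate_rate >= 0, duplicate_rate < 1,
            missing_date_rate >= 0, missing_date_rate <= 1,
            onset_mean_days >= 0,
            drugs_per_report$mean >= 1, drugs_per_report$max >= 1,
            events_per_report$mean >= 1, events_per_report$max >= 1)
  if (is.null(background_drug_weights)) {
    background_drug_weights <- 1 / (seq_len(n_drugs) + 4)
    background_drug_weights <- background_drug_weights / sum(background_drug_weights)
  }
  if (is.null(background_event_weights)) {
    background_event_weights <- 1 / (seq_len(n_events) + 4)
    background_event_weights <- background_event_weights / sum(background_event_weights)
  }
  stopifnot_prob_vector(background_drug_weights, "background_drug_weights")
  stopifnot_prob_vector(background_event_weights, "background_event_weights")
  if (length(background_drug_weights) != n_drugs)
    stop("background_drug_weights must have length n_drugs")
  if (length(background_event_weights) != n_events)
    stop("background_event_weights must have length n_events")
  for (nm in c("sex_probs", "age_bin_probs", "reporter_probs", "country_probs",
               "route_probs", "outcome_probs")) {
    stopifnot_prob_vector(get(nm), nm)
  }
  if (is.null(planted_signals)) {
    planted_signals <- data.table(drug = integer(), event = integer(), rr = numeric())
  } else {
    planted_signals <- as.data.table(planted_signals)
    if (!all(c("drug", "event", "rr") %in% names(planted_signals)))
      stop("planted_signals needs columns drug, event, rr")
    planted_signals <- planted_signals[, .(drug = as.integer(drug),
                                           event = as.integer(event),
                                           rr = as.numeric(rr))]
    if (nrow(planted_signals) > 0) {
      if (any(planted_signals$drug < 1 | planted_signals$drug > n_drugs))
        stop("planted drug index outside 1..n_drugs")
      if (any(planted_signals$event < 1 | planted_signals$event > n_events))
        stop("planted event index outside 1..n_events")
      if (any(!is.finite(planted_signals$rr) | planted_signals$rr < 0))
        stop("planted relative risks must be finite and >= 0")
      if (anyDuplicated(planted_signals[, .(drug, event)]))
        stop("duplicate planted (drug, event) pair")
      # renormalization impossible when a drug's planted probability mass > 1
      mass <- planted_signals[, .(mass = sum(background_event_weights[event] * rr)),
                              by = drug]
      if (any(mass$mass > 1))
        stop(sprintf("planted probability mass > 1 for drug %d; reduce rr or weights",
                     mass$drug[which.max(mass$mass)]))
    }
  }
  if (!is.null(biased_event)) {
    stopifnot(biased_event >= 1, biased_event <= n_events,
              !is.null(biased_event_female_prob),
              biased_event_female_prob >= 0, biased_event_female_prob <= 1)
  }
  structure(list(
    n_reports = as.integer(n_reports), n_drugs = as.integer(n_drugs),
    n_events = as.integer(n_events),
    background_drug_weights = background_drug_weights,
    background_event_weights = background_event_weights,
    planted_signals = planted_signals,
    drugs_per_report = drugs_per_report, events_per_report = events_per_report,
    duplicate_rate = duplicate_rate,
    sex_probs = sex_probs, age_bin_probs = age_bin_probs,
    reporter_probs = reporter_probs, country_probs = country_probs,
    route_probs = route_probs, outcome_probs = outcome_probs,
    onset_mean_days = onset_mean_days, missing_date_rate = missing_date_rate,
    biased_event = biased_event,
    biased_event_female_prob = biased_event_female_prob,
    outcome_second_prob = outcome_second_prob,
    seed = as.integer(seed)), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("synthetic_config:", x$n_reports, "reports,", x$n_drugs, "drugs,",
      x$n_events, "events,", nrow(x$planted_signals), "planted signal(s),",
      "seed", x$seed, "\n")
  invisible(x)
}

drug_label <- function(i) sprintf("DRUG_%03d", i)
event_label <- function(i) sprintf("PT_%03d", i)
soc_of_event <- function(i, n_soc = 8) sprintf("SOC_%02d", ((i - 1) %% n_soc) + 1)

#' Ground truth of planted signals
#'
#' One row per planted (drug, event) pair with its true relative risk; pairs
#' not listed have implicit relative risk 1.
#'
#' @param config a [synthetic_config()].
#' @return `data.table` with columns `drug`, `event` (vocabulary labels as
#'   they appear in the generated files), `drug_index`, `event_index`, `rr`.
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ps <- config$planted_signals
  data.table(drug = drug_label(ps$drug), event = event_label(ps$event),
             drug_index = ps$drug, event_index = ps$event, rr = ps$rr)
}

# integer day offsets for the 2004-01-01 .. 2023-12-31 reporting window
.window_start <- as.Date("2004-01-01")
.window_days <- as.integer(as.Date("2023-12-31") - as.Date("2004-01-01")) + 1L

fmt_date <- function(d) format(d, "%Y%m%d")

truncate_dates <- function(x, rate) {
  if (rate <= 0 || length(x) == 0) return(x)
  u <- stats::runif(length(x))
  to_month <- u < rate / 2
  to_year <- !to_month & u < rate
  x[to_month] <- substr(x[to_month], 1, 6)
  x[to_year] <- substr(x[to_year], 1, 4)
  x
}

#' Generate a synthetic FAERS-style report database
#'
#' Writes the six case tables (`DEMO`, `DRUG`, `REAC`, `THER`, `OUTC`,
#' `RPSR`) in the FAERS quarterly ASCII dialect ("$"-delimited, header line,
#' one record per line), plus a toy PT-to-SOC mapping table and a drug-name
#' synonym table (both tab-separated). Reports are generated independently;
#' for reports containing a planted drug, reaction mentions are drawn from
#' the background event distribution with planted events up-weighted by their
#' relative risk and renormalized. A fixed seed yields byte-identical files.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a bookkeeping list: `files` (named paths), `n_reports`,
#'   `n_duplicates` (extra superseding versions emitted), `ps_counts`
#'   (named vector, unique cases per primary-suspect drug), and `truth`
#'   (the [planted_truth()] table).
#' @export
generate_dataset <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(DEMO = file.path(dir, "DEMO.txt"), DRUG = file.path(dir, "DRUG.txt"),
             REAC = file.path(dir, "REAC.txt"), THER = file.path(dir, "THER.txt"),
             OUTC = file.path(dir, "OUTC.txt"), RPSR = file.path(dir, "RPSR.txt"),
             meddra_map = file.path(dir, "meddra_map.tsv"),
             drug_synonyms = file.path(dir, "drug_synonyms.tsv"))
  out <- with_seed(config$seed, .generate_tables(config))
  fwrite(out$demo, files["DEMO"], sep = "$", quote = FALSE)
  fwrite(out$drug, files["DRUG"], sep = "$", quote = FALSE)
  fwrite(out$reac, files["REAC"], sep = "$", quote = FALSE)
  fwrite(out$ther, files["THER"], sep = "$", quote = FALSE)
  fwrite(out$outc, files["OUTC"], sep = "$", quote = FALSE)
  fwrite(out$rpsr, files["RPSR"], sep = "$", quote = FALSE)
  map <- data.table(pt = event_label(seq_len(config$n_events)),
                    soc = soc_of_event(seq_len(config$n_events)))
  fwrite(map, files["meddra_map"], sep = "\t", quote = FALSE)
  canon <- drug_label(seq_len(config$n_drugs))
  syn <- data.table(raw = c(canon, paste(canon, "INJECTION")),
                    normalized = c(canon, canon))
  fwrite(syn, files["drug_synonyms"], sep = "\t", quote = FALSE)
  invisible(list(files = files, n_reports = config$n_reports,
                 n_duplicates = out$n_duplicates, ps_counts = out$ps_counts,
                 truth = planted_truth(config)))
}

.generate_tables <- function(config) {
  n <- config$n_reports
  empty <- function(...) {
    cols <- c(...)
    setNames(as.data.table(rep(list(character(0)), length(cols))), cols)
  }
  if (n == 0) {
    return(list(
      demo = empty("primaryid", "caseid", "fda_dt", "sex", "age", "age_cod",
                   "occp_cod", "reporter_country", "event_dt"),
      drug = empty("primaryid", "caseid", "drug_seq", "role_cod", "drugname", "route"),
      reac = empty("primaryid", "caseid", "pt"),
      ther = empty("primaryid", "caseid", "dsg_drug_seq", "start_dt"),
      outc = empty("primaryid", "caseid", "outc_cod"),
      rpsr = empty("primaryid", "caseid", "rpsr_cod"),
      n_duplicates = 0L,
      ps_counts = setNames(integer(config$n_drugs), drug_label(seq_len(config$n_drugs)))))
  }
  caseid <- 100000L + seq_len(n)
  primaryid <- caseid * 10L + 1L
  fda <- .window_start + sample.int(.window_days, n, replace = TRUE) - 1L

  # drug mentions (with replacement: repeated listings of a drug do occur)
  kd <- pmin(1L + stats::rpois(n, config$drugs_per_report$mean - 1),
             config$drugs_per_report$max)
  drug_idx <- sample.int(config$n_drugs, sum(kd), replace = TRUE,
                         prob = config$background_drug_weights)
  drug_report <- rep(seq_len(n), kd)
  drug_seq <- sequence(kd)
  role <- c("SS", "C", "I")[(drug_seq - 2L) %% 3L + 1L]
  role[drug_seq == 1L] <- "PS"

  # reaction mentions: background weights, up-weighted for planted drug sets
  ke <- pmin(1L + stats::rpois(n, config$events_per_report$mean - 1),
             config$events_per_report$max)
  event_report <- rep(seq_len(n), ke)
  event_idx <- sample.int(config$n_events, sum(ke), replace = TRUE,
                          prob = config$background_event_weights)
  planted <- config$planted_signals
  if (nrow(planted) > 0) {
    pd <- unique(planted$drug)
    hit <- unique(data.table(report = drug_report, drug = drug_idx)[drug %in% pd])
    if (nrow(hit) > 0) {
      sig <- hit[, .(sig = paste(sort(drug), collapse = ",")), by = "report"]
      for (s in sort(unique(sig$sig))) {
        drugs_s <- as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
        w <- config$background_event_weights
        pl <- planted[planted$drug %in% drugs_s,
                      .(mult = max(rr)), by = "event"]
        w[pl$event] <- w[pl$event] * pl$mult
        w <- w / sum(w)
        rows <- which(event_report %in% sig$report[sig$sig == s])
        event_idx[rows] <- sample.int(config$n_events, length(rows),
                                      replace = TRUE, prob = w)
      }
    }
  }

  # demographics
  sex <- sample(names(config$sex_probs), n, replace = TRUE, prob = config$sex_probs)
  if (!is.null(config$biased_event)) {
    biased_reports <- unique(event_report[event_idx == config$biased_event])
    if (length(biased_reports) > 0) {
      f <- stats::runif(length(biased_reports)) < config$biased_event_female_prob
      sex[biased_reports] <- ifelse(f, "F", "M")
    }
  }
  sex_out <- ifelse(sex == "UNK", "", sex)
  bin <- sample(seq_along(config$age_bin_probs), n, replace = TRUE,
                prob = config$age_bin_probs)
  age_years <- rep(NA_real_, n)
  age_years[bin == 1] <- sample(1:19, sum(bin == 1), replace = TRUE)
  age_years[bin == 2] <- sample(20:39, sum(bin == 2), replace = TRUE)
  age_years[bin == 3] <- sample(40:59, sum(bin == 3), replace = TRUE)
  age_years[bin == 4] <- sample(60:90, sum(bin == 4), replace = TRUE)
  cod <- sample(c("YR", "MON", "DEC"), n, replace = TRUE, prob = c(0.92, 0.05, 0.03))
  age_val <- ifelse(cod == "YR", age_years,
                    ifelse(cod == "MON", age_years * 12, age_years / 10))
  cod[is.na(age_years)] <- ""
  age_out <- ifelse(is.na(age_years), "", as.character(age_val))
  occp <- sample(names(config$reporter_probs), n, replace = TRUE,
                 prob = config$reporter_probs)
  occp <- ifelse(occp == "UNK", "", occp)
  country <- sample(names(config$country_probs), n, replace = TRUE,
                    prob = config$country_probs)
  route_drug <- sample(names(config$route_probs), sum(kd), replace = TRUE,
                       prob = config$route_probs)

  # therapy start, onset, receipt; partial-date truncation on start/event only
  start <- .window_start + sample.int(.window_days, n, replace = TRUE) - 1L
  p_onset <- 1 / (1 + config$onset_mean_days)
  onset <- stats::rgeom(n, p_onset)
  event_date <- start + onset
  start_str <- truncate_dates(fmt_date(start), config$missing_date_rate)
  event_str <- truncate_dates(fmt_date(event_date), config$missing_date_rate)

  # outcomes: one entry per report, sometimes a second
  n2 <- stats::runif(n) < config$outcome_second_prob
  outc_report <- c(seq_len(n), which(n2))
  outc_cod <- sample(names(config$outcome_probs), length(outc_report),
                     replace = TRUE, prob = config$outcome_probs)
  o <- order(outc_report)
  outc_report <- outc_report[o]; outc_cod <- outc_cod[o]

  rpsr_cod <- sample(c("FRGN", "HP", "CSM"), n, replace = TRUE,
                     prob = c(0.5, 0.4, 0.1))

  # raw drug-name variants exercise synonym normalization downstream
  variant <- sample.int(3L, sum(kd), replace = TRUE, prob = c(0.6, 0.25, 0.15))
  canon <- drug_label(drug_idx)
  drugname <- canon
  drugname[variant == 2L] <- tolower(canon[variant == 2L])
  drugname[variant == 3L] <- paste(canon[variant == 3L], "INJECTION")

  demo <- data.table(primaryid = primaryid, caseid = caseid, fda_dt = fmt_date(fda),
                     sex = sex_out, age = age_out, age_cod = cod, occp_cod = occp,
                     reporter_country = country, event_dt = event_str)
  drug <- data.table(primaryid = primaryid[drug_report], caseid = caseid[drug_report],
                     drug_seq = drug_seq, role_cod = role, drugname = drugname,
                     route = route_drug)
  reac <- data.table(primaryid = primaryid[event_report], caseid = caseid[event_report],
                     pt = event_label(event_idx))
  ther <- data.table(primaryid = primaryid[drug_report], caseid = caseid[drug_report],
                     dsg_drug_seq = drug_seq, start_dt = start_str[drug_report])
  outc <- data.table(primaryid = primaryid[outc_report], caseid = caseid[outc_report],
                     outc_cod = outc_cod)
  rpsr <- data.table(primaryid = primaryid, caseid = caseid, rpsr_cod = rpsr_cod)

  # superseding duplicate versions: same caseid, later receipt, larger primaryid
  n_dup <- round(config$duplicate_rate * n)
  if (n_dup > 0) {
    dup_reports <- sort(sample.int(n, n_dup))
    dup_pids <- primaryid[dup_reports]
    lag <- sample.int(365L, n_dup, replace = TRUE)
    demo2 <- demo[dup_reports]
    demo2[, primaryid := caseid * 10L + 2L]
    demo2[, fda_dt := fmt_date(as.Date(fda_dt, "%Y%m%d") + lag)]
    bump <- function(dt) {
      keep <- dt[dt$primaryid %in% dup_pids]
      keep[, primaryid := (primaryid %/% 10L) * 10L + 2L]
      keep
    }
    demo <- rbind(demo, demo2)
    drug <- rbind(drug, bump(drug)); reac <- rbind(reac, bump(reac))
    ther <- rbind(ther, bump(ther)); outc <- rbind(outc, bump(outc))
    rpsr <- rbind(rpsr, bump(rpsr))
    for (dt in list(demo, drug, reac, ther, outc, rpsr)) setorder(dt, primaryid)
  }

  ps_idx <- drug_idx[drug_seq == 1L]
  ps_counts <- tabulate(ps_idx, nbins = config$n_drugs)
  names(ps_counts) <- drug_label(seq_len(config$n_drugs))
  list(demo = demo, drug = drug, reac = reac, ther = ther, outc = outc,
       rpsr = rpsr, n_duplicates = as.integer(n_dup), ps_counts = ps_counts)
}
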