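# Fixture builders: tiny hand-written "$"-delimited table sets, and
# in-memory synthetic table sets (skipping the file round-trip, which has
# its own tests).

faers_headers <- c(
  DEMO = "primaryid$caseid$fda_dt$sex$age$age_cod$occp_cod$reporter_country$event_dt",
  DRUG = "primaryid$caseid$drug_seq$role_cod$drugname$route",
  REAC = "primaryid$caseid$pt",
  THER = "primaryid$caseid$dsg_drug_seq$start_dt",
  OUTC = "primaryid$caseid$outc_cod",
  RPSR = "primaryid$caseid$rpsr_cod")

# write the six tables from character record vectors (header added)
write_tiny_faers <- function(dir, DEMO = character(), DRUG = character(),
                             REAC = character(), THER = character(),
                             OUTC = character(), RPSR = character()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- list(DEMO = DEMO, DRUG = DRUG, REAC = REAC, THER = THER,
               OUTC = OUTC, RPSR = RPSR)
  for (nm in names(recs))
    writeLines(c(faers_headers[nm], recs[[nm]]), file.path(dir, paste0(nm, ".txt")))
  dir
}

# demo record with sensible defaults; override fields positionally by name
demo_rec <- function(primaryid, caseid, fda_dt = "20200101", sex = "M",
                     age = "50", age_cod = "YR", occp = "MD",
                     country = "China", event_dt = "20200105") {
  paste(primaryid, caseid, fda_dt, sex, age, age_cod, occp, country, event_dt,
        sep = "$")
}

drug_rec <- function(primaryid, caseid, seq = 1, role = "PS",
                     name = "TARGET", route = "Intravenous") {
  paste(primaryid, caseid, seq, role, name, route, sep = "$")
}

tiny_synonyms <- function(extra = NULL) {
  syn <- data.table::data.table(
    raw = c("TARGET", "TARGET INJECTION", "OTHERDRUG"),
    normalized = c("TARGET", "TARGET", "OTHERDRUG"))
  if (!is.null(extra)) syn <- rbind(syn, extra)
  syn
}

# in-memory generation: the generator's tables without touching disk
gen_tables <- function(config) {
  faersignal:::with_seed(config$seed, faersignal:::.generate_tables(config))
}

gen_fd <- function(config) {
  tabs <- gen_tables(config)
  fd <- as_faers_data(tabs[c("demo", "drug", "reac", "ther", "outc", "rpsr")])
  attr(fd, "bookkeeping") <- tabs[c("n_duplicates", "ps_counts")]
  fd
}

canon_synonyms <- function(n_drugs) {
  canon <- sprintf("DRUG_%03d", seq_len(n_drugs))
  data.table::data.table(raw = c(canon, paste(canon, "INJECTION")),
                         normalized = c(canon, canon))
}

# empirical relative reporting ratio by direct tabulation of generated
# tables, conditioning on drug presence in any role:
# [P(event | reports with drug)] / [P(event | reports without drug)]
empirical_rr <- function(tabs, drug_name, event_name) {
  drug <- tabs$drug; reac <- tabs$reac; demo <- tabs$demo
  with_drug <- unique(drug$primaryid[startsWith(drug$drugname, drug_name) |
                                       startsWith(toupper(drug$drugname), drug_name)])
  with_event <- unique(reac$primaryid[reac$pt == event_name])
  all_ids <- demo$primaryid
  n_d <- length(with_drug)
  n_nd <- length(all_ids) - n_d
  a <- length(intersect(with_drug, with_event))
  c_ <- length(with_event) - a
  (a / n_d) / (c_ / n_nd)
}
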