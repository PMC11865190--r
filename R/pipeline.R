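# Assembly of the full pipeline: raw "$"-delimited tables -> deduplicated
# universe -> target primary-suspect set -> descriptive tables, PT/SOC
# signal tables, gender volcano, onset pyramid, and a run manifest with the
# stage counters (retrieved -> deduplicated -> PS-filtered) and input
# checksums. Identical config + inputs give identical outputs.

#' Pipeline configuration
#'
#' Validates everything that can be checked before any I/O (enumerated
#' options, threshold types); path existence is checked at run start by
#' [run_pipeline()].
#'
#' @param input either a directory with `DEMO.txt` ... `RPSR.txt` or a named
#'   vector of the six file paths.
#' @param target target drug name.
#' @param synonyms path to the drug-name synonym table (tab-separated).
#' @param meddra_map path to the PT-to-SOC map (tab-separated).
#' @param out_dir output directory.
#' @param thresholds a [signal_thresholds()] object.
#' @param ebgm_mode `"mgps"` or `"simple"` (see [compute_signal_stats()]).
#' @param level `"pt"`, `"soc"` or `"both"`.
#' @param prior_fit_level `"per_level"` (fit the MGPS prior separately at PT
#'   and SOC level) or `"pt"` (reuse the PT-level prior for SOC tables).
#' @param stratify compute the gender-stratified volcano table.
#' @param seed integer seed recorded in the manifest and used for any
#'   resampling step (the core pipeline is deterministic).
#' @param country_aliases named character vector of country-spelling merges.
#' @param verbose print stage counters as the pipeline runs.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input, target, synonyms, meddra_map, out_dir,
                            thresholds = signal_thresholds(),
                            ebgm_mode = "mgps",
                            level = "both",
                            prior_fit_level = "per_level",
                            stratify = TRUE,
                            seed = 1L,
                            country_aliases = character(),
                            verbose = FALSE) {
  if (!ebgm_mode %in% c("mgps", "simple"))
    stop("unknown ebgm_mode: ", ebgm_mode, " (must be 'mgps' or 'simple')")
  if (!level %in% c("pt", "soc", "both"))
    stop("unknown level: ", level, " (must be 'pt', 'soc' or 'both')")
  if (!prior_fit_level %in% c("per_level", "pt"))
    stop("unknown prior_fit_level: ", prior_fit_level)
  stopifnot(inherits(thresholds, "signal_thresholds"),
            is.character(target), length(target) == 1, nzchar(target))
  structure(list(input = input, target = target, synonyms = synonyms,
                 meddra_map = meddra_map, out_dir = out_dir,
                 thresholds = thresholds, ebgm_mode = ebgm_mode,
                 level = level, prior_fit_level = prior_fit_level,
                 stratify = isTRUE(stratify), seed = as.integer(seed),
                 country_aliases = country_aliases,
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; `thresholds` may be a
#' nested block with any subset of the [signal_thresholds()] fields.
#' Unknown keys are a schema error listing the offending names.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), "thresholds")
  bad <- setdiff(names(raw), c(known, "thresholds"))
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$thresholds)) {
    bad_th <- setdiff(names(raw$thresholds), names(formals(signal_thresholds)))
    if (length(bad_th) > 0)
      stop("unknown thresholds key(s): ", paste(bad_th, collapse = ", "))
    raw$thresholds <- do.call(signal_thresholds, raw$thresholds)
  }
  do.call(pipeline_config, raw)
}

.stage_msg <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full signal-detection pipeline
#'
#' Stages: parse the six ASCII tables; deduplicate case versions; normalize
#' drug names; filter to target primary-suspect reports; write the
#' demographic summary and yearly trend; build PT (and SOC) contingency
#' tables against the full deduplicated universe and compute the four
#' disproportionality statistics with the joint signal criteria; optionally
#' the gender-stratified volcano and the time-to-onset pyramid; and a JSON
#' run manifest recording input checksums, the configuration, stage counts
#' and the package version. Any stage failure aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the output `files`, the `manifest`, and
#'   the in-memory results (`demographics`, `signals_pt`, `signals_soc`,
#'   `volcano`, `tto`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "setup"
  result <- tryCatch({
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character()

    stage <- "ingest"
    fd <- read_ascii_tables(config$input)
    .stage_msg(config$verbose, "ingest: %d DEMO rows (%d malformed lines skipped)",
               nrow(fd$tables$demo), sum(fd$log$malformed))

    stage <- "deduplicate"
    fd <- deduplicate(fd)
    .stage_msg(config$verbose, "dedup: retrieved=%d removed=%d retained=%d",
               fd$log$dedup$retrieved, fd$log$dedup$removed, fd$log$dedup$retained)

    stage <- "normalize"
    synonyms <- read_drug_synonyms(config$synonyms)
    fd <- normalize_drug_names(fd, synonyms)

    stage <- "primary_suspect_filter"
    fdt <- filter_primary_suspect(fd, config$target, synonyms)
    .stage_msg(config$verbose, "primary suspect: %d reports for %s",
               fdt$log$ps_filtered, fdt$target)

    stage <- "demographics"
    demog <- summarize_demographics(fdt, config$country_aliases)
    files <- c(files, write_demographic_summary(
      demog, file.path(config$out_dir, "table1")))

    stage <- "signal_pt"
    signals_pt <- NULL
    pt_prior <- NULL
    if (config$level %in% c("pt", "both")) {
      tab_pt <- build_contingency(fd, config$target, level = "PT")
      signals_pt <- compute_signal_stats(tab_pt, config$thresholds,
                                         ebgm_mode = config$ebgm_mode)
      pt_prior <- attr(signals_pt, "prior")
      signals_pt <- rank_signals(signals_pt, "ROR")
      p <- file.path(config$out_dir, "signals_pt.tsv")
      write_signal_table(signals_pt, p)
      files <- c(files, signals_pt = p)
      .stage_msg(config$verbose, "PT level: %d events, %d signals",
                 nrow(signals_pt), sum(signals_pt$signal, na.rm = TRUE))
    }

    stage <- "signal_soc"
    signals_soc <- NULL
    unmapped <- character()
    if (config$level %in% c("soc", "both")) {
      map <- read_meddra_map(config$meddra_map)
      tab_soc <- build_contingency(fd, config$target, level = "SOC",
                                   meddra_map = map)
      unmapped <- attr(tab_soc, "unmapped")
      soc_prior <- if (config$prior_fit_level == "pt" && !is.null(pt_prior))
        pt_prior else NULL
      signals_soc <- compute_signal_stats(tab_soc, config$thresholds,
                                          ebgm_mode = config$ebgm_mode,
                                          prior = soc_prior)
      signals_soc <- rank_signals(signals_soc, "ROR")
      p <- file.path(config$out_dir, "signals_soc.tsv")
      write_signal_table(signals_soc, p)
      files <- c(files, signals_soc = p)
      .stage_msg(config$verbose, "SOC level: %d classes, %d signals (%d unmapped PTs)",
                 nrow(signals_soc), sum(signals_soc$signal, na.rm = TRUE),
                 length(unmapped))
    }

    stage <- "stratified_volcano"
    volcano <- NULL
    if (config$stratify) {
      volcano <- stratified_volcano(fd, config$target)
      p <- file.path(config$out_dir, "volcano.tsv")
      fwrite(volcano, p, sep = "\t", quote = FALSE)
      files <- c(files, volcano = p)
    }

    stage <- "time_to_onset"
    onsets <- compute_onsets(fdt)
    pyramid <- bin_onsets(onsets)
    p <- file.path(config$out_dir, "tto_pyramid.tsv")
    fwrite(pyramid, p, sep = "\t", quote = FALSE)
    files <- c(files, tto_pyramid = p)

    stage <- "manifest"
    input_paths <- if (length(config$input) == 1 && dir.exists(config$input))
      list.files(config$input, full.names = TRUE) else unlist(config$input)
    manifest <- list(
      package = "faersignal",
      version = as.character(utils::packageVersion("faersignal")),
      target = fdt$target,
      seed = config$seed,
      config = list(ebgm_mode = config$ebgm_mode, level = config$level,
                    prior_fit_level = config$prior_fit_level,
                    stratify = config$stratify,
                    thresholds = unclass(config$thresholds)),
      inputs = as.list(tools::md5sum(sort(input_paths))),
      counts = list(
        retrieved = fd$log$dedup$retrieved,
        deduplicated = fd$log$dedup$retained,
        ps_filtered = fdt$log$ps_filtered,
        malformed_lines = sum(fd$log$malformed),
        outcome_entries = demog$total_outcome_entries,
        tto_records = nrow(onsets),
        tto_exclusions = as.list(attr(onsets, "exclusions")),
        unmapped_pts = length(unmapped)))
    p <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    files <- c(files, manifest = p)

    list(files = files, manifest = manifest, demographics = demog,
         signals_pt = signals_pt, signals_soc = signals_soc,
         volcano = volcano, tto = pyramid, onsets = onsets)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

#' Generate a synthetic dataset from a config file or object
#'
#' Writes the generator outputs plus the planted ground truth
#' (`planted_truth.tsv`) alongside, for stage-level testing and pipeline
#' validation.
#'
#' @param config a [synthetic_config()], or the path to a YAML file whose
#'   keys are `synthetic_config()` arguments (`planted_signals` as a list of
#'   `{drug, event, rr}` records). Unknown keys are a schema error listing
#'   the offending names.
#' @param out_dir output directory.
#' @return invisibly, the [generate_dataset()] bookkeeping list plus the
#'   truth path.
#' @export
simulate_command <- function(config, out_dir) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    raw <- yaml::read_yaml(config)
    bad <- setdiff(names(raw), names(formals(synthetic_config)))
    if (length(bad) > 0)
      stop("unknown synthetic config key(s): ", paste(bad, collapse = ", "))
    if (!is.null(raw$planted_signals))
      raw$planted_signals <- rbindlist(lapply(raw$planted_signals, as.data.table))
    config <- do.call(synthetic_config, raw)
  }
  stopifnot(inherits(config, "synthetic_config"))
  info <- generate_dataset(config, out_dir)
  truth_path <- file.path(out_dir, "planted_truth.tsv")
  fwrite(planted_truth(config), truth_path, sep = "\t", quote = FALSE)
  info$files <- c(info$files, planted_truth = truth_path)
  invisible(info)
}
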