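# Reading the FAERS quarterly ASCII dialect and reducing it to one clean
# report per case: parse, deduplicate case versions, normalize drug names,
# filter to the target drug as primary suspect.

.faers_table_names <- c("DEMO", "DRUG", "REAC", "THER", "OUTC", "RPSR")

# mandatory columns per table (after ISR/primaryid aliasing)
.mandatory_cols <- list(
  DEMO = c("primaryid", "caseid", "fda_dt"),
  DRUG = c("primaryid", "drugname", "role_cod"),
  REAC = c("primaryid", "pt"),
  THER = c("primaryid", "start_dt"),
  OUTC = c("primaryid", "outc_cod"),
  RPSR = c("primaryid")
)

# legacy FAERS headers: ISR was renamed primaryid, CASE to caseid
.column_aliases <- c(isr = "primaryid", "case" = "caseid", gndr_cod = "sex")

.read_dollar_file <- function(path, table_name) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0)
    stop(sprintf("file %s (%s) is empty: no header line", path, table_name))
  header <- strsplit(lines[1], "$", fixed = TRUE)[[1]]
  header <- tolower(trimws(header))
  hit <- header %in% names(.column_aliases)
  header[hit] <- .column_aliases[header[hit]]
  need <- .mandatory_cols[[table_name]]
  missing_col <- setdiff(need, header)
  if (length(missing_col) > 0)
    stop(sprintf("file %s (%s) lacks mandatory column(s): %s",
                 path, table_name, paste(missing_col, collapse = ", ")))
  body <- lines[-1]
  body <- body[nzchar(body)]
  nfields <- nchar(body) - nchar(gsub("$", "", body, fixed = TRUE)) + 1L
  bad <- nfields != length(header)
  n_malformed <- sum(bad)
  body <- body[!bad]
  if (length(body) == 0) {
    dt <- setNames(as.data.table(rep(list(character(0)), length(header))), header)
  } else {
    dt <- fread(text = paste(c(paste(header, collapse = "$"), body), collapse = "\n"),
                sep = "$", header = TRUE, colClasses = "character",
                na.strings = NULL, quote = "")
  }
  list(table = dt, malformed = n_malformed)
}

#' Read a set of FAERS-dialect ASCII tables
#'
#' Parses the six case tables of a FAERS quarterly extract: "$"-delimited
#' text with a header line and one record per line. Legacy column names
#' (`ISR`, `CASE`) are aliased to `primaryid`/`caseid`. Lines whose field
#' count does not match the header are counted as malformed and skipped, not
#' silently dropped: the per-file tallies are kept in the object's log.
#'
#' @param paths either a directory containing `DEMO.txt` ... `RPSR.txt`, or a
#'   named character vector/list with elements `DEMO`, `DRUG`, `REAC`,
#'   `THER`, `OUTC`, `RPSR`.
#' @return a `faers_data` object: list with `tables` (data.tables `demo`,
#'   `drug`, `reac`, `ther`, `outc`, `rpsr`, all-character columns) and `log`
#'   (`rows` and `malformed` counts per table, plus stage counters added by
#'   later steps).
#' @export
read_ascii_tables <- function(paths) {
  if (length(paths) == 1 && is.character(paths) && dir.exists(paths)) {
    paths <- setNames(file.path(paths, paste0(.faers_table_names, ".txt")),
                      .faers_table_names)
  }
  paths <- unlist(paths)
  missing_tab <- setdiff(.faers_table_names, names(paths))
  if (length(missing_tab) > 0)
    stop("missing input table(s): ", paste(missing_tab, collapse = ", "))
  for (nm in .faers_table_names) {
    if (!file.exists(paths[[nm]]))
      stop(sprintf("input file for %s not found: %s", nm, paths[[nm]]))
  }
  tables <- list(); malformed <- integer(); rows <- integer()
  for (nm in .faers_table_names) {
    parsed <- .read_dollar_file(paths[[nm]], nm)
    tables[[tolower(nm)]] <- parsed$table
    malformed[nm] <- parsed$malformed
    rows[nm] <- nrow(parsed$table)
  }
  structure(list(tables = tables,
                 log = list(rows = rows, malformed = malformed)),
            class = "faers_data")
}

#' Assemble a `faers_data` object from in-memory tables
#'
#' Convenience constructor for table sets that did not come from disk (e.g.
#' generated programmatically): equivalent to writing the six tables in the
#' ASCII dialect and re-reading them, minus the file round-trip. All columns
#' are coerced to character, matching [read_ascii_tables()] output.
#'
#' @param tables named list with elements `demo`, `drug`, `reac`, `ther`,
#'   `outc`, `rpsr` (data.frames with the dialect's column names).
#' @return a `faers_data` object.
#' @export
as_faers_data <- function(tables) {
  need <- tolower(.faers_table_names)
  missing_tab <- setdiff(need, names(tables))
  if (length(missing_tab) > 0)
    stop("missing table(s): ", paste(missing_tab, collapse = ", "))
  out <- list()
  for (nm in need) {
    dt <- as.data.table(tables[[nm]])
    mand <- .mandatory_cols[[toupper(nm)]]
    miss <- setdiff(mand, names(dt))
    if (length(miss) > 0)
      stop(sprintf("table %s lacks mandatory column(s): %s", nm,
                   paste(miss, collapse = ", ")))
    for (cc in names(dt)) data.table::set(dt, j = cc, value = as.character(dt[[cc]]))
    out[[nm]] <- dt
  }
  rows <- vapply(out, nrow, integer(1))
  names(rows) <- toupper(names(rows))
  structure(list(tables = out,
                 log = list(rows = rows,
                            malformed = setNames(integer(length(rows)),
                                                 names(rows)))),
            class = "faers_data")
}

#' @export
print.faers_data <- function(x, ...) {
  cat("faers_data:", nrow(x$tables$demo), "DEMO rows\n")
  cat("  rows:", paste(sprintf("%s=%d", names(x$log$rows), x$log$rows),
                       collapse = " "), "\n")
  if (sum(x$log$malformed) > 0)
    cat("  malformed lines skipped:",
        paste(sprintf("%s=%d", names(x$log$malformed), x$log$malformed),
              collapse = " "), "\n")
  if (!is.null(x$log$dedup))
    cat(sprintf("  dedup: retrieved=%d removed=%d retained=%d\n",
                x$log$dedup$retrieved, x$log$dedup$removed, x$log$dedup$retained))
  if (!is.null(x$target)) cat("  target:", x$target, "\n")
  invisible(x)
}

.filter_to_primaryids <- function(fd, keep) {
  fd$tables <- lapply(fd$tables, function(dt) dt[dt$primaryid %in% keep])
  fd
}

#' Remove duplicate case versions
#'
#' A FAERS case may appear under several versions (same `caseid`, different
#' `primaryid`). One record per case is kept: the version with the latest
#' receipt date (`fda_dt`; partial dates sort by their padded value), ties
#' broken by the numerically largest `primaryid`. The operation is
#' idempotent and its counters (retrieved, removed, retained) satisfy
#' retrieved - removed = retained.
#'
#' @param fd a `faers_data` object.
#' @return the deduplicated `faers_data`, with `log$dedup` counters.
#' @export
deduplicate <- function(fd) {
  stopifnot(inherits(fd, "faers_data"))
  demo <- fd$tables$demo
  retrieved <- nrow(demo)
  if (retrieved == 0) {
    fd$log$dedup <- list(retrieved = 0L, removed = 0L, retained = 0L)
    return(fd)
  }
  key <- data.table(caseid = demo$caseid,
                    primaryid = demo$primaryid,
                    dkey = date_sort_key(demo$fda_dt),
                    pid_num = suppressWarnings(as.numeric(demo$primaryid)))
  key$pid_num[is.na(key$pid_num)] <- -Inf
  setorderv(key, c("caseid", "dkey", "pid_num"))
  keep <- key[, .SD[.N], by = "caseid"]$primaryid
  fd <- .filter_to_primaryids(fd, keep)
  retained <- length(unique(keep))
  fd$log$dedup <- list(retrieved = retrieved,
                       removed = retrieved - retained,
                       retained = retained)
  fd
}

#' Read a drug-name synonym table
#'
#' Two-column tab-separated file mapping raw drug-name strings to one
#' normalized ingredient name (RxNorm-derived in real use). Both columns are
#' normalized with [normalize_drug_name()] on load, so lookups are
#' case/whitespace-insensitive.
#'
#' @param path file path.
#' @return `data.table` with columns `raw`, `normalized`.
#' @export
read_drug_synonyms <- function(path) {
  syn <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
               na.strings = NULL, quote = "")
  if (ncol(syn) < 2) stop("synonym table needs two columns: raw, normalized")
  setnames(syn, 1:2, c("raw", "normalized"))
  syn$raw <- normalize_drug_name(syn$raw)
  syn$normalized <- normalize_drug_name(syn$normalized)
  unique(syn[, c("raw", "normalized")])
}

#' Normalize drug names against a synonym table
#'
#' Adds a `drugname_norm` column to the DRUG table: names are trimmed,
#' whitespace-collapsed and upper-cased, then mapped through the synonym
#' table by exact match; names absent from the table keep their normalized
#' spelling.
#'
#' @param fd a `faers_data` object.
#' @param synonyms synonym `data.table` from [read_drug_synonyms()] or a path.
#' @return `fd` with the annotated DRUG table.
#' @export
normalize_drug_names <- function(fd, synonyms) {
  stopifnot(inherits(fd, "faers_data"))
  if (is.character(synonyms)) synonyms <- read_drug_synonyms(synonyms)
  if (nrow(synonyms) == 0) stop("empty synonym table")
  drug <- copy(fd$tables$drug)
  norm <- normalize_drug_name(drug$drugname)
  idx <- match(norm, synonyms$raw)
  drug[, drugname_norm := ifelse(is.na(idx), norm, synonyms$normalized[idx])]
  fd$tables$drug <- drug
  fd
}

#' Filter to reports with the target drug as primary suspect
#'
#' Keeps reports having at least one drug entry whose normalized name equals
#' the target and whose role code is `PS`. Matching is case-insensitive
#' after trimming and collapsing internal whitespace (via the synonym table).
#'
#' @param fd a `faers_data` object (deduplicated).
#' @param target target drug name (any synonym spelling).
#' @param synonyms synonym table or path (see [read_drug_synonyms()]).
#' @return the filtered `faers_data`; `log$ps_filtered` holds the retained
#'   report count and `$target` the normalized target name.
#' @export
filter_primary_suspect <- function(fd, target, synonyms) {
  stopifnot(inherits(fd, "faers_data"))
  if (is.character(synonyms)) synonyms <- read_drug_synonyms(synonyms)
  if (nrow(synonyms) == 0) stop("empty synonym table")
  fd <- normalize_drug_names(fd, synonyms)
  target_norm <- normalize_drug_name(target)
  idx <- match(target_norm, synonyms$raw)
  if (!is.na(idx)) target_norm <- synonyms$normalized[idx]
  drug <- fd$tables$drug
  keep <- unique(drug$primaryid[drug$drugname_norm == target_norm &
                                  drug$role_cod == "PS"])
  fd <- .filter_to_primaryids(fd, keep)
  fd$target <- target_norm
  fd$log$ps_filtered <- length(keep)
  fd
}
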