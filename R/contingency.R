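# 2x2 contingency tables for drug-event pairs against the database
# background, at MedDRA PT or SOC level. The counting unit is the report: a
# report contributes at most once to each (drug, event) cell even if the PT
# repeats within it, and SOC-level counting deduplicates one level up, to
# distinct (report, SOC) pairs.

#' Read a PT-to-SOC mapping table
#'
#' Two-column tab-separated file mapping each MedDRA preferred term to
#' exactly one (primary) system organ class. Conflicting duplicate rows are
#' an error; identical duplicates are collapsed.
#'
#' @param path file path.
#' @return a `meddra_map` data.table with columns `pt`, `soc`.
#' @export
read_meddra_map <- function(path) {
  map <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
               na.strings = NULL, quote = "")
  if (ncol(map) < 2) stop("MedDRA map needs two columns: pt, soc")
  setnames(map, 1:2, c("pt", "soc"))
  map <- unique(map[, c("pt", "soc")])
  dup <- map$pt[duplicated(map$pt)]
  if (length(dup) > 0)
    stop("PT(s) mapped to more than one SOC: ",
         paste(unique(dup), collapse = ", "))
  structure(map, class = c("meddra_map", class(map)))
}

#' Annotate reactions with their system organ class
#'
#' Joins the reaction table to the PT-to-SOC map. PTs absent from the map are
#' annotated `NA` and collected into the `unmapped` attribute: they stay
#' usable at PT level but are excluded from SOC-level tables.
#'
#' @param reactions data.table with a `pt` column (e.g. the REAC table).
#' @param map a [read_meddra_map()] table.
#' @return the annotated data.table with an added `soc` column and an
#'   `unmapped` attribute (character vector of unmapped PTs).
#' @export
map_pt_to_soc <- function(reactions, map) {
  reactions <- as.data.table(reactions)
  idx <- match(reactions$pt, map$pt)
  out <- copy(reactions)
  out[, soc := map$soc[idx]]
  attr(out, "unmapped") <- sort(unique(reactions$pt[is.na(idx)]))
  out
}

#' Build 2x2 contingency tables for every event of a target drug
#'
#' For each event label observed among the target drug's primary-suspect
#' reports, counts against the full deduplicated report universe:
#' `a` reports with target drug and event, `b` with drug without event,
#' `c` with event without drug, `d` with neither; `N = a+b+c+d` is the
#' universe size and `E = (a+b)(a+c)/N` the expected count under
#' independence.
#'
#' @param fd the full deduplicated `faers_data` universe (all drugs).
#' @param target target drug name.
#' @param synonyms synonym table or path (see [read_drug_synonyms()]); may be
#'   omitted when `fd` already carries normalized drug names.
#' @param level `"PT"` or `"SOC"`.
#' @param meddra_map a [read_meddra_map()] table (required for SOC level).
#' @return a `data.table` of class `contingency_tables` with columns `event`,
#'   `level`, `a`, `b`, `c`, `d`, `N`, `E`, ordered by decreasing `a`;
#'   attributes `target`, `n_target` (= a+b), `N`, and for SOC level
#'   `unmapped` (PTs without a SOC).
#' @export
build_contingency <- function(fd, target, synonyms = NULL, level = c("PT", "SOC"),
                              meddra_map = NULL) {
  stopifnot(inherits(fd, "faers_data"))
  level <- match.arg(level)
  drug <- fd$tables$drug
  if (!"drugname_norm" %in% names(drug)) {
    if (is.null(synonyms))
      stop("drug names not normalized yet: provide a synonym table")
    fd <- normalize_drug_names(fd, synonyms)
    drug <- fd$tables$drug
  }
  target_norm <- normalize_drug_name(target)
  if (!is.null(synonyms)) {
    if (is.character(synonyms)) synonyms <- read_drug_synonyms(synonyms)
    idx <- match(target_norm, synonyms$raw)
    if (!is.na(idx)) target_norm <- synonyms$normalized[idx]
  }
  N <- nrow(fd$tables$demo)
  target_ids <- unique(drug$primaryid[drug$drugname_norm == target_norm &
                                        drug$role_cod == "PS"])
  n_target <- length(target_ids)

  reac <- fd$tables$reac
  unmapped <- character()
  if (level == "PT") {
    pairs <- unique(data.table(primaryid = reac$primaryid, event = reac$pt))
  } else {
    if (is.null(meddra_map)) stop("SOC level requires a meddra_map")
    ann <- map_pt_to_soc(reac, meddra_map)
    unmapped <- attr(ann, "unmapped")
    ann <- ann[!is.na(ann$soc)]
    pairs <- unique(data.table(primaryid = ann$primaryid, event = ann$soc))
  }
  # totals per event over the whole universe, and within target reports
  universe_n <- N
  tot <- pairs[, .(n_event = .N), by = "event"]
  tgt <- pairs[pairs$primaryid %in% target_ids, .(a = .N), by = "event"]
  tab <- merge(tgt, tot, by = "event", all.x = TRUE)
  tab[, b := n_target - a]
  tab[, c := n_event - a]
  tab[, d := universe_n - a - b - c]
  tab[, E := (a + b) * n_event / universe_n]
  tab[, N := universe_n]
  lvl <- level
  tab[, level := lvl]
  tab[, n_event := NULL]
  setorderv(tab, c("a", "event"), order = c(-1L, 1L))
  out <- tab[, c("event", "level", "a", "b", "c", "d", "N", "E")]
  setattr(out, "class", c("contingency_tables", class(out)))
  setattr(out, "target", target_norm)
  setattr(out, "n_target", n_target)
  setattr(out, "N", N)
  if (level == "SOC") setattr(out, "unmapped", unmapped)
  out
}

#' @export
print.contingency_tables <- function(x, ...) {
  cat(sprintf("contingency_tables: %d %s-level events; target %s (%d reports) in universe N=%d\n",
              nrow(x), if (nrow(x)) x$level[1] else "?", attr(x, "target"),
              attr(x, "n_target"), attr(x, "N")))
  print(as.data.table(x), topn = 5)
  invisible(x)
}
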