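#' Construct a single safety report
#'
#' A safety report is one spontaneous adverse-event record as exported from a
#' FAERS-dashboard-style database: an opaque case identifier, a source kind
#' (direct submission vs. extracted from the literature), the suspect product
#' names and active ingredients, the reported adverse-event terms, and
#' optional demographics, outcomes and indications. Term lists are stored as
#' the raw strings from the export; normalization happens downstream through
#' [normalize_term()] so that the mapping stays auditable.
#'
#' @param case_id Non-empty case identifier string.
#' @param adverse_events Character vector of reported adverse-event terms;
#'   must contain at least one term that is non-empty after normalization.
#' @param suspect_products Character vector of suspect product (brand) names.
#' @param suspect_active_ingredients Character vector of suspect active
#'   ingredient names.
#' @param source_kind `"direct"` or `"literature"`.
#' @param sex `"F"`, `"M"` or `"unknown"`.
#' @param age_years Optional non-negative age in years (`NA` if unknown).
#' @param received_date Optional date the report was received (`Date` or
#'   `"YYYY-MM-DD"` string; `NA` if unknown).
#' @param outcomes,indications Optional character vectors.
#' @return An object of class `safety_report`.
#' @export
safety_report <- function(case_id,
                          adverse_events,
                          suspect_products = character(),
                          suspect_active_ingredients = character(),
                          source_kind = c("direct", "literature"),
                          sex = c("unknown", "F", "M"),
                          age_years = NA_real_,
                          received_date = NA,
                          outcomes = character(),
                          indications = character()) {
  source_kind <- match.arg(source_kind)
  sex <- match.arg(sex)
  if (!is.character(case_id) || length(case_id) != 1L || !nzchar(trimws(case_id)))
    stop("`case_id` must be a non-empty string", call. = FALSE)
  ades <- normalize_term(adverse_events)
  if (length(ades) == 0L)
    stop("report ", case_id, ": no adverse-event term survives normalization",
         call. = FALSE)
  if (!is.na(age_years) && age_years < 0)
    stop("`age_years` must be non-negative", call. = FALSE)
  received_date <- if (length(received_date) == 1L && is.na(received_date))
    as.Date(NA) else as.Date(received_date)
  structure(
    list(
      case_id = trimws(case_id),
      source_kind = source_kind,
      suspect_products = as.character(suspect_products),
      suspect_active_ingredients = as.character(suspect_active_ingredients),
      adverse_events = as.character(adverse_events),
      sex = sex,
      age_years = as.numeric(age_years),
      received_date = received_date,
      outcomes = as.character(outcomes),
      indications = as.character(indications)
    ),
    class = "safety_report"
  )
}

#' Construct a report set
#'
#' An ordered collection of [safety_report()] objects with a free-text
#' provenance note. Case IDs need not be unique until [deduplicate()] has
#' been applied.
#'
#' @param reports List of `safety_report` objects.
#' @param provenance Free-text description of where the reports came from.
#' @return An object of class `report_set`.
#' @export
report_set <- function(reports, provenance = "unspecified") {
  stopifnot(is.list(reports))
  ok <- vapply(reports, inherits, logical(1), what = "safety_report")
  if (!all(ok))
    stop("all elements of `reports` must be safety_report objects", call. = FALSE)
  structure(list(reports = reports, provenance = provenance),
            class = "report_set")
}

#' @export
length.report_set <- function(x) length(x$reports)

#' @export
print.report_set <- function(x, ...) {
  src <- table(vapply(x$reports, `[[`, character(1), "source_kind"))
  cat("<report_set> ", length(x), " reports (",
      paste(sprintf("%s: %d", names(src), as.integer(src)), collapse = ", "),
      ")\n  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Default synonym map for drug and event terms
#'
#' Maps brand names and salt forms onto a single canonical term. The default
#' collapses the dexmedetomidine hydrochloride salt and the Precedex brand
#' name onto `"dexmedetomidine"`. Extend or replace it with a two-column
#' data frame (`raw`, `canonical`) or a named character vector.
#'
#' @return Named character vector: names are raw (case-folded) terms, values
#'   their canonical forms.
#' @export
default_synonyms <- function() {
  c("dexmedetomidine hydrochloride" = "dexmedetomidine",
    "precedex" = "dexmedetomidine")
}

#' Normalize a raw drug or adverse-event term
#'
#' Case-folds, trims and squeezes whitespace, then applies an explicit
#' synonym map. Matching is exact-string after folding; no fuzzy matching is
#' performed, so the normalization is deterministic and auditable. Empty
#' strings are dropped (an all-empty input yields a zero-length result);
#' duplicates after normalization are collapsed, preserving first occurrence
#' order.
#'
#' @param raw Character vector of raw terms.
#' @param synonym_map Named character vector (raw -> canonical), or a
#'   two-column data frame with columns `raw` and `canonical`.
#' @return Character vector of unique canonical terms.
#' @examples
#' normalize_term("PRECEDEX")                      # "dexmedetomidine"
#' normalize_term(c("Bradycardia ", "bradycardia")) # "bradycardia"
#' @export
normalize_term <- function(raw, synonym_map = default_synonyms()) {
  if (is.data.frame(synonym_map)) {
    stopifnot(all(c("raw", "canonical") %in% names(synonym_map)))
    synonym_map <- stats::setNames(as.character(synonym_map$canonical),
                                   as.character(synonym_map$raw))
  }
  if (!is.character(raw)) stop("`raw` must be character", call. = FALSE)
  x <- tolower(gsub("[[:space:]]+", " ", trimws(raw)))
  x <- x[nzchar(x)]
  names(synonym_map) <- tolower(trimws(names(synonym_map)))
  hit <- match(x, names(synonym_map))
  x[!is.na(hit)] <- unname(synonym_map[hit[!is.na(hit)]])
  unique(x)
}

#' Read a synonym map from a two-column CSV
#'
#' @param path CSV file with columns `raw` and `canonical`.
#' @return Named character vector usable as `synonym_map`.
#' @export
read_synonyms <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("raw", "canonical") %in% names(df)))
    stop("synonym file must have columns `raw` and `canonical`", call. = FALSE)
  stats::setNames(as.character(df$canonical), as.character(df$raw))
}

# Column maps for the supported delimited layouts. Each dialect names the
# export columns holding every report field and the separator used inside
# list-valued cells.
report_dialects <- function() {
  list(
    faers = list(
      sep = ",",
      list_sep = ";",
      columns = c(
        case_id = "Case ID",
        suspect_products = "Suspect Product Names",
        suspect_active_ingredients = "Suspect Product Active Ingredients",
        adverse_events = "Reactions",
        source = "Report Source",
        sex = "Sex",
        age_years = "Patient Age",
        received_date = "Event Date",
        outcomes = "Outcomes",
        indications = "Reason for Use"
      )
    ),
    tsv = list(
      sep = "\t",
      list_sep = ";",
      columns = c(
        case_id = "case_id",
        suspect_products = "suspect_products",
        suspect_active_ingredients = "suspect_active_ingredients",
        adverse_events = "adverse_events",
        source = "source",
        sex = "sex",
        age_years = "age_years",
        received_date = "received_date",
        outcomes = "outcomes",
        indications = "indications"
      )
    )
  )
}

split_list_cell <- function(x, sep) {
  if (is.na(x) || !nzchar(trimws(x))) return(character())
  trimws(strsplit(x, sep, fixed = TRUE)[[1]])
}

# A report is literature-sourced when its report-source field matches one of
# these patterns (case-insensitive); the dashboard exposes source as a column
# but does not flag indirect reports explicitly.
is_literature_source <- function(source, patterns = "literature") {
  if (is.na(source)) return(FALSE)
  any(vapply(patterns, function(p) grepl(p, source, ignore.case = TRUE),
             logical(1)))
}

#' Load safety reports from a delimited export
#'
#' Parses a FAERS-dashboard-style delimited file into a [report_set()]. Raw
#' term strings are preserved on each report. Rows with an empty case ID or
#' an empty reactions cell are dropped, counted, and reported in the load
#' report attached as attribute `"load_report"` — never silently.
#'
#' @param path Path to the export file.
#' @param dialect `"faers"` (comma-separated, dashboard column names) or
#'   `"tsv"` (tab-separated, snake_case column names). List-valued cells are
#'   split on `";"`.
#' @param literature_patterns Patterns (case-insensitive regex) identifying a
#'   literature report source.
#' @return A `report_set`; `attr(, "load_report")` holds
#'   `list(n_rows, n_loaded, n_dropped, dropped_reasons)`.
#' @export
load_reports <- function(path, dialect = "faers",
                         literature_patterns = "literature") {
  dialects <- report_dialects()
  if (!dialect %in% names(dialects))
    stop("unknown dialect: ", dialect, " (supported: ",
         paste(names(dialects), collapse = ", "), ")", call. = FALSE)
  d <- dialects[[dialect]]
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- scan(path, what = character(), sep = "\n", n = 1, quiet = TRUE)
  cols <- scan(text = header, what = character(), sep = d$sep, quiet = TRUE)
  if (anyDuplicated(cols))
    stop("duplicated column headers in ", path, ": ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = d$sep, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  missing_cols <- setdiff(unname(d$columns), names(df))
  if (length(missing_cols))
    stop("dialect '", dialect, "' expects missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  get <- function(row, field) df[row, d$columns[[field]]]
  reports <- list()
  dropped <- c(empty_case_id = 0L, empty_reactions = 0L, malformed = 0L)
  for (i in seq_len(nrow(df))) {
    cid <- trimws(get(i, "case_id"))
    if (!nzchar(cid)) { dropped["empty_case_id"] <- dropped["empty_case_id"] + 1L; next }
    ades_raw <- split_list_cell(get(i, "adverse_events"), d$list_sep)
    if (length(normalize_term(ades_raw)) == 0L) {
      dropped["empty_reactions"] <- dropped["empty_reactions"] + 1L
      next
    }
    rep <- tryCatch(
      safety_report(
        case_id = cid,
        adverse_events = ades_raw,
        suspect_products = split_list_cell(get(i, "suspect_products"), d$list_sep),
        suspect_active_ingredients =
          split_list_cell(get(i, "suspect_active_ingredients"), d$list_sep),
        source_kind = if (is_literature_source(get(i, "source"),
                                               literature_patterns))
          "literature" else "direct",
        sex = {
          s <- toupper(trimws(get(i, "sex")))
          if (s %in% c("F", "M")) s else "unknown"
        },
        age_years = suppressWarnings(as.numeric(get(i, "age_years"))),
        received_date = {
          dt <- trimws(get(i, "received_date"))
          if (nzchar(dt)) dt else NA
        },
        outcomes = split_list_cell(get(i, "outcomes"), d$list_sep),
        indications = split_list_cell(get(i, "indications"), d$list_sep)
      ),
      error = function(e) {
        message("skipping malformed row ", i, ": ", conditionMessage(e))
        NULL
      }
    )
    if (is.null(rep)) dropped["malformed"] <- dropped["malformed"] + 1L
    else reports[[length(reports) + 1L]] <- rep
  }
  rs <- report_set(reports, provenance = paste0(dialect, " export: ", path))
  attr(rs, "load_report") <- list(
    n_rows = nrow(df),
    n_loaded = length(reports),
    n_dropped = sum(dropped),
    dropped_reasons = as.list(dropped)
  )
  rs
}

report_drug_terms <- function(r, synonym_map = default_synonyms()) {
  normalize_term(c(r$suspect_products, r$suspect_active_ingredients),
                 synonym_map)
}

#' Filter a report set to a drug cohort
#'
#' Retains exactly the reports whose normalized suspect product names OR
#' suspect active ingredients contain the cohort drug. Terms appearing only
#' in the indications field do not qualify.
#'
#' @param rs A [report_set()].
#' @param drug Canonical (normalized) drug term, e.g. `"dexmedetomidine"`.
#' @param synonym_map Synonym map applied when normalizing report terms.
#' @return A new `report_set` restricted to the cohort; the input is not
#'   modified. An empty result is permitted (with a message).
#' @export
filter_drug_cohort <- function(rs, drug, synonym_map = default_synonyms()) {
  stopifnot(inherits(rs, "report_set"))
  keep <- vapply(rs$reports, function(r)
    drug %in% report_drug_terms(r, synonym_map), logical(1))
  if (!any(keep)) message("drug cohort for '", drug, "' is empty")
  report_set(rs$reports[keep],
             provenance = paste0(rs$provenance, " | cohort: ", drug))
}

#' Deduplicate a report set
#'
#' Applies the two exclusion rules used when cleaning spontaneous-report
#' cohorts: (1) all literature-sourced (indirect) reports are removed, since
#' one published case can spawn many database entries and inflate signal
#' counts; (2) among the remaining direct reports that share a case ID, only
#' the report with the latest received date is kept (ties, including missing
#' dates, keep the first in input order). The operation is idempotent.
#'
#' @param rs A [report_set()].
#' @return A new `report_set`; `attr(, "dedup_log")` holds counts of removals
#'   by reason (`literature`, `duplicate_case_id`).
#' @export
deduplicate <- function(rs) {
  stopifnot(inherits(rs, "report_set"))
  src <- vapply(rs$reports, `[[`, character(1), "source_kind")
  direct <- rs$reports[src == "direct"]
  n_lit <- sum(src == "literature")
  keep <- rep(TRUE, length(direct))
  if (length(direct)) {
    ids <- vapply(direct, `[[`, character(1), "case_id")
    dates <- as.Date(vapply(direct, function(r)
      as.character(r$received_date), character(1)))
    for (id in unique(ids[duplicated(ids)])) {
      idx <- which(ids == id)
      dt <- dates[idx]
      score <- ifelse(is.na(dt), -Inf, as.numeric(dt))
      best <- idx[which.max(score)]  # which.max keeps the earliest index on ties
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  out <- report_set(direct[keep], provenance = paste0(rs$provenance, " | dedup"))
  attr(out, "dedup_log") <- list(literature = n_lit,
                                 duplicate_case_id = sum(!keep))
  out
}

#' Write a report set as JSON lines
#'
#' One JSON object per report; readable back with [read_reports_jsonl()].
#'
#' @param rs A [report_set()].
#' @param path Output file path.
#' @export
write_reports_jsonl <- function(rs, path) {
  stopifnot(inherits(rs, "report_set"))
  lines <- vapply(rs$reports, function(r) {
    r$received_date <- if (is.na(r$received_date)) NA_character_
                       else as.character(r$received_date)
    jsonlite::toJSON(unclass(r), auto_unbox = TRUE, null = "null", na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a report set from JSON lines
#'
#' @param path File written by [write_reports_jsonl()].
#' @param provenance Provenance note for the resulting set.
#' @return A `report_set`.
#' @export
read_reports_jsonl <- function(path, provenance = paste("jsonl:", path)) {
  lines <- readLines(path)
  reports <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    safety_report(
      case_id = x$case_id,
      adverse_events = unlist(x$adverse_events),
      suspect_products = as.character(unlist(x$suspect_products)),
      suspect_active_ingredients = as.character(unlist(x$suspect_active_ingredients)),
      source_kind = x$source_kind,
      sex = x$sex,
      age_years = if (is.null(x$age_years) || is.na(x$age_years)) NA_real_
                  else x$age_years,
      received_date = if (is.null(x$received_date)) NA else x$received_date,
      outcomes = as.character(unlist(x$outcomes)),
      indications = as.character(unlist(x$indications))
    )
  })
  report_set(reports, provenance)
}

#' Write the deduplication audit log as TSV
#'
#' @param rs A deduplicated `report_set` carrying a `"dedup_log"` attribute.
#' @param path Output TSV path.
#' @export
write_dedup_audit <- function(rs, path) {
  log <- attr(rs, "dedup_log")
  if (is.null(log)) stop("`rs` carries no dedup_log; run deduplicate() first",
                         call. = FALSE)
  df <- data.frame(reason = names(log),
                   n_removed = as.integer(unlist(log)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
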