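# Run `code` under a private seeded RNG stream, restoring any global state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specify a synthetic report cohort
#'
#' Parameterizes the synthetic report-database generator by the margins the
#' analysis observes: the cohort size, the count of the consequent event
#' (e.g. bradycardia), and for each item of interest its marginal count and
#' its joint count with the consequent — i.e. the full 2x2 table of every
#' (item, consequent) pair. Background items with plain marginal
#' probabilities and extra literature-sourced duplicates (for deduplication
#' testing) can be added.
#'
#' @param n_reports Number of direct reports in the cohort.
#' @param consequent_count Number of reports containing the consequent.
#' @param consequent_label Consequent event term (default `"bradycardia"`).
#' @param pairs Data frame with columns `label`, `kind` (`"ade"`/`"drug"`),
#'   `antecedent` (marginal count) and `joint` (count of reports with both
#'   the item and the consequent).
#' @param background_items Optional data frame with columns `label`, `kind`,
#'   `prob` — items carried at independent marginal probabilities.
#' @param literature_extra Number of literature-sourced duplicate reports to
#'   append (default 0).
#' @param cohort_drug Drug placed in every report's suspect active
#'   ingredients (default `"dexmedetomidine"`).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_reports, consequent_count,
                        consequent_label = "bradycardia",
                        pairs = NULL, background_items = NULL,
                        literature_extra = 0L,
                        cohort_drug = "dexmedetomidine", seed = 1L) {
  stopifnot(n_reports >= 1, consequent_count >= 0,
            consequent_count <= n_reports)
  if (is.null(pairs))
    pairs <- data.frame(label = character(), kind = character(),
                        antecedent = integer(), joint = integer())
  stopifnot(all(c("label", "kind", "antecedent", "joint") %in% names(pairs)))
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    if (p$joint > min(p$antecedent, consequent_count) ||
        p$antecedent > n_reports ||
        (p$antecedent - p$joint) > (n_reports - consequent_count))
      stop("unsatisfiable pair spec for '", p$label, "': need joint <= min(",
           "antecedent, consequent_count) and antecedent - joint <= ",
           "n_reports - consequent_count", call. = FALSE)
  }
  if (!is.null(background_items))
    stopifnot(all(c("label", "kind", "prob") %in% names(background_items)),
              all(background_items$prob >= 0 & background_items$prob <= 1))
  structure(
    list(n_reports = as.integer(n_reports),
         consequent_count = as.integer(consequent_count),
         consequent_label = consequent_label,
         pairs = pairs,
         background_items = background_items,
         literature_extra = as.integer(literature_extra),
         cohort_drug = cohort_drug,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Read a cohort spec from JSON
#'
#' @param path JSON file with the [cohort_spec()] fields.
#' @return A `cohort_spec`.
#' @export
cohort_spec_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  cohort_spec(
    n_reports = x$n_reports,
    consequent_count = x$consequent_count,
    consequent_label = x$consequent_label,
    pairs = as.data.frame(x$pairs),
    background_items = if (!is.null(x$background_items))
      as.data.frame(x$background_items) else NULL,
    literature_extra = if (!is.null(x$literature_extra)) x$literature_extra else 0L,
    cohort_drug = if (!is.null(x$cohort_drug)) x$cohort_drug else "dexmedetomidine",
    seed = if (!is.null(x$seed)) x$seed else 1L
  )
}

# Assemble safety reports from per-slot item lists.
assemble_reports <- function(spec, slot_ades, slot_drugs) {
  N <- spec$n_reports
  reports <- vector("list", N)
  for (t in seq_len(N)) {
    ades <- slot_ades[[t]]
    # a report must carry at least one event term; pad slots that carry no
    # configured event with terms from a fixed synthetic vocabulary,
    # round-robin so no single filler can outrank configured items. Fillers
    # land only on slots without the consequent, so they never co-occur
    # with it and cannot surface as mined rules.
    if (length(ades) == 0L) ades <- sprintf("ade_%03d", (t - 1L) %% 50L + 1L)
    reports[[t]] <- safety_report(
      case_id = sprintf("case_%06d", t),
      adverse_events = ades,
      suspect_products = character(),
      suspect_active_ingredients = c(spec$cohort_drug, slot_drugs[[t]]),
      source_kind = "direct",
      received_date = as.Date("2020-01-01") + (t %% 365)
    )
  }
  if (spec$literature_extra > 0L) {
    for (j in seq_len(spec$literature_extra)) {
      src <- reports[[((j - 1L) %% N) + 1L]]
      dup <- src
      dup$case_id <- sprintf("lit_%06d", j)
      dup$source_kind <- "literature"
      reports[[N + j]] <- dup
    }
  }
  report_set(reports, provenance = sprintf(
    "synthetic cohort (N=%d, consequent '%s'=%d, %d pairs, seed=%d)",
    N, spec$consequent_label, spec$consequent_count, nrow(spec$pairs),
    spec$seed))
}

draw_background <- function(spec, slot_ades, slot_drugs) {
  bg <- spec$background_items
  if (is.null(bg) || nrow(bg) == 0L) return(list(slot_ades, slot_drugs))
  N <- spec$n_reports
  for (i in seq_len(nrow(bg))) {
    hit <- which(stats::runif(N) < bg$prob[i])
    for (t in hit) {
      if (bg$kind[i] == "ade")
        slot_ades[[t]] <- c(slot_ades[[t]], bg$label[i])
      else
        slot_drugs[[t]] <- c(slot_drugs[[t]], bg$label[i])
    }
  }
  list(slot_ades, slot_drugs)
}

#' Generate a report set realizing exact 2x2 margins
#'
#' Deterministically constructs a cohort in which, for every pair in the
#' spec, the 2x2 table of (consequent, item) is exactly
#' `(joint, consequent - joint, antecedent - joint, remainder)`. Report
#' slots carrying the consequent are allocated first; each item's joint
#' portion is packed into consequent slots and the rest into non-consequent
#' slots, which guarantees the configured margins without integer
#' programming. Background items are drawn stochastically (seeded) and
#' literature duplicates appended for deduplication testing.
#'
#' @param spec A [cohort_spec()].
#' @return A [report_set()] of `n_reports + literature_extra` reports.
#' @export
generate_exact <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  N <- spec$n_reports
  C <- spec$consequent_count
  slot_ades <- lapply(seq_len(N), function(i)
    if (i <= C) spec$consequent_label else character())
  slot_drugs <- rep(list(character()), N)
  for (i in seq_len(nrow(spec$pairs))) {
    p <- spec$pairs[i, ]
    in_cons <- seq_len(p$joint)                       # slots 1..joint
    out_cons <- C + seq_len(p$antecedent - p$joint)   # first non-consequent slots
    for (t in c(in_cons, out_cons)) {
      if (p$kind == "ade")
        slot_ades[[t]] <- unique(c(slot_ades[[t]], p$label))
      else
        slot_drugs[[t]] <- unique(c(slot_drugs[[t]], p$label))
    }
  }
  with_seed(spec$seed, {
    bg <- draw_background(spec, slot_ades, slot_drugs)
    # shuffle slot order so downstream code cannot rely on construction order
    perm <- sample.int(N)
    assemble_reports(spec, bg[[1]][perm], bg[[2]][perm])
  })
}

#' Generate a report set by sampling the configured margins
#'
#' Stochastic counterpart of [generate_exact()]: the consequent is drawn
#' per report at probability `consequent_count / n_reports`, and each paired
#' item is drawn conditionally on the consequent from the 2x2 joint its
#' margins imply (`P(item | consequent) = joint / consequent_count`,
#' `P(item | no consequent) = (antecedent - joint) / (n_reports -
#' consequent_count)`), so realized lifts converge to the configured targets
#' as the cohort grows. Background items are independent Bernoulli draws.
#'
#' @param spec A [cohort_spec()].
#' @return A [report_set()]; identical across calls with the same seed.
#' @export
generate_stochastic <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  N <- spec$n_reports
  C <- spec$consequent_count
  with_seed(spec$seed, {
    has_cons <- stats::runif(N) < C / N
    slot_ades <- lapply(seq_len(N), function(t)
      if (has_cons[t]) spec$consequent_label else character())
    slot_drugs <- rep(list(character()), N)
    for (i in seq_len(nrow(spec$pairs))) {
      p <- spec$pairs[i, ]
      p_given_cons <- if (C > 0) p$joint / C else 0
      p_given_not <- if (N - C > 0) (p$antecedent - p$joint) / (N - C) else 0
      prob <- ifelse(has_cons, p_given_cons, p_given_not)
      hit <- which(stats::runif(N) < prob)
      for (t in hit) {
        if (p$kind == "ade")
          slot_ades[[t]] <- unique(c(slot_ades[[t]], p$label))
        else
          slot_drugs[[t]] <- unique(c(slot_drugs[[t]], p$label))
      }
    }
    bg <- draw_background(spec, slot_ades, slot_drugs)
    assemble_reports(spec, bg[[1]], bg[[2]])
  })
}

#' Specify a synthetic gene universe
#'
#' @param background_size Background universe size.
#' @param list_size Gene-list size.
#' @param pathways Data frame with columns `name`, `size`, `overlap`: each
#'   pathway realizes exactly `overlap` genes shared with the list.
#' @param seed Integer seed (symbols are assigned under a seeded
#'   permutation).
#' @return An object of class `enrichment_spec`.
#' @export
enrichment_spec <- function(background_size, list_size, pathways,
                            seed = 1L) {
  stopifnot(background_size >= 1, list_size >= 1,
            list_size <= background_size,
            all(c("name", "size", "overlap") %in% names(pathways)))
  for (i in seq_len(nrow(pathways))) {
    p <- pathways[i, ]
    if (p$overlap > min(p$size, list_size) || p$size > background_size ||
        (p$size - p$overlap) > (background_size - list_size))
      stop("unsatisfiable pathway spec for '", p$name, "'", call. = FALSE)
  }
  structure(list(background_size = as.integer(background_size),
                 list_size = as.integer(list_size),
                 pathways = pathways, seed = as.integer(seed)),
            class = "enrichment_spec")
}

#' Read an enrichment spec from JSON
#'
#' @param path JSON file with the [enrichment_spec()] fields.
#' @return An `enrichment_spec`.
#' @export
enrichment_spec_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  enrichment_spec(
    background_size = x$background_size,
    list_size = x$list_size,
    pathways = as.data.frame(x$pathways),
    seed = if (!is.null(x$seed)) x$seed else 1L
  )
}

#' Generate a synthetic gene universe realizing exact overlaps
#'
#' Builds synthetic gene symbols (`gene000001`, ...), a gene list of the
#' configured size, and one gene set per pathway spec containing exactly
#' `overlap` list genes and `size - overlap` non-list genes.
#'
#' @param spec An [enrichment_spec()].
#' @return List with elements `gene_list`, `collection` (named list of gene
#'   sets) and `background`.
#' @export
generate_gene_universe <- function(spec) {
  stopifnot(inherits(spec, "enrichment_spec"))
  with_seed(spec$seed, {
    symbols <- sprintf("gene%06d", sample.int(spec$background_size))
    gene_list <- symbols[seq_len(spec$list_size)]
    non_list <- symbols[-seq_len(spec$list_size)]
    collection <- list()
    for (i in seq_len(nrow(spec$pathways))) {
      p <- spec$pathways[i, ]
      collection[[p$name]] <- c(
        if (p$overlap > 0) gene_list[seq_len(p$overlap)] else character(),
        if (p$size > p$overlap) non_list[seq_len(p$size - p$overlap)]
        else character()
      )
    }
    list(gene_list = gene_list, collection = collection,
         background = symbols)
  })
}

#' Write a report set as a FAERS-dashboard-style export
#'
#' The inverse of [load_reports()]: writes one row per report under the
#' chosen dialect's column names, with list-valued cells joined by `";"`.
#' `load_reports(write_export(rs, path), dialect)` reproduces `rs` exactly
#' for report sets whose terms are already canonical.
#'
#' @param rs A [report_set()].
#' @param path Output file path.
#' @param dialect `"faers"` or `"tsv"` (see [load_reports()]).
#' @export
write_export <- function(rs, path, dialect = "faers") {
  stopifnot(inherits(rs, "report_set"))
  dialects <- report_dialects()
  if (!dialect %in% names(dialects))
    stop("unknown dialect: ", dialect, call. = FALSE)
  d <- dialects[[dialect]]
  join <- function(x) paste(x, collapse = paste0(d$list_sep, " "))
  rows <- lapply(rs$reports, function(r) {
    v <- c(
      r$case_id,
      join(r$suspect_products),
      join(r$suspect_active_ingredients),
      join(r$adverse_events),
      if (r$source_kind == "literature") "Literature" else "Direct",
      if (r$sex == "unknown") "" else r$sex,
      if (is.na(r$age_years)) "" else as.character(r$age_years),
      if (is.na(r$received_date)) "" else as.character(r$received_date),
      join(r$outcomes),
      join(r$indications)
    )
    stats::setNames(v, c("case_id", "suspect_products",
                         "suspect_active_ingredients", "adverse_events",
                         "source", "sex", "age_years", "received_date",
                         "outcomes", "indications"))
  })
  df <- as.data.frame(do.call(rbind, lapply(rows, rbind)),
                      stringsAsFactors = FALSE)
  if (length(rows) == 0L)
    df <- as.data.frame(matrix(character(), 0, length(d$columns)))
  names(df) <- unname(d$columns[c("case_id", "suspect_products",
                                  "suspect_active_ingredients",
                                  "adverse_events", "source", "sex",
                                  "age_years", "received_date", "outcomes",
                                  "indications")])
  utils::write.table(df, path, sep = d$sep, quote = TRUE, row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}
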