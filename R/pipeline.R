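#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis: the cohort drug and
#' consequent event, the rule-screening thresholds (lift >= 1.5, joint count
#' >= 10 by default), the significance level of the exact disproportionality
#' CIs, the enrichment FDR cutoff, and the input locations. Exactly one of
#' `input` (a delimited export) or `spec` (a synthetic [cohort_spec()], or a
#' path to its JSON form) must be given.
#'
#' @param input Path to a delimited report export (see [load_reports()]).
#' @param spec A `cohort_spec` object or path to a cohort-spec JSON file.
#' @param cohort_drug Canonical cohort drug (default `"dexmedetomidine"`).
#' @param consequent Canonical consequent event (default `"bradycardia"`).
#' @param min_lift,min_count Rule-screening thresholds (defaults 1.5, 10).
#' @param alpha Significance level for exact CIs (default 0.05).
#' @param fdr_cutoff Enrichment FDR cutoff (default 0.05).
#' @param top_k Length of the most-frequent-ADE ranking (default 10).
#' @param dialect Export dialect for `input` (default `"faers"`).
#' @param gene_list Optional path to a one-symbol-per-line gene list.
#' @param gmt Optional path to a GMT gene-set collection.
#' @param background Optional path to a one-symbol-per-line background.
#' @param seed Seed forwarded to the synthetic generator when `spec` is a
#'   path (a `cohort_spec` object keeps its own seed).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, spec = NULL,
                            cohort_drug = "dexmedetomidine",
                            consequent = "bradycardia",
                            min_lift = 1.5, min_count = 10L,
                            alpha = 0.05, fdr_cutoff = 0.05, top_k = 10L,
                            dialect = "faers", gene_list = NULL, gmt = NULL,
                            background = NULL, seed = NULL) {
  if (is.null(input) == is.null(spec))
    stop("exactly one of `input` or `spec` must be given", call. = FALSE)
  stopifnot(min_lift >= 0, min_count >= 0, alpha > 0, alpha < 1,
            fdr_cutoff > 0, top_k >= 1)
  structure(
    list(input = input, spec = spec, cohort_drug = cohort_drug,
         consequent = consequent, min_lift = min_lift,
         min_count = as.integer(min_count), alpha = alpha,
         fdr_cutoff = fdr_cutoff, top_k = as.integer(top_k),
         dialect = dialect, gene_list = gene_list, gmt = gmt,
         background = background, seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full signal-mining pipeline
#'
#' Sequences the stages end to end: ingest (load an export or generate a
#' synthetic cohort), deduplicate, filter to the drug cohort, rank the most
#' frequent events, mine and validate event-event rules, mine and validate
#' drug-event (interaction) rules, and — when a gene list and collection are
#' configured — run the enrichment stage. Each output table is written as
#' TSV under `out_dir` and a JSON manifest records the configuration, seed
#' and row counts. Any stage failure aborts with the stage name and removes
#' partial outputs. Reruns with the same configuration and seed are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results: `reports`,
#'   `cohort`, `db`, `top_ades`, `ade_rules`, `ade_validated`, `ddi_rules`,
#'   `ddi_validated`, `enrichment` (or `NULL`), and `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  out <- function(name) file.path(out_dir, name)
  stage <- "setup"
  on_fail <- function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    stage <- "ingest"
    rs <- if (!is.null(config$input)) {
      load_reports(config$input, dialect = config$dialect)
    } else {
      spec <- config$spec
      if (is.character(spec)) spec <- cohort_spec_from_json(spec)
      if (!is.null(config$seed)) spec$seed <- as.integer(config$seed)
      generate_exact(spec)
    }

    stage <- "deduplicate"
    rs_dedup <- deduplicate(rs)
    write_dedup_audit(rs_dedup, out("dedup_audit.tsv"))
    written <- c(written, out("dedup_audit.tsv"))

    stage <- "cohort"
    cohort <- filter_drug_cohort(rs_dedup, config$cohort_drug)

    stage <- "transactions"
    db <- build_transactions(cohort, kinds = c("ade", "drug"),
                             exclude = config$cohort_drug)
    top <- top_items(db, kind = "ade", k = config$top_k)
    utils::write.table(top, out("top_ades.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, out("top_ades.tsv"))

    filt <- rule_filter(min_lift = config$min_lift,
                        min_count = config$min_count,
                        consequent = config$consequent,
                        consequent_kind = "ade")

    stage <- "mine_ade_rules"
    ade_rules <- mine_rules(db, filt, antecedent_kind = "ade")
    write_rules(ade_rules, out("ade_rules.tsv"))
    written <- c(written, out("ade_rules.tsv"))

    stage <- "validate_ade_rules"
    ade_val <- validate_rules(db, ade_rules, alpha = config$alpha)
    write_validation(ade_val, out("ade_validation.tsv"))
    written <- c(written, out("ade_validation.tsv"))

    stage <- "mine_ddi_rules"
    ddi_rules <- mine_rules(db, filt, antecedent_kind = "drug")
    write_rules(ddi_rules, out("ddi_rules.tsv"))
    written <- c(written, out("ddi_rules.tsv"))

    stage <- "validate_ddi_rules"
    ddi_val <- validate_rules(db, ddi_rules, alpha = config$alpha)
    write_validation(ddi_val, out("ddi_validation.tsv"))
    written <- c(written, out("ddi_validation.tsv"))

    enr <- NULL
    if (!is.null(config$gene_list) && !is.null(config$gmt)) {
      stage <- "enrichment"
      genes <- readLines(config$gene_list)
      genes <- genes[nzchar(trimws(genes))]
      collection <- read_gmt(config$gmt)
      bg <- if (!is.null(config$background)) {
        b <- readLines(config$background)
        b[nzchar(trimws(b))]
      } else NULL
      enr <- enrich(genes, collection, background = bg,
                    fdr_cutoff = config$fdr_cutoff)
      write_enrichment(enr, out("enrichment.tsv"))
      written <- c(written, out("enrichment.tsv"))
    }

    stage <- "manifest"
    manifest <- list(
      config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
      counts = list(
        reports_ingested = length(rs),
        reports_after_dedup = length(rs_dedup),
        dedup_removed = attr(rs_dedup, "dedup_log"),
        cohort_size = length(cohort),
        n_transactions = db$n_transactions,
        vocabulary_size = nrow(db$vocabulary),
        top_ades_rows = nrow(top),
        ade_rules = nrow(ade_rules),
        ade_rules_significant = sum(ade_val$significant),
        ddi_rules = nrow(ddi_rules),
        ddi_rules_significant = sum(ddi_val$significant),
        enrichment_rows = if (is.null(enr)) NULL else nrow(enr)
      ),
      outputs = basename(written)
    )
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    written <- c(written, out("manifest.json"))

    invisible(list(reports = rs, cohort = cohort, db = db, top_ades = top,
                   ade_rules = ade_rules, ade_validated = ade_val,
                   ddi_rules = ddi_rules, ddi_validated = ddi_val,
                   enrichment = enr, manifest = manifest))
  }, error = on_fail)
}

#' Path to a bundled example specification
#'
#' The package ships two small JSON spec files: `"table4_table6"`, a cohort
#' spec encoding the sixteen reconstructed rule margins of the
#' dexmedetomidine-bradycardia worked example (N = 1611, consequent count
#' 209, plus 1050 literature duplicates), and `"table8"`, a gene-universe
#' spec for the matching enrichment worked example (background 13,256, list
#' 248, ten pathways).
#'
#' @param name `"table4_table6"` or `"table8"`.
#' @return File path inside the installed package.
#' @export
example_spec_path <- function(name = c("table4_table6", "table8")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".json"), package = "pvmine",
              mustWork = TRUE)
}
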