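#' Read a gene-set collection from a GMT file
#'
#' GMT is the tab-delimited gene-set format: one set per line as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Gene symbols are
#' case-folded to lower case and duplicates within a line collapsed.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (one per gene set); set
#'   descriptions are kept in `attr(, "descriptions")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT parse error at line ", i, ": fewer than 3 fields", call. = FALSE)
    genes <- unique(tolower(trimws(f[-(1:2)])))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L)
      stop("GMT parse error at line ", i, ": gene set '", f[1],
           "' is empty", call. = FALSE)
    sets[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of set descriptions
#'   (default `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Fold enrichment of a gene set in a gene list
#'
#' Observed-over-expected ratio of over-representation analysis:
#' `(k/n) / (K/N)` where `k` is the number of list genes in the set, `n` the
#' list size, `K` the set size within the background, and `N` the background
#' universe size. Equals 1 when the overlap matches its expectation under
#' random sampling and 0 when `k = 0`.
#'
#' @param k Overlap count, `0 <= k <= min(n, K)`.
#' @param n Gene-list size, `0 < n <= N`.
#' @param K Gene-set size, `0 < K <= N`.
#' @param N Background universe size.
#' @return Non-negative fold-enrichment value.
#' @export
fold_enrichment <- function(k, n, K, N) {
  if (!(n > 0 && n <= N && K > 0 && K <= N && k >= 0 && k <= min(n, K)))
    stop("invalid counts: need 0 <= k <= min(n, K), 0 < n <= N, 0 < K <= N",
         call. = FALSE)
  (k / n) / (K / N)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`:
#' the chance of drawing at least `k` set members in a random sample of `n`
#' genes from a background of `N` containing `K` set members.
#'
#' @inheritParams fold_enrichment
#' @return p-value in `[0, 1]`; `k = 0` gives 1.
#' @export
hypergeom_pvalue <- function(k, n, K, N) {
  if (!(n > 0 && n <= N && K > 0 && K <= N && k >= 0 && k <= min(n, K)))
    stop("invalid counts: need 0 <= k <= min(n, K), 0 < n <= N, 0 < K <= N",
         call. = FALSE)
  if (k == 0) return(1)
  # log-space tail for numerical stability at extreme overlaps
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: each p-value is multiplied by
#' `m/rank`, a running minimum enforces monotonicity from the largest p
#' down, values are capped at 1, and the original order is preserved.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Over-representation analysis of a gene list against a collection
#'
#' Intersects every gene set with the background universe, computes the
#' hypergeometric over-representation p-value and fold enrichment for each
#' set overlapping the list, adjusts p-values by Benjamini-Hochberg across
#' all tested (non-zero-overlap) sets, and returns rows passing the FDR
#' cutoff sorted by fold enrichment descending.
#'
#' @param gene_list Character vector of gene symbols (case-insensitive);
#'   must be a subset of the background.
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param background Character vector of background gene symbols; defaults
#'   to the union of all genes in the collection.
#' @param fdr_cutoff Keep rows with `fdr <= fdr_cutoff` (default 0.05); use
#'   `Inf` to keep everything tested.
#' @return Data frame with columns `pathway`, `k_overlap`, `K_pathway`,
#'   `n_list`, `N_background`, `fold_enrichment`, `p_value`, `fdr`,
#'   `overlap_genes` (comma-separated symbols).
#' @export
enrich <- function(gene_list, collection, background = NULL,
                   fdr_cutoff = 0.05) {
  gene_list <- unique(tolower(trimws(gene_list)))
  gene_list <- gene_list[nzchar(gene_list)]
  if (length(gene_list) == 0L)
    stop("empty gene list", call. = FALSE)
  if (is.null(background))
    background <- unique(tolower(unlist(collection)))
  else
    background <- unique(tolower(trimws(background)))
  missing <- setdiff(gene_list, background)
  if (length(missing))
    stop("gene list contains symbols outside the background: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...", call. = FALSE)
  n <- length(gene_list)
  N <- length(background)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(tolower(collection[[nm]])), background)
    if (length(set) == 0L) return(NULL)
    ov <- intersect(gene_list, set)
    k <- length(ov)
    if (k == 0L) return(NULL)
    data.frame(
      pathway = nm,
      k_overlap = k,
      K_pathway = length(set),
      n_list = n,
      N_background = N,
      fold_enrichment = fold_enrichment(k, n, length(set), N),
      p_value = hypergeom_pvalue(k, n, length(set), N),
      overlap_genes = paste(sort(ov), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L)
    return(data.frame(pathway = character(), k_overlap = integer(),
                      K_pathway = integer(), n_list = integer(),
                      N_background = integer(), fold_enrichment = numeric(),
                      p_value = numeric(), fdr = numeric(),
                      overlap_genes = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out <- out[out$fdr <= fdr_cutoff, , drop = FALSE]
  out <- out[order(-out$fold_enrichment, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("pathway", "k_overlap", "K_pathway", "n_list", "N_background",
          "fold_enrichment", "p_value", "fdr", "overlap_genes")]
}

#' Write an enrichment table as TSV
#'
#' Columns mirror the conventional pathway-table layout: pathway, overlap
#' and set sizes, fold enrichment (2 dp), FDR, and the overlapping genes.
#'
#' @param rows Output of [enrich()].
#' @param path Output TSV path.
#' @export
write_enrichment <- function(rows, path) {
  df <- data.frame(
    pathway = rows$pathway,
    num_genes = rows$k_overlap,
    pathway_genes = rows$K_pathway,
    fold_enrichment = round(rows$fold_enrichment, 2),
    enrichment_fdr = signif(rows$fdr, 3),
    gene_list = rows$overlap_genes
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
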