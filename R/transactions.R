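#' Build an itemset transaction database from a report cohort
#'
#' Converts each report into one transaction over a fixed vocabulary of
#' items. An item is a (label, kind) pair where kind is `"ade"` (adverse
#' event term) or `"drug"` (co-reported suspect product or active
#' ingredient); the same label may exist under both kinds. The cohort drug
#' itself is excluded by default: it is present in every report of the
#' cohort by construction, so mining it as an item would contaminate every
#' rule.
#'
#' @param rs A deduplicated [report_set()].
#' @param kinds Item kinds to include: subset of `c("ade", "drug")`.
#' @param exclude Canonical labels omitted from the vocabulary (default the
#'   cohort drug, `"dexmedetomidine"`). Applies to both kinds.
#' @param synonym_map Synonym map used to normalize report terms.
#' @return An object of class `transaction_db`: a list with `n_transactions`,
#'   `transactions` (list of integer item-ID vectors), and `vocabulary`
#'   (data frame with columns `label`, `kind`).
#' @export
build_transactions <- function(rs, kinds = c("ade", "drug"),
                               exclude = "dexmedetomidine",
                               synonym_map = default_synonyms()) {
  stopifnot(inherits(rs, "report_set"))
  kinds <- match.arg(kinds, several.ok = TRUE)
  if (length(rs) == 0L)
    stop("cannot build transactions from an empty report set", call. = FALSE)
  per_report <- lapply(rs$reports, function(r) {
    keys <- character()
    if ("ade" %in% kinds) {
      ades <- setdiff(normalize_term(r$adverse_events, synonym_map), exclude)
      keys <- c(keys, item_key(ades, "ade"))
    }
    if ("drug" %in% kinds) {
      drugs <- setdiff(report_drug_terms(r, synonym_map), exclude)
      keys <- c(keys, item_key(drugs, "drug"))
    }
    keys
  })
  vocab_keys <- sort(unique(unlist(per_report)))
  transactions <- lapply(per_report, function(k)
    sort(match(k, vocab_keys)))
  structure(
    list(
      n_transactions = length(transactions),
      transactions = transactions,
      vocabulary = key_to_vocab(vocab_keys)
    ),
    class = "transaction_db"
  )
}

# Items are addressed internally by the key "<kind>:<label>".
item_key <- function(label, kind) {
  if (length(label) == 0L) return(character())
  paste0(kind, ":", label)
}

key_to_vocab <- function(keys) {
  kind <- sub(":.*$", "", keys)
  label <- sub("^[^:]+:", "", keys)
  data.frame(label = label, kind = kind, stringsAsFactors = FALSE)
}

vocab_keys <- function(db) item_key(db$vocabulary$label, db$vocabulary$kind)

#' @export
print.transaction_db <- function(x, ...) {
  cat("<transaction_db> ", x$n_transactions, " transactions, ",
      nrow(x$vocabulary), " items (",
      paste(sprintf("%s: %d", names(table(x$vocabulary$kind)),
                    as.integer(table(x$vocabulary$kind))), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

# Resolve user-facing item references ("label" or "kind:label") to vocabulary
# row indices. Bare labels must be unambiguous across kinds.
resolve_items <- function(db, items, kind = NULL) {
  keys <- vocab_keys(db)
  vapply(items, function(it) {
    if (grepl(":", it, fixed = TRUE)) {
      id <- match(it, keys)
      if (is.na(id)) stop("unknown item: ", it, call. = FALSE)
      return(id)
    }
    kind_ok <- if (is.null(kind)) TRUE else db$vocabulary$kind == kind
    hits <- which(db$vocabulary$label == it & kind_ok)
    if (length(hits) == 0L) stop("unknown item: ", it, call. = FALSE)
    if (length(hits) > 1L)
      stop("ambiguous item '", it, "': present as ",
           paste(db$vocabulary$kind[hits], collapse = " and "),
           "; qualify as \"kind:label\"", call. = FALSE)
    hits
  }, integer(1), USE.NAMES = FALSE)
}

# Number of transactions containing every item in `ids` (vocabulary indices).
joint_count_ids <- function(db, ids) {
  sum(vapply(db$transactions, function(tr) all(ids %in% tr), logical(1)))
}

#' Count transactions containing an item
#'
#' @param db A `transaction_db`.
#' @param item Item reference: a label, or `"kind:label"` if the label exists
#'   under both kinds.
#' @param kind Optional kind restriction for bare labels.
#' @return Integer count of transactions containing the item.
#' @export
item_count <- function(db, item, kind = NULL) {
  stopifnot(inherits(db, "transaction_db"))
  id <- resolve_items(db, item, kind)
  joint_count_ids(db, id)
}

#' Rank the most frequent items of a kind
#'
#' Returns the `k` most frequently occurring items of the requested kind,
#' count-descending; ties are broken lexicographically by label so that the
#' ranking is deterministic and stable under permutation of the transactions.
#'
#' @param db A `transaction_db`.
#' @param kind `"ade"` or `"drug"`.
#' @param k Number of items to return (the full ranking if `k` exceeds the
#'   vocabulary).
#' @return Data frame with columns `rank`, `label`, `count`.
#' @export
top_items <- function(db, kind = "ade", k = 10L) {
  stopifnot(inherits(db, "transaction_db"), k >= 1)
  ids <- which(db$vocabulary$kind == kind)
  if (length(ids) == 0L)
    return(data.frame(rank = integer(), label = character(), count = integer()))
  counts <- tabulate(unlist(lapply(db$transactions, unique)),
                     nbins = nrow(db$vocabulary))[ids]
  labels <- db$vocabulary$label[ids]
  ord <- order(-counts, labels)
  n <- min(k, length(ids))
  data.frame(rank = seq_len(n),
             label = labels[ord][seq_len(n)],
             count = counts[ord][seq_len(n)],
             stringsAsFactors = FALSE)
}

#' Write a transaction database in basket format
#'
#' One transaction per line; items as tab-separated `"kind:label"` tokens.
#' Empty transactions are written as empty lines, so the round trip through
#' [read_basket()] is exact.
#'
#' @param db A `transaction_db`.
#' @param path Output file path.
#' @export
write_basket <- function(db, path) {
  stopifnot(inherits(db, "transaction_db"))
  keys <- vocab_keys(db)
  lines <- vapply(db$transactions, function(tr)
    paste(keys[tr], collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a transaction database from basket format
#'
#' @param path File written by [write_basket()].
#' @return A `transaction_db` equal (up to vocabulary ordering, which is
#'   canonical) to the one written.
#' @export
read_basket <- function(path) {
  lines <- readLines(path)
  per_tr <- lapply(lines, function(l)
    if (nzchar(l)) strsplit(l, "\t", fixed = TRUE)[[1]] else character())
  keys <- sort(unique(unlist(per_tr)))
  structure(
    list(
      n_transactions = length(per_tr),
      transactions = lapply(per_tr, function(k) sort(match(k, keys))),
      vocabulary = key_to_vocab(keys)
    ),
    class = "transaction_db"
  )
}
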