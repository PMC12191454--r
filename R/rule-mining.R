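#' Support of an itemset
#'
#' Fraction of transactions containing every item of the set: the joint
#' count divided by the total number of transactions. The exact integer
#' count is attached as attribute `"count"`.
#'
#' @param db A `transaction_db`.
#' @param items Character vector of item references (labels or
#'   `"kind:label"`).
#' @param kind Optional kind restriction for bare labels.
#' @return Support in `[0, 1]`, with `attr(, "count")` the joint count.
#' @export
itemset_support <- function(db, items, kind = NULL) {
  stopifnot(inherits(db, "transaction_db"), length(items) >= 1L)
  ids <- resolve_items(db, items, kind)
  cnt <- joint_count_ids(db, ids)
  structure(cnt / db$n_transactions, count = cnt)
}

#' Confidence of a rule antecedent -> consequent
#'
#' Conditional frequency of the consequent given the antecedent: the number
#' of transactions containing both itemsets divided by the number containing
#' the antecedent.
#'
#' @param db A `transaction_db`.
#' @param antecedent,consequent Item references (see [itemset_support()]).
#' @param antecedent_kind,consequent_kind Optional kind restrictions.
#' @return Confidence in `[0, 1]`.
#' @export
rule_confidence <- function(db, antecedent, consequent,
                            antecedent_kind = NULL, consequent_kind = NULL) {
  a <- resolve_items(db, antecedent, antecedent_kind)
  c_ <- resolve_items(db, consequent, consequent_kind)
  na <- joint_count_ids(db, a)
  if (na == 0L)
    stop("undefined rule: antecedent occurs in no transaction", call. = FALSE)
  joint_count_ids(db, union(a, c_)) / na
}

#' Lift of a rule antecedent -> consequent
#'
#' Ratio of the observed joint support to the product of the marginal
#' supports: `count(X and Y) * N / (count(X) * count(Y))`. Lift is 1 under
#' independence and symmetric in the two itemsets.
#'
#' @inheritParams rule_confidence
#' @return Non-negative lift value.
#' @export
rule_lift <- function(db, antecedent, consequent,
                      antecedent_kind = NULL, consequent_kind = NULL) {
  a <- resolve_items(db, antecedent, antecedent_kind)
  c_ <- resolve_items(db, consequent, consequent_kind)
  na <- joint_count_ids(db, a)
  nc <- joint_count_ids(db, c_)
  if (na == 0L || nc == 0L)
    stop("undefined rule: a marginal support is zero", call. = FALSE)
  joint_count_ids(db, union(a, c_)) * db$n_transactions / (na * nc)
}

#' Rule filter thresholds
#'
#' The screening thresholds applied to candidate rules: minimum lift,
#' minimum joint count, and the fixed consequent itemset. The defaults
#' (lift >= 1.5, count >= 10, consequent bradycardia) are the conventional
#' screen for a desk-scale spontaneous-report cohort.
#'
#' @param min_lift Minimum lift (default 1.5).
#' @param min_count Minimum joint count (default 10).
#' @param consequent Consequent item references (default `"bradycardia"`).
#' @param consequent_kind Kind of the consequent items (default `"ade"`).
#' @return An object of class `rule_filter`.
#' @export
rule_filter <- function(min_lift = 1.5, min_count = 10L,
                        consequent = "bradycardia", consequent_kind = "ade") {
  stopifnot(min_lift >= 0, min_count >= 0, length(consequent) >= 1L)
  structure(list(min_lift = min_lift, min_count = as.integer(min_count),
                 consequent = consequent, consequent_kind = consequent_kind),
            class = "rule_filter")
}

#' Mine association rules with a fixed consequent
#'
#' Enumerates antecedent itemsets of the given kind level-wise
#' (Apriori-style): an antecedent survives level `l` only if its joint count
#' with the consequent is at least `min_count`, which is anti-monotone in
#' the antecedent and therefore prunes all of its supersets. Each surviving
#' antecedent is emitted as a rule `antecedent -> consequent` if it also
#' passes the lift threshold. Rules are sorted lift-descending, ties broken
#' by count descending then antecedent label.
#'
#' @param db A `transaction_db`.
#' @param filter A [rule_filter()].
#' @param antecedent_kind `"ade"` for co-presenting events, `"drug"` for
#'   co-administered drug (interaction) screening.
#' @param max_antecedent_size Maximum antecedent itemset size (default 1:
#'   single-item antecedents).
#' @return Data frame of class `rule_set` with columns `antecedent`,
#'   `consequent`, `support`, `confidence`, `coverage`, `lift`, `count`
#'   (full precision; see [format_rules()] for display rounding).
#' @export
mine_rules <- function(db, filter = rule_filter(), antecedent_kind = "ade",
                       max_antecedent_size = 1L) {
  stopifnot(inherits(db, "transaction_db"), inherits(filter, "rule_filter"),
            max_antecedent_size >= 1L)
  cons_ids <- resolve_items(db, filter$consequent, filter$consequent_kind)
  n_cons <- joint_count_ids(db, cons_ids)
  N <- db$n_transactions
  cand_ids <- setdiff(which(db$vocabulary$kind == antecedent_kind), cons_ids)

  # Level-wise enumeration; frontier holds antecedent id-sets whose joint
  # count with the consequent passed min_count.
  emit <- list()
  frontier <- lapply(cand_ids, identity)
  level <- 1L
  repeat {
    joint <- vapply(frontier, function(ids)
      joint_count_ids(db, c(ids, cons_ids)), integer(1))
    keep <- joint >= filter$min_count
    frontier <- frontier[keep]
    joint <- joint[keep]
    for (i in seq_along(frontier)) {
      ids <- frontier[[i]]
      n_ant <- joint_count_ids(db, ids)
      if (n_ant == 0L || n_cons == 0L) next  # lift undefined (min_count = 0)
      lift <- joint[i] * N / (n_ant * n_cons)
      if (lift >= filter$min_lift)
        emit[[length(emit) + 1L]] <- list(
          ids = ids, count = joint[i], n_ant = n_ant, lift = lift)
    }
    if (level >= max_antecedent_size || length(frontier) == 0L) break
    # Candidate generation: extend each surviving set by a larger-id item.
    frontier <- unlist(lapply(frontier, function(ids) {
      ext <- cand_ids[cand_ids > max(ids)]
      lapply(ext, function(e) c(ids, e))
    }), recursive = FALSE)
    if (is.null(frontier)) frontier <- list()
    level <- level + 1L
  }

  rows <- lapply(emit, function(e) {
    data.frame(
      antecedent = paste(sort(db$vocabulary$label[e$ids]), collapse = " + "),
      consequent = paste(sort(db$vocabulary$label[cons_ids]), collapse = " + "),
      support = e$count / N,
      confidence = e$count / e$n_ant,
      coverage = e$n_ant / N,
      lift = e$lift,
      count = e$count,
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(antecedent = character(), consequent = character(),
               support = numeric(), confidence = numeric(),
               coverage = numeric(), lift = numeric(), count = integer(),
               stringsAsFactors = FALSE)
  out <- out[order(-out$lift, -out$count, out$antecedent), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "antecedent_kind") <- antecedent_kind
  attr(out, "consequent_count") <- n_cons
  attr(out, "n_transactions") <- N
  class(out) <- c("rule_set", "data.frame")
  out
}

#' Format a rule set for display
#'
#' Applies the conventional display rounding — support and coverage to 4
#' decimal places, confidence and lift to 3 — while [mine_rules()] retains
#' full precision.
#'
#' @param rules A `rule_set`.
#' @return Data frame with rounded columns.
#' @export
format_rules <- function(rules) {
  out <- as.data.frame(rules)
  out$support <- round(out$support, 4)
  out$coverage <- round(out$coverage, 4)
  out$confidence <- round(out$confidence, 3)
  out$lift <- round(out$lift, 3)
  out
}

#' Write a rule set as TSV
#'
#' Columns: antecedent, consequent, support, confidence, coverage, lift,
#' count, at display rounding.
#'
#' @param rules A `rule_set`.
#' @param path Output TSV path.
#' @export
write_rules <- function(rules, path) {
  utils::write.table(format_rules(rules), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
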