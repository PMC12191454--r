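#' Construct a 2x2 contingency table
#'
#' Cell layout follows the standard disproportionality design: rows are
#' with/without the consequent event (e.g. bradycardia), columns are
#' with/without the second item (another adverse event or a co-administered
#' drug). `n11` counts reports with both, `n22` reports with neither.
#'
#' @param n11,n12,n21,n22 Non-negative integer cell counts.
#' @return An object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(n11, n12, n21, n22) {
  cells <- c(n11 = n11, n12 = n12, n21 = n21, n22 = n22)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  if (sum(cells) == 0)
    stop("all-zero contingency table", call. = FALSE)
  structure(stats::setNames(as.list(as.integer(cells)), names(cells)),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$n11, x$n12, x$n21, x$n22), 2, 2, byrow = TRUE,
              dimnames = list(c("event", "no event"),
                              c("item", "no item")))
  print(m)
  invisible(x)
}

#' @export
as.matrix.contingency_2x2 <- function(x, ...) {
  matrix(c(x$n11, x$n12, x$n21, x$n22), 2, 2, byrow = TRUE)
}

#' Cross-tabulate two items of a transaction database
#'
#' Builds the 2x2 table for a (row item, column item) pair: `n11` counts
#' transactions with both items, `n12` row-item only, `n21` column-item
#' only, `n22` neither. Row item is conventionally the consequent event.
#'
#' @param db A `transaction_db`.
#' @param row_item,col_item Item references (labels or `"kind:label"`).
#' @param row_kind,col_kind Optional kind restrictions.
#' @return A [contingency_2x2()].
#' @export
table_for_pair <- function(db, row_item, col_item,
                           row_kind = NULL, col_kind = NULL) {
  stopifnot(inherits(db, "transaction_db"))
  r <- resolve_items(db, row_item, row_kind)
  c_ <- resolve_items(db, col_item, col_kind)
  if (identical(r, c_))
    stop("row and column item are identical", call. = FALSE)
  n11 <- joint_count_ids(db, c(r, c_))
  nr <- joint_count_ids(db, r)
  nc <- joint_count_ids(db, c_)
  contingency_2x2(n11 = n11, n12 = nr - n11, n21 = nc - n11,
                  n22 = db$n_transactions - nr - nc + n11)
}

# --- Exact inference on the 2x2 table ------------------------------------
#
# With all margins fixed, the count in cell (1,1) follows Fisher's
# noncentral hypergeometric distribution with noncentrality equal to the
# odds ratio psi. The point estimate is the conditional MLE (the psi whose
# conditional mean equals the observed cell), and the exact central CI
# inverts the distribution's tail probabilities at alpha/2 per side. At the
# boundary of the support the estimate and one CI limit degenerate to 0 or
# +Inf; no continuity correction is needed in this framework.

nchg_setup <- function(tab) {
  m <- tab$n11 + tab$n21          # column-1 margin (with item)
  n <- tab$n12 + tab$n22          # column-2 margin
  k <- tab$n11 + tab$n12          # row-1 margin (with event)
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  list(x = tab$n11, lo = lo, hi = hi, support = support,
       logdc = lchoose(m, support) + lchoose(n, k - support))
}

nchg_density <- function(s, psi) {
  logd <- s$logdc + s$support * log(psi)
  d <- exp(logd - max(logd))
  d / sum(d)
}

nchg_mean <- function(s, psi) {
  if (psi == 0) return(s$lo)
  if (!is.finite(psi)) return(s$hi)
  sum(s$support * nchg_density(s, psi))
}

# P(X >= x) and P(X <= x) under noncentrality psi.
nchg_tail_ge <- function(s, x, psi) sum(nchg_density(s, psi)[s$support >= x])
nchg_tail_le <- function(s, x, psi) sum(nchg_density(s, psi)[s$support <= x])

# Solve f(log psi) = 0 for monotone f with a sign change located by
# doubling; tol is relative on psi.
nchg_root <- function(f, tol = 1e-8) {
  lo <- -1; hi <- 1
  while (f(lo) > 0 && lo > -745) lo <- lo * 2
  while (f(hi) < 0 && hi < 745) hi <- hi * 2
  r <- stats::uniroot(f, c(lo, hi), tol = tol)
  exp(r$root)
}

# Exact two-sided p at psi = 1: total probability of tables no more likely
# than the observed one (the usual two-sided convention).
nchg_p_twosided <- function(s) {
  d <- nchg_density(s, 1)
  dx <- d[match(s$x, s$support)]
  min(1, sum(d[d <= dx * (1 + 1e-7)]))
}

cond_mle_psi <- function(s, tol = 1e-8) {
  if (s$x == s$lo) return(0)
  if (s$x == s$hi) return(Inf)
  nchg_root(function(t) nchg_mean(s, exp(t)) - s$x, tol)
}

#' Odds ratio of a 2x2 table with exact confidence interval
#'
#' The default estimator is the conditional maximum-likelihood odds ratio:
#' the noncentrality maximizing the noncentral hypergeometric likelihood of
#' the observed table with all margins fixed, paired with the exact central
#' confidence interval obtained by inverting the conditional tail
#' probabilities at `alpha/2` per side. The unconditional sample
#' (cross-product) estimate `n11*n22 / (n12*n21)` is always reported
#' alongside. Boundary tables (a zero in the first row-column cross) yield
#' 0 or `Inf` estimates with one-sided intervals rather than an error.
#'
#' @param table A [contingency_2x2()].
#' @param alpha Two-sided significance level (default 0.05 for a 95% CI).
#' @param estimator `"conditional_mle"` (default) or `"sample"` for the
#'   point estimate; the CI is exact in both cases.
#' @param tol Relative root-finding tolerance for the MLE and CI endpoints.
#' @return An object of class `or_result`: a list with `estimate`, `ci_low`,
#'   `ci_high`, `alpha`, `significant` (CI excludes 1), `sample_or`, and
#'   `estimator`.
#' @export
odds_ratio <- function(table, alpha = 0.05,
                       estimator = c("conditional_mle", "sample"),
                       tol = 1e-8) {
  stopifnot(inherits(table, "contingency_2x2"), alpha > 0, alpha < 1)
  estimator <- match.arg(estimator)
  s <- nchg_setup(table)
  sample_or <- (table$n11 * table$n22) / (table$n12 * table$n21)
  if (s$lo == s$hi) {
    # Degenerate margin: the table carries no information about psi.
    res <- list(estimate = NA_real_, ci_low = 0, ci_high = Inf,
                alpha = alpha, significant = FALSE,
                sample_or = sample_or, estimator = estimator)
    return(structure(res, class = "or_result"))
  }
  mle <- cond_mle_psi(s, tol)
  ci_low <- if (s$x == s$lo) 0 else
    nchg_root(function(t) nchg_tail_ge(s, s$x, exp(t)) - alpha / 2, tol)
  ci_high <- if (s$x == s$hi) Inf else
    nchg_root(function(t) alpha / 2 - nchg_tail_le(s, s$x, exp(t)), tol)
  estimate <- if (estimator == "conditional_mle") mle else sample_or
  structure(
    list(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
         alpha = alpha, significant = (ci_low > 1) || (ci_high < 1),
         sample_or = sample_or, estimator = estimator),
    class = "or_result"
  )
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR = %.4g, %g%% CI [%.4g, %.4g]%s\n",
              x$estimate, 100 * (1 - x$alpha), x$ci_low, x$ci_high,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Validate mined rules by exact disproportionality analysis
#'
#' For each rule the 2x2 table of (consequent item, antecedent item) is
#' cross-tabulated from the transaction database and the exact odds ratio
#' computed. A rule whose confidence interval includes 1 is flagged as not
#' significant; no multiple-testing adjustment is applied by default (the
#' per-rule CI-excludes-1 criterion), but Benjamini-Hochberg adjusted exact
#' p-values can be requested.
#'
#' @param db The `transaction_db` the rules were mined from.
#' @param rules A `rule_set` from [mine_rules()] (single-item antecedents).
#' @param alpha Significance level for the exact CIs.
#' @param adjust `"none"` (default) or `"BH"`: when `"BH"`, two-sided exact
#'   p-values are added and adjusted, and `significant` additionally
#'   requires `fdr <= alpha`.
#' @return Data frame with the rule columns plus `odds_ratio`, `ci_low`,
#'   `ci_high`, `sample_or`, `significant` (and `p_value`, `fdr` under BH).
#' @export
validate_rules <- function(db, rules, alpha = 0.05,
                           adjust = c("none", "BH")) {
  stopifnot(inherits(db, "transaction_db"))
  adjust <- match.arg(adjust)
  ant_kind <- attr(rules, "antecedent_kind")
  cons_kind <- "ade"
  if (nrow(rules) == 0L) {
    out <- as.data.frame(rules)
    out$odds_ratio <- out$ci_low <- out$ci_high <- out$sample_or <- numeric()
    out$significant <- logical()
    return(out)
  }
  res <- lapply(seq_len(nrow(rules)), function(i) {
    tab <- table_for_pair(db, rules$consequent[i], rules$antecedent[i],
                          row_kind = cons_kind, col_kind = ant_kind)
    or <- odds_ratio(tab, alpha = alpha)
    p <- if (adjust == "BH") nchg_p_twosided(nchg_setup(tab)) else NA_real_
    data.frame(odds_ratio = or$estimate, ci_low = or$ci_low,
               ci_high = or$ci_high, sample_or = or$sample_or,
               significant = or$significant, p_value = p)
  })
  res <- do.call(rbind, res)
  out <- cbind(as.data.frame(rules), res)
  if (adjust == "BH") {
    out$fdr <- bh_fdr(out$p_value)
    out$significant <- out$significant & out$fdr <= alpha
  } else {
    out$p_value <- NULL
  }
  out
}

#' Write a disproportionality table as TSV
#'
#' Columns: item, OR, CI lower, CI upper, significant, mirroring the
#' conventional validation-table layout; ORs and CI bounds at 2 decimal
#' places.
#'
#' @param validated Output of [validate_rules()].
#' @param path Output TSV path.
#' @export
write_validation <- function(validated, path) {
  df <- data.frame(
    item = validated$antecedent,
    odds_ratio = round(validated$odds_ratio, 2),
    ci_low = round(validated$ci_low, 2),
    ci_high = round(validated$ci_high, 2),
    significant = validated$significant
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
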