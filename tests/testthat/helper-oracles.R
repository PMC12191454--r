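# Brute-force oracles and small fixture builders shared across the suite.
# Oracles are deliberately naive and independent of the package internals.

# A tiny transaction database built directly from a list of character
# vectors of "kind:label" tokens, bypassing the report layer.
db_from_baskets <- function(baskets) {
  tmp <- tempfile(fileext = ".basket")
  on.exit(unlink(tmp))
  writeLines(vapply(baskets, paste, character(1), collapse = "\t"), tmp)
  read_basket(tmp)
}

# Exhaustive-scan support count: how many baskets contain all the tokens.
bf_count <- function(baskets, tokens) {
  sum(vapply(baskets, function(b) all(tokens %in% b), logical(1)))
}

# Exhaustive rule enumeration: all antecedent subsets (of one kind, up to
# max_size) against a fixed consequent token, filtered on count and lift.
bf_rules <- function(baskets, consequent, antecedent_kind,
                     min_lift, min_count, max_size = 1L) {
  N <- length(baskets)
  items <- sort(unique(unlist(baskets)))
  cands <- setdiff(items[startsWith(items, paste0(antecedent_kind, ":"))],
                   consequent)
  n_cons <- bf_count(baskets, consequent)
  out <- list()
  for (size in seq_len(min(max_size, length(cands)))) {
    for (idx in utils::combn(length(cands), size, simplify = FALSE)) {
      ant <- cands[idx]
      joint <- bf_count(baskets, c(ant, consequent))
      if (joint < min_count) next
      n_ant <- bf_count(baskets, ant)
      if (n_ant == 0 || n_cons == 0) next
      lift <- joint * N / (n_ant * n_cons)
      if (lift < min_lift) next
      label <- paste(sort(sub("^[^:]+:", "", ant)), collapse = " + ")
      out[[length(out) + 1L]] <- data.frame(
        antecedent = label, count = joint, lift = lift,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(antecedent = character(), count = integer(),
                      lift = numeric()))
  res <- do.call(rbind, out)
  res[order(-res$lift, -res$count, res$antecedent), , drop = FALSE]
}

# Random basket database over a small vocabulary, seeded.
random_baskets <- function(seed, n_tr = 30L, n_ade = 6L, n_drug = 4L,
                           p = 0.3) {
  set.seed(seed)
  vocab <- c(sprintf("ade:a%02d", seq_len(n_ade)),
             sprintf("drug:d%02d", seq_len(n_drug)))
  lapply(seq_len(n_tr), function(i) {
    b <- vocab[stats::runif(length(vocab)) < p]
    if (!length(b)) b <- sample(vocab, 1)
    b
  })
}

# Independent BH step-up reimplementation (sort, m*p/i, running minimum
# from the largest p, cap at 1, restore input order).
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Hypergeometric upper tail by explicit enumeration of all n-subsets of a
# small universe.
bf_hyper_tail <- function(k, n, K, N) {
  stopifnot(N <= 25)
  subsets <- utils::combn(N, n, simplify = FALSE)
  hits <- vapply(subsets, function(s) sum(s <= K) >= k, logical(1))
  mean(hits)
}

# Random small report sets for property tests on the report store.
random_report_set <- function(seed, n = 20L) {
  set.seed(seed)
  reports <- lapply(seq_len(n), function(i) {
    case <- sample.int(ceiling(n / 2), 1)
    safety_report(
      case_id = sprintf("c%02d", case),
      adverse_events = sample(c("bradycardia", "hypotension", "pyrexia"),
                              sample(1:2, 1)),
      # duplicates of one case report the same suspect drug, as real
      # duplicate submissions do
      suspect_active_ingredients =
        if (case %% 2 == 0) "dexmedetomidine" else "midazolam",
      source_kind = if (stats::runif(1) < 0.3) "literature" else "direct",
      received_date = as.Date("2021-01-01") + sample.int(100, 1)
    )
  })
  report_set(reports, "random fixture")
}

case_ids <- function(rs) vapply(rs$reports, `[[`, character(1), "case_id")

# The bundled worked-example margins, as plain data for expectations.
table4_margins <- data.frame(
  label = c("syncope", "loss of consciousness", "cardiac arrest",
            "hypotension", "overdose", "drug interaction",
            "product administered to patient of inappropriate age",
            "cardio-respiratory arrest", "respiratory arrest"),
  antecedent = c(18L, 27L, 119L, 128L, 33L, 61L, 47L, 43L, 74L),
  joint = c(11L, 14L, 44L, 46L, 10L, 17L, 11L, 10L, 15L),
  lift = c(4.711, 3.997, 2.850, 2.770, 2.336, 2.148, 1.804, 1.793, 1.562),
  support = c(0.0068, 0.0087, 0.0273, 0.0286, 0.0062, 0.0106, 0.0068,
              0.0062, 0.0093),
  confidence = c(0.611, 0.519, 0.370, 0.359, 0.303, 0.279, 0.234, 0.233,
                 0.203),
  or = c(11.04, 7.65, 4.71, 4.54, 3.01, 2.73, 2.11, 2.08, 1.76),
  significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

table6_margins <- data.frame(
  label = c("lactated ringer's solution", "bupivacaine", "risperidone",
            "albuterol", "potassium chloride", "haloperidol", "sevoflurane"),
  antecedent = c(17L, 31L, 38L, 52L, 68L, 83L, 107L),
  joint = c(12L, 12L, 12L, 13L, 14L, 17L, 21L),
  lift = c(5.441, 2.984, 2.434, 1.927, 1.587, 1.579, 1.513),
  support = c(0.0074, 0.0074, 0.0074, 0.0081, 0.0087, 0.0106, 0.0130),
  confidence = c(0.706, 0.387, 0.316, 0.250, 0.206, 0.205, 0.196),
  or = c(16.96, 4.43, 3.22, 2.32, 1.79, 1.79, 1.71),
  significant = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

table8_expected <- data.frame(
  pathway = c("Ribosome", "Circadian rhythm", "Cardiac muscle contraction",
              "Oxidative phosphorylation", "Mitophagy-animal",
              "Acute myeloid leukemia", "Parkinson's disease",
              "Chemical carcinogenesis-reactive oxygen species",
              "Hypertrophic cardiomyopathy", "Coronavirus disease-COVID-19"),
  k = c(20L, 4L, 8L, 12L, 6L, 6L, 21L, 17L, 7L, 18L),
  K = c(130L, 34L, 87L, 133L, 68L, 70L, 262L, 220L, 91L, 235L),
  fe = c(8.22, 6.29, 4.92, 4.82, 4.72, 4.58, 4.28, 4.13, 4.11, 4.09),
  stringsAsFactors = FALSE
)
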