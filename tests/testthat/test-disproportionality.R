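test_that("table_for_pair equals brute-force cross-tabulation", {
  for (seed in 1:5) {
    baskets <- random_baskets(seed, n_tr = 40)
    db <- db_from_baskets(baskets)
    keys <- paste0(db$vocabulary$kind, ":", db$vocabulary$label)
    for (p in utils::combn(keys[1:5], 2, simplify = FALSE)) {
      tab <- table_for_pair(db, p[1], p[2])
      n11 <- bf_count(baskets, p)
      nr <- bf_count(baskets, p[1]); nc <- bf_count(baskets, p[2])
      expect_equal(tab$n11, n11)
      expect_equal(tab$n12, nr - n11)
      expect_equal(tab$n21, nc - n11)
      expect_equal(tab$n22, length(baskets) - nr - nc + n11)
    }
  }
  db <- db_from_baskets(list("ade:x", "ade:y"))
  expect_equal(table_for_pair(db, "ade:x", "ade:y")$n11, 0)  # disjoint items
  expect_error(table_for_pair(db, "ade:x", "ade:x"), "identical")
})

test_that("reconstructed pair margins give the expected 2x2 cells", {
  spec <- cohort_spec(1611, 209,
                      pairs = data.frame(label = "syncope", kind = "ade",
                                         antecedent = 18, joint = 11))
  db <- build_transactions(generate_exact(spec))
  tab <- table_for_pair(db, "ade:bradycardia", "ade:syncope")
  expect_equal(unlist(tab), c(n11 = 11, n12 = 198, n21 = 7, n22 = 1395))
})

test_that("conditional-MLE odds ratio matches the independent exact-test oracle", {
  set.seed(20)
  tables <- c(
    list(c(11, 198, 7, 1395), c(12, 197, 5, 1397), c(3, 1, 2, 9)),
    lapply(1:12, function(i) rpois(4, lambda = sample(c(5, 30, 200), 1)) + 1)
  )
  for (tb in tables) {
    tab <- contingency_2x2(tb[1], tb[2], tb[3], tb[4])
    mine <- odds_ratio(tab)
    oracle <- stats::fisher.test(matrix(tb, 2, 2, byrow = TRUE))
    # the oracle's own root-finding is looser than ours, hence the 1%
    expect_equal(mine$estimate, unname(oracle$estimate), tolerance = 1e-3)
    expect_equal(mine$ci_low, oracle$conf.int[1], tolerance = 1e-2)
    expect_equal(mine$ci_high, oracle$conf.int[2], tolerance = 1e-2)
    expect_equal(mine$significant,
                 oracle$conf.int[1] > 1 || oracle$conf.int[2] < 1)
  }
})

test_that("independence tables give an odds ratio of exactly 1", {
  for (tb in list(c(4, 8, 2, 4), c(10, 10, 10, 10), c(6, 3, 4, 2))) {
    tab <- contingency_2x2(tb[1], tb[2], tb[3], tb[4])
    expect_equal(odds_ratio(tab)$estimate, 1, tolerance = 1e-7)
    expect_equal(odds_ratio(tab, estimator = "sample")$estimate, 1)
    expect_false(odds_ratio(tab)$significant)
  }
})

test_that("estimates respect the table symmetries", {
  tab <- contingency_2x2(11, 198, 7, 1395)
  est <- odds_ratio(tab)$estimate
  # swapping both rows and both columns leaves the estimate unchanged
  swapped <- contingency_2x2(1395, 7, 198, 11)
  expect_equal(odds_ratio(swapped)$estimate, est, tolerance = 1e-6)
  # swapping only the rows inverts it
  rows <- contingency_2x2(7, 1395, 11, 198)
  expect_equal(odds_ratio(rows)$estimate, 1 / est, tolerance = 1e-6)
})

test_that("conditional-MLE and sample estimates agree on well-filled tables", {
  set.seed(33)
  for (i in 1:20) {
    tb <- sample(20:400, 4, replace = TRUE)
    tab <- contingency_2x2(tb[1], tb[2], tb[3], tb[4])
    cm <- odds_ratio(tab)$estimate
    so <- (tb[1] * tb[4]) / (tb[2] * tb[3])
    expect_lt(abs(cm - so) / so, 0.01)
  }
})

test_that("boundary tables degenerate to 0 or Inf without an exception", {
  zero_low <- odds_ratio(contingency_2x2(0, 20, 5, 100))
  expect_equal(zero_low$estimate, 0)
  expect_equal(zero_low$ci_low, 0)
  expect_gt(zero_low$ci_high, 0)
  zero_high <- odds_ratio(contingency_2x2(5, 0, 10, 100))
  expect_equal(zero_high$estimate, Inf)
  expect_equal(zero_high$ci_high, Inf)
  expect_error(contingency_2x2(0, 0, 0, 0), "all-zero")
  # degenerate margin: no information about the odds ratio
  degen <- odds_ratio(contingency_2x2(0, 0, 10, 90))
  expect_true(is.na(degen$estimate))
  expect_false(degen$significant)
})

test_that("exact CIs achieve nominal coverage under the conditional model", {
  # draw n11 from the noncentral hypergeometric at a known true odds ratio
  # and check the 95% CI covers it at >= nominal rate minus sampling noise
  true_or <- 3
  tab0 <- contingency_2x2(10, 30, 40, 120)  # fixes the margins
  s <- pvmine:::nchg_setup(tab0)
  probs <- pvmine:::nchg_density(s, true_or)
  set.seed(2024)
  draws <- sample(s$support, 400, replace = TRUE, prob = probs)
  covered <- vapply(draws, function(x) {
    k <- tab0$n11 + tab0$n12
    m <- tab0$n11 + tab0$n21
    tab <- contingency_2x2(x, k - x, m - x,
                           tab0$n22 + tab0$n21 - (m - x))
    or <- odds_ratio(tab)
    or$ci_low <= true_or && true_or <= or$ci_high
  }, logical(1))
  # binomial noise at n = 400: sd ~ 0.011; exact intervals are conservative
  expect_gte(mean(covered), 0.95 - 0.03)
})

test_that("validate_rules reproduces the worked-example significance splits", {
  spec <- cohort_spec_from_json(example_spec_path("table4_table6"))
  db <- build_transactions(deduplicate(generate_exact(spec)))
  ade <- validate_rules(db, mine_rules(db, rule_filter(), "ade"))
  expect_equal(sum(ade$significant), 6)
  expect_setequal(
    ade$antecedent[!ade$significant],
    c("product administered to patient of inappropriate age",
      "cardio-respiratory arrest", "respiratory arrest"))
  ddi <- validate_rules(db, mine_rules(db, rule_filter(), "drug"))
  expect_equal(sum(ddi$significant), 4)
  expect_setequal(ddi$antecedent[!ddi$significant],
                  c("potassium chloride", "haloperidol", "sevoflurane"))
  # empty rule list -> empty output
  empty <- mine_rules(db, rule_filter(min_count = 1e6), "ade")
  expect_equal(nrow(validate_rules(db, empty)), 0)
})

test_that("optional BH adjustment tightens the significance flag", {
  spec <- cohort_spec_from_json(example_spec_path("table4_table6"))
  db <- build_transactions(deduplicate(generate_exact(spec)))
  rules <- mine_rules(db, rule_filter(), "ade")
  plain <- validate_rules(db, rules)
  bh <- validate_rules(db, rules, adjust = "BH")
  expect_true(all(c("p_value", "fdr") %in% names(bh)))
  expect_true(all(bh$fdr >= bh$p_value - 1e-12))
  expect_true(all(bh$significant <= plain$significant))
})
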