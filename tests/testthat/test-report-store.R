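test_that("normalize_term folds case and whitespace and applies synonyms", {
  expect_equal(normalize_term("PRECEDEX"), "dexmedetomidine")
  expect_equal(normalize_term("dexmedetomidine hydrochloride"),
               "dexmedetomidine")
  expect_equal(normalize_term(" Bradycardia "), "bradycardia")
  expect_equal(normalize_term(c("Bradycardia", "bradycardia ")),
               "bradycardia")
  expect_length(normalize_term(character()), 0)
  # custom maps as named vector or data frame
  expect_equal(normalize_term("versed", c(versed = "midazolam")),
               "midazolam")
  expect_equal(
    normalize_term("versed", data.frame(raw = "versed",
                                        canonical = "midazolam")),
    "midazolam")
})

test_that("safety_report enforces its invariants", {
  expect_error(safety_report("", "bradycardia"), "case_id")
  expect_error(safety_report("c1", c("", "  ")), "normalization")
  expect_error(safety_report("c1", "bradycardia", age_years = -1),
               "non-negative")
  r <- safety_report("c1", "bradycardia")
  expect_s3_class(r, "safety_report")
  expect_identical(r$source_kind, "direct")
})

write_fixture_csv <- function(rows, path,
                              header = paste0('"Case ID","Suspect Product Names",',
                                              '"Suspect Product Active Ingredients",',
                                              '"Reactions","Report Source","Sex",',
                                              '"Patient Age","Event Date",',
                                              '"Outcomes","Reason for Use"')) {
  writeLines(c(header, rows), path)
  path
}

test_that("load_reports drops degenerate rows and reports them", {
  f <- write_fixture_csv(c(
    '"c1","Precedex","dexmedetomidine","Bradycardia; Syncope","Direct","F","64","2021-03-01","Hospitalized","sedation"',
    '"c2","Precedex","dexmedetomidine","","Direct","M","55","2021-03-02","",""',
    '"c3","","dexmedetomidine","Pyrexia","Literature","","","","",""'
  ), tempfile(fileext = ".csv"))
  rs <- load_reports(f, dialect = "faers")
  expect_length(rs, 2)
  lr <- attr(rs, "load_report")
  expect_equal(lr$n_dropped, 1)
  expect_equal(lr$dropped_reasons$empty_reactions, 1)
  expect_equal(case_ids(rs), c("c1", "c3"))
  expect_identical(rs$reports[[2]]$source_kind, "literature")
  expect_equal(rs$reports[[1]]$adverse_events, c("Bradycardia", "Syncope"))
})

test_that("load_reports rejects malformed layouts", {
  dup <- tempfile(fileext = ".csv")
  writeLines(c('"Case ID","Case ID","Reactions"', '"a","b","c"'), dup)
  expect_error(load_reports(dup), "duplicated column headers")
  expect_error(load_reports(tempfile(), dialect = "nope"),
               "unknown dialect")
  expect_error(load_reports(tempfile(fileext = ".csv")), "not found")
})

test_that("filter_drug_cohort scopes to suspect product fields only", {
  in_products <- safety_report("p1", "bradycardia",
                               suspect_products = "Precedex")
  in_ingredients <- safety_report("p2", "pyrexia",
                                  suspect_active_ingredients =
                                    "dexmedetomidine hydrochloride")
  in_indications_only <- safety_report("p3", "pyrexia",
                                       suspect_products = "midazolam",
                                       indications = "dexmedetomidine")
  rs <- report_set(list(in_products, in_ingredients, in_indications_only))
  out <- filter_drug_cohort(rs, "dexmedetomidine")
  expect_equal(case_ids(out), c("p1", "p2"))
})

test_that("filter_drug_cohort recovers the seeded cohort size", {
  set.seed(42)
  reports <- lapply(1:100, function(i)
    safety_report(sprintf("r%03d", i), "pyrexia",
                  suspect_active_ingredients =
                    if (i <= 40) "dexmedetomidine" else "propofol"))
  rs <- report_set(sample(reports))
  expect_length(filter_drug_cohort(rs, "dexmedetomidine"), 40)
})

test_that("deduplicate removes literature reports and collapses case IDs", {
  lit <- function(id) safety_report(id, "pyrexia", source_kind = "literature")
  rs <- report_set(list(
    safety_report("a", "bradycardia"),
    lit("b"), lit("c"),
    safety_report("d", "hypotension"),
    safety_report("e", "pyrexia")
  ))
  out <- deduplicate(rs)
  expect_length(out, 3)
  expect_equal(attr(out, "dedup_log")$literature, 2)

  # latest received date wins among same-case-ID direct reports
  rs2 <- report_set(list(
    safety_report("x", "bradycardia", received_date = "2021-01-01"),
    safety_report("x", "hypotension", received_date = "2021-06-01")
  ))
  out2 <- deduplicate(rs2)
  expect_length(out2, 1)
  expect_equal(out2$reports[[1]]$adverse_events, "hypotension")
  expect_equal(attr(out2, "dedup_log")$duplicate_case_id, 1)

  # date ties (including missing dates) keep the first in input order
  rs3 <- report_set(list(
    safety_report("y", "bradycardia"),
    safety_report("y", "hypotension")
  ))
  expect_equal(deduplicate(rs3)$reports[[1]]$adverse_events, "bradycardia")
})

test_that("deduplicate is idempotent and commutes with cohort filtering", {
  for (seed in 1:5) {
    rs <- random_report_set(seed)
    once <- deduplicate(rs)
    twice <- deduplicate(once)
    expect_equal(case_ids(twice), case_ids(once))
    a <- filter_drug_cohort(deduplicate(rs), "dexmedetomidine")
    b <- deduplicate(filter_drug_cohort(rs, "dexmedetomidine"))
    expect_equal(case_ids(a), case_ids(b))
    # inputs are not mutated
    expect_length(rs, 20)
  }
})

test_that("report sets round-trip through JSON lines", {
  rs <- random_report_set(7)
  f <- tempfile(fileext = ".jsonl")
  write_reports_jsonl(rs, f)
  back <- read_reports_jsonl(f)
  expect_equal(length(back), length(rs))
  for (i in seq_along(rs$reports))
    expect_equal(back$reports[[i]], rs$reports[[i]])
})

test_that("dedup audit log is written as TSV", {
  rs <- deduplicate(random_report_set(3))
  f <- tempfile(fileext = ".tsv")
  write_dedup_audit(rs, f)
  audit <- read.delim(f)
  expect_setequal(audit$reason, c("literature", "duplicate_case_id"))
  expect_error(write_dedup_audit(random_report_set(3), tempfile()),
               "dedup_log")
})
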