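Package: pvmine
Title: Pharmacovigilance Signal Mining with Association Rules and Exact
    Disproportionality Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mining drug safety signals from spontaneous
    adverse-event report databases in the style of FAERS dashboard exports.
    Reports are normalized, deduplicated and filtered to a drug cohort,
    converted to itemset transactions, and mined for association rules
    (support, confidence, coverage, lift) linking co-reported adverse events
    or co-administered drugs to a consequent event such as bradycardia.
    Mined rules are validated by exact 2x2 disproportionality analysis using
    the conditional maximum-likelihood odds ratio with exact confidence
    intervals. A hypergeometric over-representation module computes pathway
    fold enrichment with Benjamini-Hochberg false discovery rates for a gene
    list against a GMT gene-set collection. A synthetic report-database
    generator with an exact-marginal mode turns any set of 2x2 margins into a
    reproducible worked example, and a pipeline runner orchestrates the
    stages end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
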