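vocab <- default_vocabulary()

test_that("coverage arithmetic is exact to 2 dp and guards its domain", {
  expect_equal(coverage(729, 13627)$percent, 5.35)
  expect_equal(coverage(0, 100)$percent, 0)
  expect_equal(coverage(822, 13602)$percent, 6.04)
  expect_error(coverage(1, 0), "positive")
  expect_error(coverage(5, 3), "\\[0, total\\]")
  # scale invariance in the integers
  for (k in c(2, 7, 13)) {
    expect_equal(coverage(k * 207, k * 8025)$percent,
                 coverage(207, 8025)$percent)
  }
})

test_that("pairwise comparison does exact set algebra", {
  r <- pairwise_compare(c("1", "2", "3"), c("2", "3", "4"))
  expect_equal(r$overlap_count, 2)
  expect_equal(r$unique_a_count, 1)
  expect_equal(r$unique_b_count, 1)
  expect_equal(r$unique_a_keys, "1")
  expect_equal(r$unique_b_keys, "4")

  same <- pairwise_compare(c("7", "8"), c("8", "7"))
  expect_equal(same$unique_a_count, 0)
  expect_equal(same$unique_b_count, 0)

  expect_error(pairwise_compare(load_fixture("table3"), load_fixture("table2")),
               "same")
})

test_that("pairwise comparison equals the brute-force oracle (property)", {
  set.seed(691)
  for (rep in 1:50) {
    a <- as.character(sample(1:400, sample(0:120, 1)))
    b <- as.character(sample(1:400, sample(0:120, 1)))
    got <- pairwise_compare(a, b)
    want <- oracle_pairwise(a, b)
    expect_identical(got$overlap_keys, want$overlap)
    expect_identical(got$unique_a_keys, want$unique_a)
    expect_identical(got$unique_b_keys, want$unique_b)
    # partition identities
    expect_equal(got$overlap_count + got$unique_a_count, length(unique(a)))
    expect_equal(got$overlap_count + got$unique_b_count, length(unique(b)))
    expect_length(intersect(got$unique_a_keys, got$unique_b_keys), 0)
  }
})

test_that("difference categorization follows the fixed precedence order", {
  keys <- c("k1", "k2", "k3", "k4", "k5", "k6")
  names_of <- c(
    k1 = "Lisinopril",                                        # IN term type
    k2 = "Timolol 2.5 MG/ML Ophthalmic Solution (Betimol)",   # dose form
    k3 = "tamsulosin 0.4 MG Oral Capsule",                    # BPH
    k4 = "Hydrochlorothiazide 12.5 MG / Lisinopril 10 MG Oral Tablet",
    k5 = "Olddrug 10 MG Oral Tablet",                         # retired
    k6 = "Newdrug 10 MG Oral Tablet")                         # nothing known
  tts <- c(k1 = "IN")
  statuses <- c(k5 = "retired")
  res <- categorize_differences(keys, names_of, tts, statuses, vocab)
  expect_equal(unname(res$assignments$category),
               c("term_type", "dose_form", "bph_indication", "combination",
                 "retired", "uncategorized"))
  expect_equal(sum(res$category_counts), length(keys))

  # term type outranks dose form when both apply
  both <- categorize_differences(
    "x", c(x = "Timolol Ophthalmic Solution"), c(x = "MIN"), vocab = vocab)
  expect_equal(both$assignments$category, "term_type")
})

test_that("hypertension cohort selection applies all three gates", {
  dx <- data.frame(
    patient_id = c("a", "b", "c", "d", "e", "f", "g"),
    code = c("401.9", "I10", "I10", "4019", "I10.9", "I15", "401"),
    code_type = c("ICD9", "ICD10", "ICD10", "ICD9", "ICD10", "ICD10", "ICD9"),
    encounter_type = c("outpatient", "outpatient", "other", "outpatient",
                       "outpatient", "outpatient", "outpatient"),
    age_at_encounter = c(45L, 17L, 45L, 80L, 50L, 60L, 18L),
    stringsAsFactors = FALSE)
  # a: qualifies; b: minor; c: not outpatient; d: undotted ICD-9 dialect
  # qualifies; e: I10 subcode excluded; f: wrong code; g: bare 401 at 18
  expect_equal(select_htn_cohort(dx), c("a", "d", "g"))
})

test_that("class frequency tables count each matched record once", {
  decisions <- data.frame(
    rxcui_matched = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    rxcui_classes = c("ACE", "ACE", "THIAZIDE+ACE", "BETA_BLOCKER", NA),
    stringsAsFactors = FALSE)
  tab <- class_frequency_table(decisions, "rxcui")
  expect_equal(tab$total_mapped, 4)
  expect_equal(sum(tab$rows$count), tab$total_mapped)
  # the combination is one row under its own label, not one per component
  expect_equal(tab$rows$count[tab$rows$class_label == "ACE"], 2L)
  expect_equal(tab$rows$count[tab$rows$class_label == "THIAZIDE+ACE"], 1L)
  expect_equal(tab$rows$percent[tab$rows$class_label == "ACE"], 50)

  single <- class_frequency_table(data.frame(
    rxcui_matched = TRUE, rxcui_classes = "CCB", stringsAsFactors = FALSE),
    "rxcui")
  expect_equal(single$rows$percent, 100)
})

test_that("frequency percentages sum to 100 within rounding slack (property)", {
  set.seed(217)
  for (rep in 1:20) {
    n <- sample(3:400, 1)
    labels <- sample(c(vocab$labels, "THIAZIDE+ACE"), n, replace = TRUE)
    decisions <- data.frame(rxcui_matched = TRUE, rxcui_classes = labels,
                            stringsAsFactors = FALSE)
    tab <- class_frequency_table(decisions, "rxcui")
    expect_lt(abs(sum(tab$rows$percent) - 100), 0.05)
  }
})

test_that("prescription coverage uses all records as the denominator", {
  decisions <- data.frame(rxcui_matched = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  cov <- prescription_coverage(decisions, "rxcui")
  expect_equal(cov$mapped_terms, 2L)
  expect_equal(cov$total_terms, 5L)
  expect_equal(cov$percent, 40)
  zero <- prescription_coverage(
    data.frame(rxcui_matched = rep(FALSE, 10)), "rxcui")
  expect_equal(zero$percent, 0)
})
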