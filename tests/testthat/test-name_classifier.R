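vocab <- default_vocabulary()

test_that("normalization applies the first-word and combination rules", {
  n1 <- normalize_raw_med_name("Lisinopril 10 MG Oral Tablet", vocab = vocab)
  expect_equal(n1$token, "lisinopril")
  expect_equal(n1$rule_applied, "first_word")
  expect_equal(n1$source, "Lisinopril 10 MG Oral Tablet")

  n2 <- normalize_raw_med_name("HCTZ-metoprolol 25-50 MG Oral Tablet",
                               vocab = vocab)
  expect_equal(n2$token, "hctz_metoprolol")
  expect_equal(n2$rule_applied, "combination_join")

  n3 <- normalize_raw_med_name("HCTZ/metoprolol 25-50 MG Oral Tablet",
                               vocab = vocab)
  expect_equal(n3$token, "hctz_metoprolol")

  expect_equal(normalize_raw_med_name("", vocab = vocab)$rule_applied,
               "unparseable")
  expect_equal(normalize_raw_med_name("12345 678", vocab = vocab)$rule_applied,
               "unparseable")
})

test_that("two bare words join only when both are known ingredients", {
  known <- c("hydrochlorothiazide", "metoprolol")
  joined <- normalize_raw_med_name("Hydrochlorothiazide Metoprolol 25-50 MG",
                                   known_ingredients = known, vocab = vocab)
  expect_equal(joined$token, "hydrochlorothiazide_metoprolol")
  expect_equal(joined$rule_applied, "combination_join")
  # "Oral Tablet" after a lone ingredient must not be absorbed
  plain <- normalize_raw_med_name("Metoprolol Tartrate 25 MG",
                                  known_ingredients = known, vocab = vocab)
  expect_equal(plain$token, "metoprolol")
  expect_equal(plain$rule_applied, "first_word")
})

test_that("exception patterns take precedence over extraction rules", {
  exceptions <- c("oral\\s+minoxidil" = "minoxidil")
  n <- normalize_raw_med_name("Oral Minoxidil 10 MG Tablet",
                              exceptions = exceptions, vocab = vocab)
  expect_equal(n$token, "minoxidil")
  expect_equal(n$rule_applied, "exception_list")
})

test_that("combination permutations expand orderings and abbreviations", {
  out <- expand_combination_permutations(
    c("hydrochlorothiazide", "metoprolol"),
    synonyms = list(hydrochlorothiazide = "hctz"))
  expect_setequal(out, c("hctz_metoprolol", "hydrochlorothiazide_metoprolol",
                         "metoprolol_hctz", "metoprolol_hydrochlorothiazide"))

  expect_setequal(expand_combination_permutations(c("a", "b")),
                  c("a_b", "b_a"))
  expect_error(expand_combination_permutations("lisinopril"), "at least 2")

  # 2 components, synonym-set sizes a=2 and b=1 -> 2*a*b tokens
  expect_length(expand_combination_permutations(
    c("hydrochlorothiazide", "lisinopril"),
    synonyms = list(hydrochlorothiazide = "hctz")), 4)
  # three components: 3! orderings
  expect_length(expand_combination_permutations(c("a", "b", "c")), 6)
})

test_that("name classification matches, resolves generics, discards the rest", {
  map <- load_fixture("table2")
  d <- classify_name("Lotensin 20 MG Oral Tablet", map, vocab = vocab)
  expect_true(d$matched)
  expect_equal(d$classes, "ACE")
  expect_equal(d$generic_of, "benazepril")

  expect_false(classify_name("Atorvastatin 40 MG Oral Tablet", map,
                             vocab = vocab)$matched)
  # timolol is deliberately absent from curated name maps
  expect_false(classify_name("Timolol 0.5% Ophthalmic Solution", map,
                             vocab = vocab)$matched)
})

test_that("classification is case-insensitive and pure", {
  map <- load_fixture("table2")
  raws <- c("Zestril 10 MG Oral Tablet", "CAPTOPRIL 25 MG ORAL TABLET",
            "enalapril 5 mg oral tablet", "Metformin 500 MG Oral Tablet")
  for (raw in raws) {
    a <- classify_name(raw, map, vocab = vocab)
    b <- classify_name(toupper(raw), map, vocab = vocab)
    c2 <- classify_name(raw, map, vocab = vocab)
    expect_equal(a$matched, b$matched)
    expect_equal(a$classes, b$classes)
    expect_equal(a[c("matched", "classes", "drug_count", "matched_key")],
                 c2[c("matched", "classes", "drug_count", "matched_key")])
  }
})

test_that("permutation closure: every ordering of a combination matches alike", {
  maps <- build_demo_maps(retired_fraction = 0, vocab = vocab)
  combo_keys <- map_keys(maps$name_map)[grepl("_", map_keys(maps$name_map))]
  expect_gt(length(combo_keys), 0)
  canonical <- unique(vapply(strsplit(combo_keys, "_"), function(parts)
    paste(sort(parts), collapse = "|"), character(1)))
  for (key in combo_keys) {
    raw <- paste0(gsub("_", "-", key), " 25-50 MG Oral Tablet")
    d <- classify_name(raw, maps$name_map, vocab = vocab)
    expect_true(d$matched, info = raw)
    expect_equal(d$drug_count, 2L, info = raw)
  }
  # all permutations of one product agree on the class set
  perms <- expand_combination_permutations(
    c("hydrochlorothiazide", "lisinopril"),
    synonyms = vocab$synonyms)
  classes <- lapply(perms, function(p)
    sort(classify_name(paste0(gsub("_", "/", p), " 12.5-10 MG Oral Tablet"),
                       maps$name_map, vocab = vocab)$classes))
  expect_true(all(vapply(classes, identical, logical(1), y = classes[[1]])))
  expect_setequal(classes[[1]], c("ACE", "THIAZIDE"))
})
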