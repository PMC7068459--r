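vocab <- default_vocabulary()

test_that("short RxCUIs are removed by string length", {
  rel <- ahtnclass:::terminology_relations(
    rxcui = c("12", "999", "1000", "858810"),
    class_name = "beta blocking agents", rela_source = "ATC",
    rela = "atc_class_member")
  res <- remove_short_rxcuis(rel)
  expect_equal(res$kept$rxcui, c("1000", "858810"))
  expect_equal(res$removed_count, 2)

  all_long <- remove_short_rxcuis(rel[3:4, ])
  expect_equal(all_long$removed_count, 0)
  expect_equal(nrow(all_long$kept), 2)

  none <- remove_short_rxcuis(rel[0, ])
  expect_equal(none$removed_count, 0)
  expect_equal(nrow(none$kept), 0)
})

test_that("ATC builder keeps accepted class names and is idempotent", {
  rel <- ahtnclass:::terminology_relations(
    rxcui = c("10101", "10101", "20202", "30303"),
    class_name = c("beta blocking agents", "beta blocking agents",
                   "lipid modifying agents", "ace inhibitors, plain"),
    rela_source = "ATC", rela = "atc_class_member",
    concept_name = c("Timolol 10 MG Oral Tablet", "Timolol 10 MG Oral Tablet",
                     "Atorvastatin 40 MG Oral Tablet",
                     "Lisinopril 10 MG Oral Tablet"))
  map <- build_atc_map(rel, vocab)
  expect_equal(sort(map_keys(map)), c("10101", "30303"))
  expect_equal(map_entry(map, "10101")$classes, "BETA_BLOCKER")
  expect_equal(map_entry(map, "30303")$classes, "ACE")

  # order invariance
  shuffled <- rel[c(4, 2, 3, 1), ]
  expect_equal(build_atc_map(shuffled, vocab)$entries, map$entries)
})

test_that("MED-RT builder applies the two-step may_treat + has_MoA filter", {
  rel <- ahtnclass:::terminology_relations(
    rxcui = c("10101", "10101",   # both steps -> in
              "20202",            # may_treat only -> out
              "30303", "30303"),  # MoA but may_treat is for glaucoma -> out
    class_name = c("Hypertension", "Adrenergic beta1-Antagonists",
                   "Hypertension",
                   "Glaucoma", "Adrenergic beta1-Antagonists"),
    rela_source = "MEDRT",
    rela = c("may_treat", "has_MoA", "may_treat", "may_treat", "has_MoA"))
  map <- build_medrt_map(rel, vocab)
  expect_equal(map_keys(map), "10101")
  expect_equal(map_entry(map, "10101")$classes, "BETA_BLOCKER")
})

test_that("builder outputs equal brute-force oracles on random relation sets", {
  set.seed(1504)
  for (rep in 1:8) {
    rel <- random_relations(sample(50:200, 1), vocab)
    atc_rel <- rel[rel$rela_source == "ATC", ]
    medrt_rel <- rel[rel$rela_source == "MEDRT", ]
    expect_identical(map_as_label_sets(build_atc_map(atc_rel, vocab)),
                     oracle_atc(atc_rel, vocab))
    built <- build_medrt_map(medrt_rel, vocab)
    expect_identical(map_as_label_sets(built), oracle_medrt(medrt_rel, vocab))
    # step 2 never adds keys beyond the may_treat-hypertension set
    htn <- unique(medrt_rel$rxcui[medrt_rel$rela == "may_treat" &
                                    tolower(medrt_rel$class_name) %in%
                                      vocab$may_treat_hypertension])
    expect_true(all(map_keys(built) %in% htn))
  }
})

test_that("drug-ontology builder merges indication and MoA lists", {
  indication <- list(hypertension = c("858810", "77777", "88888", "99999"))
  moa <- list(ACE = c("858810", "99999"), THIAZIDE = c("99999"))
  map <- build_dron_map(indication, moa, vocab = vocab,
                        display_names = c("858810" = "Enalapril Maleate 20 MG Oral Tablet"))
  expect_equal(map_entry(map, "858810")$classes, "ACE")
  # combination: on two MoA lists -> both labels, drug count 2
  expect_equal(map_entry(map, "99999")$classes, "ACE+THIAZIDE")
  expect_equal(map_entry(map, "99999")$drug_count, 2L)
  # indication-only keys are reported, not emitted
  expect_false("77777" %in% map_keys(map))
  expect_setequal(attr(map, "unassigned"), c("77777", "88888"))
})

test_that("drug-ontology builder honours manual additions and term-type policy", {
  indication <- list(hypertension = c("11111", "22222"))
  moa <- list(ACE = "11111")
  expect_warning(
    map <- build_dron_map(indication, moa,
                          manual_additions = list("22222" = "VASODILATOR",
                                                  "33333" = "CENTRAL_ACTING"),
                          vocab = vocab),
    "outside")
  expect_equal(map_entry(map, "22222")$classes, "VASODILATOR")
  expect_equal(map_entry(map, "33333")$classes, "CENTRAL_ACTING")

  # IN/MIN/PIN term types are dropped from the rxcui map
  map2 <- build_dron_map(list(hypertension = c("11111", "44444")),
                         list(ACE = c("11111", "44444")),
                         term_types = c("11111" = "SCD", "44444" = "IN"),
                         vocab = vocab)
  expect_equal(map_keys(map2), "11111")
})

test_that("reconciliation applies additions and exclusions with an audit", {
  base <- classification_map("rxcui", random_entries(10, "rxcui", vocab),
                             vocabulary = vocab, version_tag = "0.9")
  adds <- random_entries(3, "rxcui", vocab)
  adds$key <- as.character(100001:100003)  # guaranteed novel
  out <- reconcile_maps(base, adds)
  expect_equal(map_size(out), 13)
  expect_setequal(attr(out, "audit")$added, adds$key)

  # re-adding an existing entry identically is a no-op
  again <- reconcile_maps(out, out$entries[1, ])
  expect_equal(map_size(again), 13)
  expect_length(attr(again, "audit")$added, 0)

  # conflicting addition is an error, not an overwrite
  conflict <- out$entries[1, ]
  conflict$classes <- if (conflict$classes == "ACE") "ARB" else "ACE"
  conflict$drug_count <- 1L
  expect_error(reconcile_maps(out, conflict), "conflict")

  # exclusions remove keys and are audited
  excl <- reconcile_maps(out, exclusions = out$entries$key[1:2])
  expect_equal(map_size(excl), 11)
  expect_setequal(attr(excl, "audit")$excluded, out$entries$key[1:2])
})

test_that("reconciliation reproduces the v1.0 cardinality (2543 + 96)", {
  keys <- sprintf("%06d", 1:2543)
  base <- classification_map("rxcui", data.frame(
    key = keys, display_name = keys, classes = "ACE",
    stringsAsFactors = FALSE), version_tag = "initial")
  novel <- sprintf("%06d", 900001:900096)
  adds <- data.frame(key = novel, display_name = novel, classes = "ACE",
                     stringsAsFactors = FALSE)
  v1 <- reconcile_maps(base, adds, version_tag = "1.0")
  expect_equal(map_size(v1), 2639)
  expect_true(all(map_keys(base) %in% map_keys(v1)))
})

test_that("dose-form and indication screening flags the known offenders", {
  entries <- data.frame(
    key = c("207371", "208560", "858813", "700001"),
    display_name = c("Minoxidil 20 MG/ML Topical Solution (Rogaine)",
                     "Timolol 2.5 MG/ML Ophthalmic Solution (Betimol)",
                     "Enalapril Maleate 5 MG Oral Tablet",
                     "Tamsulosin 0.4 MG Oral Capsule"),
    stringsAsFactors = FALSE)
  report <- screen_dose_forms_and_indications(entries, vocab)
  expect_setequal(report$key, c("207371", "208560", "700001"))
  expect_equal(report$reason[report$key == "207371"], "dose_form")
  expect_equal(report$reason[report$key == "208560"], "dose_form")
  expect_equal(report$reason[report$key == "700001"], "excluded_ingredient")
})
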