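#' Configuration for the synthetic EHR generator
#'
#' Describes the simulated world: a hypertensive cohort's prescribing
#' table in which roughly 15% of prescription records are antihypertensive
#' (the share observed in large CDM extracts), the antihypertensive class
#' mix follows published per-class prescribing shares, and the remainder is
#' split between confounder products (ophthalmic/topical dose forms and
#' BPH-indicated alpha-blockers, which terminology-derived maps
#' misclassify) and ordinary non-antihypertensive noise drugs (statins,
#' antidiabetics, ...).
#'
#' @param seed Integer seed; every generator output is a pure function of
#'   the configuration including this seed.
#' @param n_patients Patients in the simulated cohort.
#' @param n_prescriptions Prescription records to generate.
#' @param antihypertensive_fraction Probability a record is a true
#'   antihypertensive prescription.
#' @param class_mixture Named numeric vector over (possibly combination)
#'   class labels, summing to 1; the default renormalizes published
#'   per-class prescribing shares.
#' @param confounder_fraction Probability a record is a confounder product
#'   (ophthalmic/topical/BPH).
#' @param retired_fraction Fraction of curated RxCUI-map entries marked
#'   retired (still classifiable; absent from terminology exports).
#' @param name_noise Probability of a surface perturbation of the raw
#'   name: case flip for single-ingredient products; random permutation
#'   order, separator choice and abbreviation substitution for
#'   combinations.
#' @param n_short_rxcui,n_in_termtype Counts of known-bad rows planted in
#'   the relation export: RxCUIs of fewer than 4 digits, and
#'   ingredient-level (IN) term-type rows.
#' @param htn_patient_fraction Fraction of patients who qualify for the
#'   hypertension cohort in the generated diagnosis table.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 4180,
                             n_patients = 500,
                             n_prescriptions = 5000,
                             antihypertensive_fraction = 0.15,
                             class_mixture = default_class_mixture(),
                             confounder_fraction = 0.02,
                             retired_fraction = 0.05,
                             name_noise = 0.2,
                             n_short_rxcui = 5,
                             n_in_termtype = 4,
                             htn_patient_fraction = 0.6) {
  cfg <- list(seed = as.integer(seed), n_patients = as.integer(n_patients),
              n_prescriptions = as.integer(n_prescriptions),
              antihypertensive_fraction = antihypertensive_fraction,
              class_mixture = class_mixture,
              confounder_fraction = confounder_fraction,
              retired_fraction = retired_fraction,
              name_noise = name_noise,
              n_short_rxcui = as.integer(n_short_rxcui),
              n_in_termtype = as.integer(n_in_termtype),
              htn_patient_fraction = htn_patient_fraction)
  probs <- c(cfg$antihypertensive_fraction, cfg$confounder_fraction,
             cfg$retired_fraction, cfg$name_noise, cfg$htn_patient_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("all fractions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$antihypertensive_fraction + cfg$confounder_fraction > 1) {
    stop("antihypertensive_fraction + confounder_fraction must not exceed 1",
         call. = FALSE)
  }
  if (abs(sum(cfg$class_mixture) - 1) > 1e-9) {
    stop("class_mixture must sum to 1", call. = FALSE)
  }
  if (is.null(names(cfg$class_mixture)) || any(names(cfg$class_mixture) == "")) {
    stop("class_mixture must be a named vector of class labels", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_class_mixture <- function() {
  tab <- load_fixture("table7")
  mix <- tab$count / sum(tab$count)
  names(mix) <- tab$class_label
  mix
}

# Ingredient catalog backing the demo maps. Ingredients that exist mainly
# as confounder dose forms or non-HTN indications (timolol, betaxolol,
# minoxidil, the BPH alpha-blockers) are deliberately NOT here, so the
# curated maps never classify a confounder record.
demo_ingredients <- function() {
  list(
    ACE = c("lisinopril", "enalapril", "benazepril", "captopril",
            "fosinopril", "quinapril", "ramipril"),
    ARB = c("losartan", "valsartan", "olmesartan", "irbesartan",
            "candesartan"),
    BETA_BLOCKER = c("metoprolol", "atenolol", "carvedilol", "propranolol",
                     "bisoprolol", "nebivolol"),
    CCB = c("amlodipine", "nifedipine", "diltiazem", "verapamil",
            "felodipine"),
    LOOP_DIURETIC = c("furosemide", "bumetanide", "torsemide"),
    THIAZIDE = c("hydrochlorothiazide", "chlorthalidone", "indapamide",
                 "metolazone"),
    ALDOSTERONE_ANTAGONIST = c("spironolactone", "eplerenone"),
    DIRECT_RENIN_INHIBITOR = "aliskiren",
    ALPHA1_BLOCKER = c("doxazosin", "prazosin", "terazosin"),
    POTASSIUM_SPARING = c("amiloride", "triamterene"),
    VASODILATOR = "hydralazine",
    CENTRAL_ACTING = c("clonidine", "methyldopa", "guanfacine"),
    OTHER = "reserpine"
  )
}

demo_combinations <- function() {
  list(
    `THIAZIDE+ACE` = list(c("hydrochlorothiazide", "lisinopril"),
                          c("hydrochlorothiazide", "benazepril")),
    `THIAZIDE+ARB` = list(c("hydrochlorothiazide", "losartan"),
                          c("hydrochlorothiazide", "valsartan"))
  )
}

# Confounder and noise product catalogs; RxCUIs in the 9xxxxx range are
# reserved for products absent from the curated maps.
demo_confounders <- function() {
  data.frame(
    rxcui = c("900001", "900002", "900003", "900004", "900005", "900006",
              "900007", "900008"),
    display_name = c(
      "Timolol 2.5 MG/ML Ophthalmic Solution",
      "Timolol 5 MG/ML Ophthalmic Solution",
      "Betaxolol 2.5 MG/ML Ophthalmic Suspension",
      "Minoxidil 20 MG/ML Topical Solution",
      "Minoxidil 50 MG/ML Topical Foam",
      "Tamsulosin 0.4 MG Oral Capsule",
      "Alfuzosin 10 MG Extended Release Oral Tablet",
      "Silodosin 8 MG Oral Capsule"
    ),
    reason = c("ophthalmic", "ophthalmic", "ophthalmic", "topical", "topical",
               "bph", "bph", "bph"),
    # the RxMix-style misclassification each product rides in on
    atc_class = c("beta blocking agents", "beta blocking agents",
                  "beta blocking agents",
                  "arteriolar smooth muscle, agents acting on",
                  "arteriolar smooth muscle, agents acting on",
                  "alpha-adrenoreceptor antagonists",
                  "alpha-adrenoreceptor antagonists",
                  "alpha-adrenoreceptor antagonists"),
    moa_class = c("Adrenergic beta1-Antagonists", "Adrenergic beta1-Antagonists",
                  "Adrenergic beta1-Antagonists",
                  "Potassium Channel Interactions",
                  "Potassium Channel Interactions",
                  "Adrenergic alpha1-Antagonists",
                  "Adrenergic alpha1-Antagonists",
                  "Adrenergic alpha1-Antagonists"),
    stringsAsFactors = FALSE
  )
}

demo_noise_drugs <- function() {
  data.frame(
    rxcui = as.character(950001:950010),
    display_name = c(
      "Atorvastatin 40 MG Oral Tablet", "Simvastatin 20 MG Oral Tablet",
      "Metformin 500 MG Oral Tablet", "Insulin Glargine 100 UNT/ML Injection",
      "Omeprazole 20 MG Delayed Release Oral Capsule",
      "Levothyroxine 0.05 MG Oral Tablet", "Albuterol 0.09 MG/ACTUAT Inhaler",
      "Sertraline 50 MG Oral Tablet", "Amoxicillin 500 MG Oral Capsule",
      "Gabapentin 300 MG Oral Capsule"
    ),
    stringsAsFactors = FALSE
  )
}

#' Build the demonstration classification-map pair
#'
#' Constructs a consistent name-keyed and RxCUI-keyed map pair covering
#' every drug-class label (including thiazide/ACE and thiazide/ARB
#' combinations) plus the packaged excerpt fixtures, with a linking table
#' tying each RxCUI to its name token so the generator can emit records
#' that both methods classify identically. Combination name entries are
#' expanded over every permutation and abbreviation
#' (see [expand_combination_permutations()]). A deterministic slice of
#' RxCUI entries is marked `retired` (they remain classifiable — curated
#' maps keep retired identifiers on purpose).
#'
#' @param retired_fraction Fraction of RxCUI entries marked retired.
#' @param vocab A [class_vocabulary][read_vocabulary].
#' @return A list with `name_map`, `rxcui_map`, and `links` (data frame
#'   `rxcui`, `token`, `display_name`, `classes`, `drug_count`, `status`).
#' @export
build_demo_maps <- function(retired_fraction = 0.05,
                            vocab = default_vocabulary()) {
  ingredients <- demo_ingredients()
  combos <- demo_combinations()
  strengths <- c(5, 10, 25)
  links <- list()
  next_cui <- 100001L

  for (label in names(ingredients)) {
    for (ing in ingredients[[label]]) {
      for (st in strengths[1:2]) {
        links[[length(links) + 1]] <- data.frame(
          rxcui = as.character(next_cui),
          token = ing,
          display_name = sprintf("%s %g MG Oral Tablet", cap_first(ing), st),
          classes = label,
          drug_count = 1L,
          term_type = "SCD",
          stringsAsFactors = FALSE
        )
        next_cui <- next_cui + 1L
      }
    }
  }
  for (label in names(combos)) {
    for (pair in combos[[label]]) {
      links[[length(links) + 1]] <- data.frame(
        rxcui = as.character(next_cui),
        token = paste(pair, collapse = "_"),
        display_name = sprintf("%s 12.5 MG / %s 10 MG Oral Tablet",
                               cap_first(pair[1]), cap_first(pair[2])),
        classes = label,
        drug_count = 2L,
        term_type = "SCD",
        stringsAsFactors = FALSE
      )
      next_cui <- next_cui + 1L
    }
  }
  links <- do.call(rbind, links)
  links$status <- "active"
  if (retired_fraction > 0) {
    period <- max(2L, as.integer(round(1 / retired_fraction)))
    links$status[seq_len(nrow(links)) %% period == 0] <- "retired"
  }

  rxcui_entries <- data.frame(
    key = links$rxcui, display_name = links$display_name,
    classes = links$classes, drug_count = links$drug_count,
    term_type = links$term_type, status = links$status,
    stringsAsFactors = FALSE
  )
  table3 <- load_fixture("table3")
  rxcui_entries <- rbind(rxcui_entries,
                         table3$entries[, names(rxcui_entries)])
  rxcui_map <- classification_map("rxcui", rxcui_entries, vocabulary = vocab,
                                  version_tag = "demo-1.0")

  name_rows <- list()
  seen <- character()
  for (label in names(ingredients)) {
    for (ing in ingredients[[label]]) {
      name_rows[[length(name_rows) + 1]] <- data.frame(
        key = ing, display_name = cap_first(ing), classes = label,
        drug_count = 1L, stringsAsFactors = FALSE
      )
    }
  }
  for (label in names(combos)) {
    for (pair in combos[[label]]) {
      perms <- expand_combination_permutations(pair, synonyms = vocab$synonyms)
      for (tok in perms) {
        name_rows[[length(name_rows) + 1]] <- data.frame(
          key = tok, display_name = tok, classes = label, drug_count = 2L,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  name_entries <- do.call(rbind, name_rows)
  table2 <- load_fixture("table2")
  extra <- table2$entries[!table2$entries$key %in% name_entries$key, ]
  name_entries <- rbind(name_entries,
                        extra[, c("key", "display_name", "classes",
                                  "drug_count")])
  name_map <- classification_map("name", name_entries, vocabulary = vocab,
                                 version_tag = "demo-1.0")
  list(name_map = name_map, rxcui_map = rxcui_map, links = links)
}

cap_first <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

#' Generate a synthetic prescribing table with ground-truth labels
#'
#' Each record is, independently, a true antihypertensive prescription
#' (drawn from the demo map pair with consistent raw name and RxCUI, class
#' drawn from `class_mixture`), a confounder product (ophthalmic/topical
#' dose form or BPH-indicated alpha-blocker, whose RxCUI is absent from
#' curated maps), or a non-antihypertensive noise drug. Name noise applies
#' case flips, and for combinations a random component permutation,
#' hyphen/slash separator, and abbreviation substitution — all surface
#' forms a name classifier must absorb. Output is a pure function of the
#' configuration.
#'
#' @param config A [synthetic_config()].
#' @param maps A map pair from [build_demo_maps()]; defaults to one built
#'   with the config's `retired_fraction`.
#' @return A list with `records` (a `prescribing_table`) and `labels`
#'   (data frame `record`, `true_classes` (`"+"`-joined or `NA`),
#'   `is_antihypertensive`, `confounder_reason`).
#' @export
generate_prescribing <- function(config,
                                 maps = build_demo_maps(config$retired_fraction)) {
  stopifnot(inherits(config, "synthetic_config"))
  bad_labels <- names(config$class_mixture)[
    !names(config$class_mixture) %in% maps$links$classes]
  if (length(bad_labels) > 0) {
    stop("class_mixture label(s) with no demo-map entries: ",
         paste(bad_labels, collapse = ", "), call. = FALSE)
  }
  set.seed(config$seed)
  n <- config$n_prescriptions
  confounders <- demo_confounders()
  noise <- demo_noise_drugs()
  links_by_class <- split(seq_len(nrow(maps$links)), maps$links$classes)

  u <- stats::runif(n)
  kind <- ifelse(u < config$antihypertensive_fraction, "ahtn",
                 ifelse(u < config$antihypertensive_fraction +
                          config$confounder_fraction, "confounder", "noise"))
  patient_id <- sprintf("P%05d", sample.int(config$n_patients, n,
                                            replace = TRUE))
  order_date <- as.Date("2011-01-01") +
    sample.int(2403, n, replace = TRUE) - 1  # through 2017-07-31

  raw_name <- character(n)
  rxcui <- character(n)
  true_classes <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    if (kind[i] == "ahtn") {
      label <- sample(names(config$class_mixture), 1,
                      prob = config$class_mixture)
      row <- maps$links[sample(links_by_class[[label]], 1), ]
      raw_name[i] <- render_raw_name(row, config$name_noise,
                                     maps$name_map$vocabulary %||%
                                       default_vocabulary())
      rxcui[i] <- row$rxcui
      true_classes[i] <- row$classes
    } else if (kind[i] == "confounder") {
      row <- confounders[sample.int(nrow(confounders), 1), ]
      raw_name[i] <- row$display_name
      rxcui[i] <- row$rxcui
      reason[i] <- row$reason
    } else {
      row <- noise[sample.int(nrow(noise), 1), ]
      raw_name[i] <- row$display_name
      rxcui[i] <- row$rxcui
    }
  }

  records <- data.frame(patient_id = patient_id, order_date = order_date,
                        raw_med_name = raw_name, rxnorm_cui = rxcui,
                        stringsAsFactors = FALSE)
  class(records) <- c("prescribing_table", "data.frame")
  labels <- data.frame(record = seq_len(n), true_classes = true_classes,
                       is_antihypertensive = kind == "ahtn",
                       confounder_reason = reason, stringsAsFactors = FALSE)
  list(records = records, labels = labels)
}

# Surface form of a prescribing raw name for one link row, with optional
# noise. Combination tokens render as "a-b 12.5-10 MG Oral Tablet" with
# random permutation/separator/abbreviation under noise.
render_raw_name <- function(row, name_noise, vocab) {
  noisy <- stats::runif(1) < name_noise
  if (row$drug_count >= 2) {
    parts <- strsplit(row$token, "_", fixed = TRUE)[[1]]
    if (noisy) {
      parts <- parts[sample.int(length(parts))]
      parts <- vapply(parts, function(p) {
        syn <- vocab$synonyms[[p]]
        if (length(syn) > 0 && stats::runif(1) < 0.5) sample(syn, 1) else p
      }, character(1), USE.NAMES = FALSE)
      sep <- sample(c("-", "/"), 1)
    } else {
      sep <- "-"
    }
    nm <- sprintf("%s 12.5-10 MG Oral Tablet",
                  paste(vapply(parts, cap_first, character(1)),
                        collapse = sep))
  } else {
    nm <- row$display_name
  }
  if (noisy && stats::runif(1) < 0.5) nm <- toupper(nm)
  nm
}

#' Generate a terminology-relation export with known-bad rows
#'
#' Emulates a batch class-by-drug query over the curated map: every active
#' curated RxCUI entry yields consistent ATC class-membership rows and
#' MED-RT `may_treat` hypertension + `has_MoA` rows (retired entries are
#' skipped — later terminology releases no longer carry them). On top, the
#' export plants known-bad rows whose exact counts are recorded as ground
#' truth: RxCUIs of fewer than 4 digits, ophthalmic/topical and
#' BPH-indicated confounder products (misclassified by the terminology
#' exactly as real batch output misclassifies them), and ingredient-level
#' IN term-type rows excluded from curated maps by the term-type policy.
#'
#' @param config A [synthetic_config()].
#' @param maps A map pair from [build_demo_maps()].
#' @param vocab A [class_vocabulary][read_vocabulary].
#' @return A `terminology_relations` data frame with attribute
#'   `ground_truth`: list of `short_rxcuis`, `ophthalmic_rxcuis`,
#'   `topical_rxcuis`, `bph_rxcuis`, `in_termtype_rxcuis`.
#' @export
generate_relation_export <- function(config,
                                     maps = build_demo_maps(config$retired_fraction),
                                     vocab = default_vocabulary()) {
  stopifnot(inherits(config, "synthetic_config"))
  atc_name_for <- inverse_acceptance(vocab$atc_class_names)
  moa_name_for <- inverse_acceptance(vocab$medrt_moa_names)

  links <- maps$links[maps$links$status == "active", , drop = FALSE]
  rows <- list()
  emit <- function(rxcui, class_name, source, rela, concept, tty) {
    rows[[length(rows) + 1]] <<- data.frame(
      rxcui = rxcui, concept_name = concept, term_type = tty,
      rela_source = source, rela = rela, class_name = class_name,
      stringsAsFactors = FALSE
    )
  }
  for (j in seq_len(nrow(links))) {
    row <- links[j, ]
    for (lbl in split_label(row$classes)) {
      emit(row$rxcui, atc_name_for[[lbl]], "ATC", "atc_class_member",
           row$display_name, row$term_type)
      emit(row$rxcui, moa_name_for[[lbl]], "MEDRT", "has_MoA",
           row$display_name, row$term_type)
    }
    emit(row$rxcui, "Hypertension", "MEDRT", "may_treat", row$display_name,
         row$term_type)
  }

  # short-RxCUI artifacts
  short_pool <- c("12", "345", "99", "7", "111", "20", "408", "55", "3", "880")
  short_rxcuis <- short_pool[seq_len(min(config$n_short_rxcui,
                                         length(short_pool)))]
  for (s in short_rxcuis) {
    emit(s, atc_name_for[["ACE"]], "ATC", "atc_class_member",
         paste("Artifact", s), NA_character_)
  }

  # confounder products, misclassified the way batch output misclassifies
  confounders <- demo_confounders()
  if (config$confounder_fraction == 0) {
    confounders <- confounders[0, , drop = FALSE]
  }
  for (j in seq_len(nrow(confounders))) {
    row <- confounders[j, ]
    emit(row$rxcui, row$atc_class, "ATC", "atc_class_member",
         row$display_name, "SCD")
    emit(row$rxcui, "Hypertension", "MEDRT", "may_treat", row$display_name,
         "SCD")
    emit(row$rxcui, row$moa_class, "MEDRT", "has_MoA", row$display_name,
         "SCD")
  }

  # ingredient-level (IN) rows
  ingredients <- demo_ingredients()
  in_labels <- utils::head(names(ingredients), config$n_in_termtype)
  in_rxcuis <- character(0)
  for (k in seq_along(in_labels)) {
    lbl <- in_labels[k]
    ing <- ingredients[[lbl]][1]
    cui <- as.character(800000L + k)
    in_rxcuis <- c(in_rxcuis, cui)
    emit(cui, atc_name_for[[lbl]], "ATC", "atc_class_member", cap_first(ing),
         "IN")
    emit(cui, "Hypertension", "MEDRT", "may_treat", cap_first(ing), "IN")
    emit(cui, moa_name_for[[lbl]], "MEDRT", "has_MoA", cap_first(ing), "IN")
  }

  rel <- if (length(rows) == 0) empty_relations() else do.call(rbind, rows)
  class(rel) <- c("terminology_relations", "data.frame")
  attr(rel, "ground_truth") <- list(
    short_rxcuis = short_rxcuis,
    ophthalmic_rxcuis = confounders$rxcui[confounders$reason == "ophthalmic"],
    topical_rxcuis = confounders$rxcui[confounders$reason == "topical"],
    bph_rxcuis = confounders$rxcui[confounders$reason == "bph"],
    in_termtype_rxcuis = in_rxcuis
  )
  rel
}

# label -> first acceptance-list name conferring exactly that label
inverse_acceptance <- function(acceptance) {
  out <- list()
  for (nm in names(acceptance)) {
    labels <- acceptance[[nm]]
    if (length(labels) == 1 && is.null(out[[labels]])) out[[labels]] <- nm
  }
  out
}

#' Generate a synthetic diagnosis table with known cohort membership
#'
#' Produces a labeled mix of qualifying records (adult, outpatient,
#' ICD-9 401.x — dotted and undotted dialects — or ICD-10 I10) and
#' non-qualifying records that each fail exactly one gate (minor age,
#' non-outpatient encounter, or a non-qualifying code such as I15 or an
#' I10 subcode).
#'
#' @param config A [synthetic_config()].
#' @return A `diagnosis_table` with attribute `ground_truth`: the sorted
#'   vector of qualifying patient ids.
#' @export
generate_diagnoses <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  ids <- sprintf("P%05d", seq_len(config$n_patients))
  qualifying <- stats::runif(config$n_patients) < config$htn_patient_fraction
  good_codes <- list(c("401.9", "ICD9"), c("401.1", "ICD9"), c("4019", "ICD9"),
                     c("401", "ICD9"), c("I10", "ICD10"))
  bad_codes <- list(c("I15", "ICD10"), c("I10.9", "ICD10"), c("I110", "ICD10"),
                    c("402.1", "ICD9"), c("E11.9", "ICD10"))
  rows <- list()
  for (k in seq_along(ids)) {
    n_rows <- sample.int(3, 1)
    for (r in seq_len(n_rows)) {
      if (qualifying[k] && r == 1) {
        cd <- good_codes[[sample.int(length(good_codes), 1)]]
        enc <- "outpatient"
        age <- sample(18:90, 1)
      } else {
        fail <- sample.int(3, 1)
        if (fail == 1) {        # right code, minor
          cd <- good_codes[[sample.int(length(good_codes), 1)]]
          enc <- "outpatient"
          age <- sample(1:17, 1)
        } else if (fail == 2) { # right code, inpatient
          cd <- good_codes[[sample.int(length(good_codes), 1)]]
          enc <- "other"
          age <- sample(18:90, 1)
        } else {                # wrong code
          cd <- bad_codes[[sample.int(length(bad_codes), 1)]]
          enc <- "outpatient"
          age <- sample(18:90, 1)
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = ids[k], code = cd[1], code_type = cd[2],
        encounter_type = enc, age_at_encounter = age,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("diagnosis_table", "data.frame")
  attr(out, "ground_truth") <- sort(ids[qualifying])
  out
}

#' Write the synthetic bundle to disk
#'
#' Emits the prescribing CSV (PCORnet column names), diagnosis CSV,
#' relation TSV and ground-truth labels CSV for one configuration.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_synthetic_bundle <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  maps <- build_demo_maps(config$retired_fraction)
  gen <- generate_prescribing(config, maps)
  rel <- generate_relation_export(config, maps)
  dx <- generate_diagnoses(config)

  paths <- c(
    prescribing = file.path(dir, "prescribing.csv"),
    diagnoses = file.path(dir, "diagnoses.csv"),
    relations = file.path(dir, "relations.tsv"),
    labels = file.path(dir, "labels.csv"),
    name_map = file.path(dir, "name_map.csv"),
    rxcui_map = file.path(dir, "rxcui_map.csv")
  )
  rx <- gen$records
  utils::write.csv(
    data.frame(PATID = rx$patient_id, RX_ORDER_DATE = as.character(rx$order_date),
               RAW_RX_MED_NAME = rx$raw_med_name, RXNORM_CUI = rx$rxnorm_cui,
               stringsAsFactors = FALSE),
    paths[["prescribing"]], row.names = FALSE, na = "")
  utils::write.csv(
    data.frame(PATID = dx$patient_id, DX = dx$code, DX_TYPE = dx$code_type,
               ENC_TYPE = ifelse(dx$encounter_type == "outpatient", "AV", "IP"),
               AGE = dx$age_at_encounter, stringsAsFactors = FALSE),
    paths[["diagnoses"]], row.names = FALSE)
  utils::write.table(rel, paths[["relations"]], sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  utils::write.csv(gen$labels, paths[["labels"]], row.names = FALSE, na = "")
  write_classification_csv(maps$name_map, paths[["name_map"]])
  write_classification_csv(maps$rxcui_map, paths[["rxcui_map"]])
  invisible(paths)
}
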