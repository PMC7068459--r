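# Half-up rounding to 2 decimal places; the small epsilon absorbs IEEE
# representation error (e.g. 100*x landing at 257.99999...).
round2 <- function(x) floor(100 * x + 0.5 + 1e-9) / 100

#' Term or prescription coverage of a classification map
#'
#' Coverage is the number of terms (or prescription records) assigned an
#' antihypertensive class divided by the total number of unique terms (or
#' records), as a percentage rounded half-up to 2 decimal places.
#'
#' @param mapped Number of mapped terms/records.
#' @param total Total number of terms/records; must be positive.
#' @return A list of class `coverage_result`: `total_terms`,
#'   `mapped_terms`, `percent`.
#' @examples
#' coverage(729, 13627)$percent  # 5.35
#' @export
coverage <- function(mapped, total) {
  if (length(total) != 1 || length(mapped) != 1 || is.na(total) ||
      is.na(mapped) || total <= 0) {
    stop("total must be a single positive count", call. = FALSE)
  }
  if (mapped < 0 || mapped > total) {
    stop("mapped must lie in [0, total]", call. = FALSE)
  }
  structure(
    list(total_terms = as.integer(total), mapped_terms = as.integer(mapped),
         percent = round2(100 * mapped / total)),
    class = "coverage_result"
  )
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("coverage: %d / %d (%.2f%%)\n", x$mapped_terms, x$total_terms,
              x$percent))
  invisible(x)
}

#' Pairwise comparison of two key sets
#'
#' Exact set algebra over two classification key sets (same kind): the
#' overlap and the keys unique to each side, with counts. Key vectors come
#' back sorted for deterministic output.
#'
#' @param a,b Character vectors of keys (duplicates ignored), or
#'   [classification_map]s of the same kind.
#' @return A list of class `comparison_result`: `overlap_count`,
#'   `unique_a_count`, `unique_b_count`, `overlap_keys`, `unique_a_keys`,
#'   `unique_b_keys`.
#' @examples
#' pairwise_compare(c("1001", "1002", "1003"), c("1002", "1003", "1004"))
#' @export
pairwise_compare <- function(a, b) {
  if (inherits(a, "classification_map") || inherits(b, "classification_map")) {
    if (!(inherits(a, "classification_map") &&
          inherits(b, "classification_map") && a$kind == b$kind)) {
      stop("pairwise_compare needs two key vectors or two maps of the same ",
           "kind", call. = FALSE)
    }
    a <- map_keys(a)
    b <- map_keys(b)
  }
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  overlap <- sort(intersect(a, b))
  ua <- sort(setdiff(a, b))
  ub <- sort(setdiff(b, a))
  structure(
    list(overlap_count = length(overlap), unique_a_count = length(ua),
         unique_b_count = length(ub), overlap_keys = overlap,
         unique_a_keys = ua, unique_b_keys = ub),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("comparison: overlap %d | unique to A %d | unique to B %d\n",
              x$overlap_count, x$unique_a_count, x$unique_b_count))
  invisible(x)
}

#' Categorize keys unique to one classification
#'
#' Explains why keys ended up on only one side of a map comparison. Each
#' key is assigned the first matching category in fixed precedence order:
#' `term_type` (low-specificity RxNorm term types IN/MIN/PIN),
#' `dose_form` (ophthalmic/topical products), `bph_indication`
#' (alpha-blockers primarily indicated for benign prostatic hyperplasia),
#' `combination` (multi-ingredient product names), `retired` (withdrawn
#' identifiers), else `uncategorized`.
#'
#' @param unique_keys Character vector of keys to explain.
#' @param concept_names Named character vector key -> display name.
#' @param term_types Optional named character vector key -> RxNorm term
#'   type.
#' @param statuses Optional named character vector key -> status
#'   (`retired`/`remapped` feed the `retired` category).
#' @param vocab A [class_vocabulary][read_vocabulary] supplying dose-form
#'   tokens, BPH ingredients and the excluded term-type list.
#' @return A list of class `difference_categories`: `category_counts`
#'   (named integer vector over all six categories) and `assignments`
#'   (data frame `key`, `category`).
#' @export
categorize_differences <- function(unique_keys, concept_names = NULL,
                                   term_types = NULL, statuses = NULL,
                                   vocab = default_vocabulary()) {
  unique_keys <- as.character(unique_keys)
  categories <- c("term_type", "dose_form", "bph_indication", "combination",
                  "retired", "uncategorized")
  lookup <- function(table, key) {
    if (is.null(table) || !key %in% names(table)) NULL else table[[key]]
  }
  assign_one <- function(key) {
    tt <- lookup(term_types, key)
    if (!is.null(tt) && !is.na(tt) && tt %in% vocab$term_types_excluded) {
      return("term_type")
    }
    nm <- lookup(concept_names, key)
    if (!is.null(nm) && !is.na(nm)) {
      low <- tolower(nm)
      if (any(vapply(vocab$dose_form_tokens,
                     function(tok) grepl(paste0("\\b", tok, "\\b"), low),
                     logical(1)))) {
        return("dose_form")
      }
      first_word <- sub("^([a-z0-9-]+).*$", "\\1", low)
      if (first_word %in% vocab$bph_ingredients) return("bph_indication")
      # RxNorm multi-ingredient names separate components with " / "
      if (grepl(" / ", nm, fixed = TRUE) || grepl("_", nm, fixed = TRUE)) {
        return("combination")
      }
    }
    st <- lookup(statuses, key)
    if (!is.null(st) && !is.na(st) && st %in% c("retired", "remapped")) {
      return("retired")
    }
    "uncategorized"
  }
  assigned <- vapply(unique_keys, assign_one, character(1), USE.NAMES = FALSE)
  counts <- vapply(categories, function(cat) sum(assigned == cat), integer(1))
  structure(
    list(category_counts = counts,
         assignments = data.frame(key = unique_keys, category = assigned,
                                  stringsAsFactors = FALSE)),
    class = "difference_categories"
  )
}

#' Select the hypertension cohort from a diagnosis table
#'
#' A patient enters the cohort with at least one outpatient encounter at
#' age >= 18 carrying an essential-hypertension diagnosis: ICD-9 401.x
#' (any fourth digit, dot optional) or ICD-10 I10 exactly (I10 subcodes
#' such as I10.x or I11 do not qualify).
#'
#' @param diagnoses A `diagnosis_table` (see [read_diagnosis_table()]) or
#'   data frame with columns `patient_id`, `code`, `code_type`,
#'   `encounter_type`, `age_at_encounter`.
#' @return Sorted character vector of qualifying patient ids.
#' @export
select_htn_cohort <- function(diagnoses) {
  code <- toupper(gsub(" ", "", diagnoses$code))
  icd9 <- diagnoses$code_type == "ICD9" &
    grepl("^401(\\.[0-9]+)?$|^401[0-9]*$", code)
  icd10 <- diagnoses$code_type == "ICD10" & code == "I10"
  qualifies <- (icd9 | icd10) &
    diagnoses$encounter_type == "outpatient" &
    !is.na(diagnoses$age_at_encounter) & diagnoses$age_at_encounter >= 18
  sort(unique(diagnoses$patient_id[qualifies]))
}

#' Per-class frequency table over classified records
#'
#' Counts matched records by assigned antihypertensive class; each matched
#' record is counted exactly once, under its (possibly combination) class
#' label — a thiazide/ACE combination product contributes one count to the
#' `THIAZIDE+ACE` row, not one to each component. Percentages are over
#' total matched records, rounded half-up to 2 decimal places.
#'
#' @param decisions A `classified_records` data frame from
#'   [classify_records()].
#' @param method `"rxcui"` or `"name"` — which method's decisions to
#'   tabulate.
#' @return A list of class `class_frequency_table`: `rows` (data frame
#'   `class_label`, `count`, `percent`, sorted by descending count) and
#'   `total_mapped`.
#' @export
class_frequency_table <- function(decisions, method = c("rxcui", "name")) {
  method <- match.arg(method)
  matched_col <- paste0(method, "_matched")
  classes_col <- paste0(method, "_classes")
  if (!all(c(matched_col, classes_col) %in% names(decisions))) {
    stop("decisions lack ", method, " classification columns; run ",
         "classify_records() with that method", call. = FALSE)
  }
  labels <- decisions[[classes_col]][decisions[[matched_col]]]
  total <- length(labels)
  tab <- table(labels)
  rows <- data.frame(
    class_label = names(tab),
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  rows$percent <- if (total > 0) round2(100 * rows$count / total) else numeric(0)
  rows <- rows[order(-rows$count, rows$class_label), , drop = FALSE]
  rownames(rows) <- NULL
  structure(list(rows = rows, total_mapped = total),
            class = "class_frequency_table")
}

#' @export
print.class_frequency_table <- function(x, ...) {
  cat(sprintf("class frequencies over %d mapped records\n", x$total_mapped))
  print(x$rows, row.names = FALSE)
  invisible(x)
}

#' Prescription-level coverage of classified records
#'
#' @param decisions A `classified_records` data frame.
#' @param method `"rxcui"` or `"name"`.
#' @return A [coverage] result: mapped records over all records.
#' @export
prescription_coverage <- function(decisions, method = c("rxcui", "name")) {
  method <- match.arg(method)
  matched_col <- paste0(method, "_matched")
  if (!matched_col %in% names(decisions)) {
    stop("decisions lack ", method, " classification columns", call. = FALSE)
  }
  coverage(sum(decisions[[matched_col]]), nrow(decisions))
}

#' Summarize a map comparison as JSON-ready structures
#'
#' @param result A `comparison_result`.
#' @return A plain list with exact integer counts (key sets omitted),
#'   suitable for `jsonlite::write_json()`.
#' @export
comparison_summary <- function(result) {
  stopifnot(inherits(result, "comparison_result"))
  list(overlap = result$overlap_count, unique_a = result$unique_a_count,
       unique_b = result$unique_b_count)
}
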