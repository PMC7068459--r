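#' Remove RxCUIs shorter than four digits
#'
#' Batch terminology queries over EHR-derived RxCUI lists pick up short
#' numeric artifacts that are not real drug identifiers; relations whose
#' RxCUI string has fewer than 4 digits are dropped before map building.
#'
#' @param relations A `terminology_relations` data frame
#'   (see [read_rxclass_batch()]).
#' @return A list with `kept` (the surviving relations, input order
#'   preserved) and `removed_count`.
#' @examples
#' rel <- ahtnclass:::terminology_relations(
#'   rxcui = c("12", "999", "1000", "858810"),
#'   class_name = "x", rela_source = "ATC")
#' remove_short_rxcuis(rel)$removed_count  # 2
#' @export
remove_short_rxcuis <- function(relations) {
  keep <- nchar(relations$rxcui) >= 4
  kept <- relations[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed_count = sum(!keep))
}

#' Build a classification map from ATC class-membership relations
#'
#' Keeps exactly the RxCUIs having at least one relation whose ATC class
#' name is on the vocabulary's antihypertensive acceptance list; each
#' surviving RxCUI is labelled with the union of the drug-class labels its
#' accepted ATC classes confer. ATC models the drug class only, so every
#' dose form of an ingredient is carried along (e.g. ophthalmic timolol
#' arrives as a "beta blocking agents" member); use
#' [screen_dose_forms_and_indications()] downstream.
#'
#' @param relations Relations with `rela_source == "ATC"`.
#' @param vocab A [class_vocabulary][read_vocabulary].
#' @param version_tag Version recorded on the map.
#' @return A [classification_map] of kind `"rxcui"`, keys sorted.
#' @export
build_atc_map <- function(relations, vocab = default_vocabulary(),
                          version_tag = "atc-0.1") {
  stopifnot(all(relations$rela_source == "ATC"))
  hits <- relations[tolower(relations$class_name) %in%
                      names(vocab$atc_class_names), , drop = FALSE]
  labels_per_row <- vocab$atc_class_names[tolower(hits$class_name)]
  relations_to_map(hits, labels_per_row, vocab, version_tag)
}

#' Build a classification map from MED-RT relations
#'
#' Two-step filter: (1) keep RxCUIs having a `may_treat` relation whose
#' class name denotes hypertension; (2) of those, keep RxCUIs that also
#' have at least one `has_MoA` relation whose class name is on the
#' vocabulary's antihypertensive mechanism-of-action acceptance list.
#' Class labels come from the matching MoA names. Step 2 never adds keys.
#'
#' @param relations Relations with `rela_source == "MEDRT"` and `rela` in
#'   `may_treat` / `has_MoA`.
#' @inheritParams build_atc_map
#' @return A [classification_map] of kind `"rxcui"`, keys sorted.
#' @export
build_medrt_map <- function(relations, vocab = default_vocabulary(),
                            version_tag = "medrt-0.1") {
  stopifnot(all(relations$rela_source == "MEDRT"))
  may_treat <- relations$rela == "may_treat" &
    tolower(relations$class_name) %in% vocab$may_treat_hypertension
  htn_rxcuis <- unique(relations$rxcui[may_treat])
  moa <- relations[relations$rela == "has_MoA" &
                     relations$rxcui %in% htn_rxcuis &
                     tolower(relations$class_name) %in%
                       names(vocab$medrt_moa_names), , drop = FALSE]
  labels_per_row <- vocab$medrt_moa_names[tolower(moa$class_name)]
  relations_to_map(moa, labels_per_row, vocab, version_tag)
}

# Aggregate accepted (relation row, labels) pairs into one map entry per
# rxcui, sorted by key for order-invariance.
relations_to_map <- function(hits, labels_per_row, vocab, version_tag) {
  if (nrow(hits) == 0) {
    return(classification_map("rxcui",
                              data.frame(key = character(),
                                         display_name = character(),
                                         classes = character(),
                                         stringsAsFactors = FALSE),
                              vocabulary = vocab, version_tag = version_tag))
  }
  by_key <- split(seq_len(nrow(hits)), hits$rxcui)
  keys <- sort(names(by_key))
  entries <- do.call(rbind, lapply(keys, function(k) {
    idx <- by_key[[k]]
    labels <- sort(unique(unlist(labels_per_row[idx])))
    nm <- hits$concept_name[idx]
    tt <- hits$term_type[idx]
    data.frame(
      key = k,
      display_name = if (all(is.na(nm))) k else nm[!is.na(nm)][1],
      classes = join_label(labels),
      term_type = if (all(is.na(tt))) NA_character_ else tt[!is.na(tt)][1],
      stringsAsFactors = FALSE
    )
  }))
  classification_map("rxcui", entries, vocabulary = vocab,
                     version_tag = version_tag)
}

#' Build a classification map from drug-ontology RxCUI lists
#'
#' Mirrors classification from ontology query output: the export consists
#' of one RxCUI list per therapeutic indication and one per mechanism of
#' action. Map keys are the RxCUIs on the hypertension-indication list;
#' each key's classes are the union of the mechanism labels of every MoA
#' list containing it, plus any manual class additions (the hand-curation
#' step for mechanisms the ontology does not yet represent). Combination
#' products appear on several MoA lists and so carry all component labels.
#' Indication RxCUIs with no mechanism and no manual addition are excluded
#' from the map and returned as an `unassigned` review report.
#'
#' @param indication_lists Named list of RxCUI character vectors, one per
#'   therapeutic indication; must contain a `hypertension` element.
#' @param moa_lists Named list of RxCUI character vectors; names are
#'   drug-class labels (`"+"`-joined labels allowed) in the vocabulary.
#' @param manual_additions Named list mapping rxcui to a character vector
#'   of class labels, applied on top of the MoA merge. An addition for an
#'   RxCUI outside the indication list is honoured with a warning.
#' @param display_names Optional named character vector rxcui ->
#'   display name.
#' @param term_types Optional named character vector rxcui -> RxNorm term
#'   type; entries whose term type is on the vocabulary's excluded list
#'   (IN/MIN/PIN by default) are dropped.
#' @inheritParams build_atc_map
#' @return A [classification_map] of kind `"rxcui"` with an `unassigned`
#'   attribute (character vector of indication RxCUIs left without a
#'   class).
#' @export
build_dron_map <- function(indication_lists, moa_lists,
                           manual_additions = list(),
                           display_names = NULL, term_types = NULL,
                           vocab = default_vocabulary(),
                           version_tag = "dron-0.1") {
  if (!"hypertension" %in% tolower(names(indication_lists))) {
    stop("indication_lists must contain a 'hypertension' list", call. = FALSE)
  }
  bad <- names(moa_lists)[!label_in_vocabulary(names(moa_lists), vocab)]
  if (length(bad) > 0) {
    stop("moa_lists names must be vocabulary labels; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  htn <- unique(as.character(
    indication_lists[[which(tolower(names(indication_lists)) == "hypertension")[1]]]))

  stray <- setdiff(names(manual_additions), htn)
  if (length(stray) > 0) {
    warning("manual addition(s) for RxCUI(s) outside the hypertension ",
            "indication list: ", paste(utils::head(stray, 5), collapse = ", "),
            call. = FALSE)
  }
  all_keys <- sort(unique(c(htn, names(manual_additions))))
  classes_of <- function(k) {
    moa <- unlist(lapply(names(moa_lists), function(lbl) {
      if (k %in% moa_lists[[lbl]]) split_label(lbl) else character()
    }))
    sort(unique(c(moa, unlist(manual_additions[[k]]))))
  }
  class_sets <- lapply(all_keys, classes_of)
  unassigned <- all_keys[lengths(class_sets) == 0]
  keep <- lengths(class_sets) > 0
  keys <- all_keys[keep]
  entries <- data.frame(
    key = keys,
    display_name = if (is.null(display_names)) keys else {
      dn <- unname(display_names[keys]); ifelse(is.na(dn), keys, dn)
    },
    classes = vapply(class_sets[keep], join_label, character(1)),
    term_type = if (is.null(term_types)) NA_character_ else
      unname(term_types[keys]),
    stringsAsFactors = FALSE
  )
  if (!is.null(term_types)) {
    drop <- !is.na(entries$term_type) &
      entries$term_type %in% vocab$term_types_excluded
    entries <- entries[!drop, , drop = FALSE]
  }
  map <- classification_map("rxcui", entries, vocabulary = vocab,
                            version_tag = version_tag)
  attr(map, "unassigned") <- unassigned
  map
}

#' Reconcile a classification map with curated additions and exclusions
#'
#' Applies the review step that turns a candidate map into a released
#' version: entries are added (novel keys, or exact duplicates of existing
#' entries, which are no-ops), then excluded keys are removed. An addition
#' whose key exists with a different class payload is a validation error —
#' that conflict needs manual resolution, not silent overwrite. The result
#' carries an `audit` attribute listing every key added and excluded.
#'
#' @param base A [classification_map].
#' @param additions A data frame of entry rows (columns as in
#'   [classification_map]) or a `classification_map` of the same kind.
#' @param exclusions Character vector of keys to remove.
#' @param version_tag Version recorded on the result; default appends
#'   `"+r"` to the base tag.
#' @return The reconciled [classification_map] with an `audit` attribute
#'   (list of `added` and `excluded` key vectors).
#' @export
reconcile_maps <- function(base, additions = NULL, exclusions = character(),
                           version_tag = NULL) {
  stopifnot(inherits(base, "classification_map"))
  add_entries <- NULL
  if (inherits(additions, "classification_map")) {
    if (additions$kind != base$kind) {
      stop("additions map kind does not match base map kind", call. = FALSE)
    }
    add_entries <- additions$entries
  } else if (!is.null(additions) && NROW(additions) > 0) {
    add_entries <- classification_map(base$kind, additions,
                                      vocabulary = base$vocabulary)$entries
  }
  entries <- base$entries
  added <- character()
  if (!is.null(add_entries) && nrow(add_entries) > 0) {
    existing <- match(add_entries$key, entries$key)
    conflict <- !is.na(existing) &
      entries$classes[existing] != add_entries$classes
    if (any(conflict)) {
      stop("addition(s) conflict with existing entries for key(s): ",
           paste(utils::head(add_entries$key[conflict], 5), collapse = ", "),
           "; resolve manually", call. = FALSE)
    }
    novel <- is.na(existing) & !duplicated(add_entries$key)
    added <- add_entries$key[novel]
    entries <- rbind(entries, add_entries[novel, names(entries), drop = FALSE])
  }
  excluded <- intersect(exclusions, entries$key)
  entries <- entries[!entries$key %in% exclusions, , drop = FALSE]
  rownames(entries) <- NULL
  out <- classification_map(
    base$kind, entries, vocabulary = base$vocabulary,
    version_tag = version_tag %||% paste0(base$version_tag, "+r")
  )
  attr(out, "audit") <- list(added = added, excluded = excluded)
  out
}

#' Screen map entries for suspect dose forms and indications
#'
#' Terminology-derived maps pull in products that are not systemic
#' antihypertensives: ophthalmic beta-blockers (glaucoma), topical
#' minoxidil (hair loss), and alpha-blockers primarily indicated for
#' benign prostatic hyperplasia. This screen flags — report only — entries
#' whose display name contains a configured dose-form token, or whose
#' ingredient (first word of the display name) is on the configured
#' exclusion list. Apply the actual removal via [reconcile_maps()].
#'
#' @param entries A data frame with `key` and `display_name` columns, or a
#'   [classification_map].
#' @param vocab A [class_vocabulary][read_vocabulary] supplying
#'   `dose_form_tokens` and `excluded_ingredients`.
#' @return A data frame report with columns `key`, `display_name`,
#'   `reason` (`"dose_form"` or `"excluded_ingredient"`); zero rows when
#'   nothing is suspect.
#' @export
screen_dose_forms_and_indications <- function(entries,
                                              vocab = default_vocabulary()) {
  if (inherits(entries, "classification_map")) entries <- entries$entries
  nm <- tolower(entries$display_name)
  dose_form <- Reduce(`|`, lapply(vocab$dose_form_tokens, function(tok) {
    grepl(paste0("\\b", tok, "\\b"), nm)
  }), rep(FALSE, length(nm)))
  first_word <- sub("^([a-z0-9-]+).*$", "\\1", nm)
  excluded <- first_word %in% vocab$excluded_ingredients
  flagged <- dose_form | excluded
  data.frame(
    key = entries$key[flagged],
    display_name = entries$display_name[flagged],
    reason = ifelse(dose_form[flagged], "dose_form", "excluded_ingredient"),
    stringsAsFactors = FALSE
  )
}
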