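#' Classify an RxCUI against an RxCUI-keyed map
#'
#' Exact lookup on the digit key. Longitudinal EHR extracts contain RxCUIs
#' that later RxNorm releases retired or remapped; a curated map carries
#' those keys on purpose, so a retired/remapped key still matches and its
#' status is reported on the decision. No remap-following happens at
#' lookup time — remapped identifiers are map content, not resolution
#' logic.
#'
#' @param rxcui A digit string, or `NA` for a record with no RxCUI.
#' @param map A [classification_map] of kind `"rxcui"`.
#' @return A `class_decision` (see [classify_name()]); `key_status` is
#'   `"absent"` when the RxCUI is missing, `"unknown"` when present but
#'   not in the map.
#' @examples
#' map <- load_fixture("table3")
#' classify_rxcui("858813", map)
#' @export
classify_rxcui <- function(rxcui, map) {
  stopifnot(inherits(map, "classification_map"))
  if (map$kind != "rxcui") stop("classify_rxcui needs an rxcui-kind map",
                                call. = FALSE)
  if (length(rxcui) != 1 || is.na(rxcui) || rxcui == "") {
    return(class_decision(matched = FALSE, key_status = "absent"))
  }
  i <- match(rxcui, map$entries$key)
  if (is.na(i)) return(class_decision(matched = FALSE, key_status = "unknown"))
  e <- map$entries[i, ]
  class_decision(matched = TRUE, classes = split_label(e$classes),
                 drug_count = e$drug_count, matched_key = e$key,
                 key_status = e$status)
}

#' Classify prescribing records by name, RxCUI, or both
#'
#' Annotates every record with one classification decision per requested
#' method. Record count is always preserved; unmatched records are kept
#' (they form coverage denominators). In `mode = "both"` a per-record
#' `agreement` flag reports whether the two methods assign the same class
#' set; when the methods disagree both decisions are retained — the two
#' classifications are reported separately, never arbitrated.
#'
#' @param records A `prescribing_table` (see [read_prescribing_table()]),
#'   or any data frame with `raw_med_name` and `rxnorm_cui` columns.
#' @param name_map A name-kind [classification_map] (modes `"name"`,
#'   `"both"`).
#' @param rxcui_map An rxcui-kind [classification_map] (modes `"rxcui"`,
#'   `"both"`).
#' @param mode Which classification method(s) to apply.
#' @param exceptions,vocab Passed to the name normalizer.
#' @return The input data frame with, per method `m` in
#'   `name`/`rxcui`: `<m>_matched`, `<m>_classes` (`"+"`-joined label or
#'   `NA`), `<m>_drug_count`, `<m>_matched_key`, `<m>_key_status`; plus
#'   `agreement` in mode `"both"`. Class `classified_records`.
#' @export
classify_records <- function(records, name_map = NULL, rxcui_map = NULL,
                             mode = c("both", "name", "rxcui"),
                             exceptions = NULL,
                             vocab = default_vocabulary()) {
  mode <- match.arg(mode)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  out <- records
  if (mode %in% c("name", "both")) {
    if (is.null(name_map) || name_map$kind != "name") {
      stop("mode '", mode, "' needs a name-kind map", call. = FALSE)
    }
    out <- cbind(out, classify_names_vectorized(records$raw_med_name,
                                                name_map, exceptions, vocab))
  }
  if (mode %in% c("rxcui", "both")) {
    if (is.null(rxcui_map) || rxcui_map$kind != "rxcui") {
      stop("mode '", mode, "' needs an rxcui-kind map", call. = FALSE)
    }
    out <- cbind(out, classify_rxcuis_vectorized(records$rxnorm_cui,
                                                 rxcui_map))
  }
  if (mode == "both") {
    same <- !is.na(out$name_classes) & !is.na(out$rxcui_classes) &
      vapply(seq_len(nrow(out)), function(i) {
        setequal(split_label(out$name_classes[i]),
                 split_label(out$rxcui_classes[i]))
      }, logical(1))
    out$agreement <- out$name_matched & out$rxcui_matched & same
  }
  rownames(out) <- NULL
  class(out) <- c("classified_records", "data.frame")
  out
}

classify_names_vectorized <- function(raw_names, map, exceptions, vocab) {
  known <- single_ingredient_tokens(map)
  tokens <- vapply(raw_names, function(r) {
    normalize_raw_med_name(r, exceptions = exceptions,
                           known_ingredients = known, vocab = vocab)$token
  }, character(1), USE.NAMES = FALSE)
  i <- match(tokens, map$entries$key)
  matched <- !is.na(i)
  data.frame(
    name_token = tokens,
    name_matched = matched,
    name_classes = ifelse(matched, map$entries$classes[i], NA_character_),
    name_drug_count = ifelse(matched, map$entries$drug_count[i], 0L),
    name_matched_key = ifelse(matched, map$entries$key[i], NA_character_),
    name_key_status = ifelse(matched, map$entries$status[i], "absent"),
    stringsAsFactors = FALSE
  )
}

classify_rxcuis_vectorized <- function(rxcuis, map) {
  missing <- is.na(rxcuis) | rxcuis == ""
  i <- match(rxcuis, map$entries$key)
  matched <- !is.na(i)
  data.frame(
    rxcui_matched = matched,
    rxcui_classes = ifelse(matched, map$entries$classes[i], NA_character_),
    rxcui_drug_count = ifelse(matched, map$entries$drug_count[i], 0L),
    rxcui_matched_key = ifelse(matched, map$entries$key[i], NA_character_),
    rxcui_key_status = ifelse(matched, map$entries$status[i],
                              ifelse(missing, "absent", "unknown")),
    stringsAsFactors = FALSE
  )
}

#' Export classified records to CSV
#'
#' @param records A `classified_records` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_classified_records <- function(records, path) {
  out <- as.data.frame(records)
  out$order_date <- as.character(out$order_date)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
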