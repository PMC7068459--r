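#' Read a PCORnet-style PRESCRIBING table
#'
#' Reads a prescription-order extract in the PCORnet CDM v3.0 PRESCRIBING
#' layout (one row per prescription, with the raw medication name string
#' exactly as it left the source EHR and the RxNorm CUI assigned during CDM
#' mapping, when any). Raw medication names are preserved verbatim apart
#' from surrounding whitespace; empty, `"NA"` and `"NULL"` RxCUI cells
#' become missing values.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector remapping logical column names
#'   (`patient_id`, `order_date`, `raw_med_name`, `rxnorm_cui`) to the
#'   file's header names. Defaults follow PCORnet CDM conventions
#'   (`PATID`, `RX_ORDER_DATE`, `RAW_RX_MED_NAME`, `RXNORM_CUI`).
#' @param missing_values Strings treated as missing in the RxCUI column.
#' @param date_formats Formats tried in order when parsing order dates;
#'   ISO-8601 first.
#' @param on_bad_date `"fail"` (default) stops with the offending row
#'   number; `"skip"` drops unparseable-date rows with a warning.
#' @param delim Field delimiter.
#' @return A data frame of class `prescribing_table` with columns
#'   `patient_id`, `order_date` (`Date`), `raw_med_name`, `rxnorm_cui`
#'   (character, `NA` when missing), in file row order.
#' @export
read_prescribing_table <- function(path,
                                   column_map = NULL,
                                   missing_values = c("", "NA", "NULL"),
                                   date_formats = c("%Y-%m-%d", "%m/%d/%Y",
                                                    "%d%b%Y"),
                                   on_bad_date = c("fail", "skip"),
                                   delim = ",") {
  on_bad_date <- match.arg(on_bad_date)
  defaults <- c(patient_id = "PATID", order_date = "RX_ORDER_DATE",
                raw_med_name = "RAW_RX_MED_NAME", rxnorm_cui = "RXNORM_CUI")
  cmap <- defaults
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map

  raw <- utils::read.csv(path, sep = delim, colClasses = "character",
                         check.names = FALSE, strip.white = FALSE)
  idx <- match(toupper(cmap), toupper(names(raw)))
  names(idx) <- names(cmap)
  if (anyNA(idx)) {
    stop("prescribing table is missing required column(s): ",
         paste(cmap[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    patient_id = raw[[idx[["patient_id"]]]],
    order_date_raw = raw[[idx[["order_date"]]]],
    raw_med_name = trimws(raw[[idx[["raw_med_name"]]]]),
    rxnorm_cui = raw[[idx[["rxnorm_cui"]]]],
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$patient_id) | out$patient_id == "")) {
    stop("empty patient id in row(s): ",
         paste(utils::head(which(is.na(out$patient_id) | out$patient_id == ""), 5),
               collapse = ", "), call. = FALSE)
  }
  out$rxnorm_cui[out$rxnorm_cui %in% missing_values | is.na(out$rxnorm_cui)] <-
    NA_character_
  out$rxnorm_cui <- trimws(out$rxnorm_cui)
  nondigit <- !is.na(out$rxnorm_cui) & !grepl("^[0-9]+$", out$rxnorm_cui)
  if (any(nondigit)) {
    warning(sum(nondigit), " non-numeric RXNORM_CUI cell(s) treated as missing",
            call. = FALSE)
    out$rxnorm_cui[nondigit] <- NA_character_
  }

  dates <- parse_dates(out$order_date_raw, date_formats)
  bad <- which(is.na(dates) & out$order_date_raw != "")
  if (length(bad) > 0) {
    if (on_bad_date == "fail") {
      stop("unparseable order date in data row(s): ",
           paste(utils::head(bad, 5), collapse = ", "),
           " (value: '", out$order_date_raw[bad[1]], "')", call. = FALSE)
    }
    warning("skipping ", length(bad), " row(s) with unparseable order dates",
            call. = FALSE)
    keep <- setdiff(seq_len(nrow(out)), bad)
    out <- out[keep, , drop = FALSE]
    dates <- dates[keep]
  }
  out$order_date <- dates
  out <- out[, c("patient_id", "order_date", "raw_med_name", "rxnorm_cui")]
  rownames(out) <- NULL
  class(out) <- c("prescribing_table", "data.frame")
  out
}

parse_dates <- function(x, formats) {
  res <- as.Date(rep(NA_character_, length(x)))
  remaining <- x != "" & !is.na(x)
  for (fmt in formats) {
    if (!any(remaining)) break
    parsed <- as.Date(x[remaining], format = fmt)
    # reject format hits that drop information (e.g. %Y-%m-%d on "01/02/2011")
    ok <- !is.na(parsed)
    res[which(remaining)[ok]] <- parsed[ok]
    remaining[which(remaining)[ok]] <- FALSE
  }
  res
}

#' Read and write classification-map CSV files
#'
#' The name-keyed schema has columns `Code`, `Drug_Name`, `Generic`,
#' `Drug_Class` (an arbitrary code, the single-word drug name, the resolved
#' generic ingredient for brand names, and the drug class). The RxCUI-keyed
#' schema has columns `RxCUI`, `Drug_Product`, `Rx_Norm_Drug_Class` (alias
#' `Drug_Class`) plus optional `Drug_Count`, `Term_Type` and `Status`.
#' Headers are matched case-insensitively. Combination classes are written
#' as component labels joined with `"+"`.
#'
#' Duplicate keys carrying identical class payloads are deduplicated;
#' duplicate keys with conflicting payloads are rejected.
#'
#' @param path File path.
#' @param kind `"name"` or `"rxcui"`.
#' @param vocabulary Optional [class_vocabulary][read_vocabulary]; when
#'   supplied, unknown class labels are a validation error.
#' @param version_tag Version string recorded on the returned map.
#' @return `read_classification_csv()` returns a
#'   [classification_map]; `write_classification_csv()` invisibly returns
#'   `path`.
#' @export
read_classification_csv <- function(path, kind = c("name", "rxcui"),
                                    vocabulary = NULL, version_tag = "0.1") {
  kind <- match.arg(kind)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  hdr <- tolower(names(raw))
  pick <- function(...) {
    for (nm in c(...)) {
      i <- match(nm, hdr)
      if (!is.na(i)) return(raw[[i]])
    }
    NULL
  }
  if (kind == "name") {
    drug_name <- pick("drug_name", "name")
    classes <- pick("drug_class", "class")
    if (is.null(drug_name) || is.null(classes)) {
      stop("name-kind classification CSV needs Drug_Name and Drug_Class ",
           "columns", call. = FALSE)
    }
    generic <- pick("generic") %||% rep(NA_character_, length(drug_name))
    generic[generic %in% c("", "-", "—")] <- NA_character_
    entries <- data.frame(
      key = tolower(trimws(drug_name)),
      display_name = trimws(drug_name),
      classes = trimws(classes),
      generic_of = tolower(generic),
      stringsAsFactors = FALSE
    )
  } else {
    rxcui <- pick("rxcui")
    classes <- pick("rx_norm_drug_class", "drug_class", "class")
    if (is.null(rxcui) || is.null(classes)) {
      stop("rxcui-kind classification CSV needs RxCUI and Rx_Norm_Drug_Class ",
           "(or Drug_Class) columns", call. = FALSE)
    }
    entries <- data.frame(
      key = trimws(rxcui),
      display_name = trimws(pick("drug_product", "display_name") %||% rxcui),
      classes = trimws(classes),
      stringsAsFactors = FALSE
    )
    entries$term_type <- pick("term_type", "tty") %||% NA_character_
    entries$term_type[!is.na(entries$term_type) & entries$term_type == ""] <-
      NA_character_
    entries$status <- pick("status") %||% "active"
  }
  dc <- pick("drug_count")
  if (!is.null(dc)) entries$drug_count <- as.integer(dc)

  entries <- dedupe_entries(entries)
  if (nrow(entries) == 0) {
    entries <- data.frame(key = character(), display_name = character(),
                          classes = character(), stringsAsFactors = FALSE)
  }
  classification_map(kind, entries, vocabulary = vocabulary,
                     version_tag = version_tag)
}

dedupe_entries <- function(entries) {
  if (nrow(entries) == 0 || !anyDuplicated(entries$key)) return(entries)
  split_idx <- split(seq_len(nrow(entries)), entries$key)
  conflicts <- character()
  keep <- integer()
  for (key in names(split_idx)) {
    idx <- split_idx[[key]]
    payloads <- unique(entries$classes[idx])
    if (length(payloads) > 1) conflicts <- c(conflicts, key)
    keep <- c(keep, idx[1])
  }
  if (length(conflicts) > 0) {
    stop("conflicting class payloads for duplicated key(s): ",
         paste(utils::head(sort(conflicts), 5), collapse = ", "),
         call. = FALSE)
  }
  entries[sort(keep), , drop = FALSE]
}

#' @rdname read_classification_csv
#' @param map A [classification_map] to serialize.
#' @export
write_classification_csv <- function(map, path) {
  stopifnot(inherits(map, "classification_map"))
  e <- map$entries
  if (map$kind == "name") {
    # Drug_Name must normalize back to the key on re-read; keep the display
    # surface only when it does
    out <- data.frame(
      Code = seq_len(nrow(e)),
      Drug_Name = ifelse(tolower(e$display_name) == e$key, e$display_name,
                         e$key),
      Generic = ifelse(is.na(e$generic_of), "", e$generic_of),
      Drug_Class = e$classes,
      Drug_Count = e$drug_count,
      stringsAsFactors = FALSE
    )
  } else {
    out <- data.frame(
      RxCUI = e$key,
      Drug_Product = e$display_name,
      Rx_Norm_Drug_Class = e$classes,
      Drug_Count = e$drug_count,
      Term_Type = ifelse(is.na(e$term_type), "", e$term_type),
      Status = e$status,
      stringsAsFactors = FALSE
    )
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read an RxClass batch-query export
#'
#' Parses the tabular output of a batch `getClassByRxNormDrugId` query (one
#' row per drug-to-class relationship). Columns are resolved
#' case-insensitively: the RxCUI, the concept name, the relationship source
#' (`relaSource`: ATC, MED-RT or DrOn), the relationship (`rela`, e.g.
#' `may_treat`, `has_MoA`) and the class name; a term-type column is
#' optional.
#'
#' @param path Path to the export (tab-separated by default).
#' @param delim Field delimiter.
#' @return A data frame of class `terminology_relations` with columns
#'   `rxcui`, `concept_name`, `term_type`, `rela_source` (one of `"ATC"`,
#'   `"MEDRT"`, `"DRON"`), `rela`, `class_name`.
#' @export
read_rxclass_batch <- function(path, delim = "\t") {
  raw <- utils::read.delim(path, sep = delim, colClasses = "character",
                           check.names = FALSE, strip.white = TRUE)
  hdr <- tolower(gsub("[ _]", "", names(raw)))
  pick <- function(...) {
    for (nm in c(...)) {
      i <- match(nm, hdr)
      if (!is.na(i)) return(raw[[i]])
    }
    NULL
  }
  rxcui <- pick("rxcui", "minconceptrxcui", "drugid")
  concept <- pick("conceptname", "name", "minconceptname", "drugname")
  source <- pick("relasource", "classtype", "source")
  rela <- pick("rela", "relationship")
  class_name <- pick("classname", "classid", "class")
  term_type <- pick("termtype", "tty")
  if (is.null(rxcui) || is.null(source) || is.null(class_name)) {
    stop("RxClass batch file needs columns resolvable to rxcui, relaSource ",
         "and class name", call. = FALSE)
  }
  n <- length(rxcui)
  if (n == 0) return(empty_relations())
  rel <- data.frame(
    rxcui = trimws(rxcui),
    concept_name = concept %||% rep(NA_character_, n),
    term_type = term_type %||% rep(NA_character_, n),
    rela_source = normalize_rela_source(source),
    rela = rela %||% rep(NA_character_, n),
    class_name = trimws(class_name),
    stringsAsFactors = FALSE
  )
  rel$term_type[!is.na(rel$term_type) & rel$term_type == ""] <- NA_character_
  bad <- !grepl("^[0-9]+$", rel$rxcui)
  if (any(bad)) {
    stop("non-numeric rxcui value(s) in relationship export: ",
         paste(utils::head(unique(rel$rxcui[bad]), 5), collapse = ", "),
         call. = FALSE)
  }
  rownames(rel) <- NULL
  class(rel) <- c("terminology_relations", "data.frame")
  rel
}

normalize_rela_source <- function(x) {
  key <- toupper(gsub("[^A-Za-z]", "", x))
  out <- c(ATC = "ATC", MEDRT = "MEDRT", NDFRT = "MEDRT", DRON = "DRON")[key]
  if (anyNA(out)) {
    stop("unrecognized relaSource value(s): ",
         paste(utils::head(unique(x[is.na(out)]), 5), collapse = ", "),
         call. = FALSE)
  }
  unname(out)
}

# In-code constructor for relation collections (used by the synthetic
# generator and tests).
terminology_relations <- function(rxcui, class_name, rela_source,
                                  rela = NA_character_,
                                  concept_name = NA_character_,
                                  term_type = NA_character_) {
  n <- length(rxcui)
  rel <- data.frame(
    rxcui = as.character(rxcui),
    concept_name = rep_len(as.character(concept_name), n),
    term_type = rep_len(as.character(term_type), n),
    rela_source = normalize_rela_source(rep_len(as.character(rela_source), n)),
    rela = rep_len(as.character(rela), n),
    class_name = as.character(class_name),
    stringsAsFactors = FALSE
  )
  class(rel) <- c("terminology_relations", "data.frame")
  rel
}

empty_relations <- function() {
  rel <- data.frame(rxcui = character(), concept_name = character(),
                    term_type = character(), rela_source = character(),
                    rela = character(), class_name = character(),
                    stringsAsFactors = FALSE)
  class(rel) <- c("terminology_relations", "data.frame")
  rel
}

#' Read a diagnosis table
#'
#' Reads a diagnosis extract (PCORnet DIAGNOSIS-style) for hypertension
#' cohort selection. Code types `"09"`, `"9"` and `"ICD9"` normalize to
#' `ICD9`; `"10"` and `"ICD10"` to `ICD10`. Encounter types `"AV"`
#' (ambulatory visit), `"OA"` (other ambulatory) and `"OUTPATIENT"`
#' normalize to `outpatient`; everything else to `other`.
#'
#' @param path Path to a CSV with a header row.
#' @param column_map Named character vector remapping logical names
#'   (`patient_id`, `code`, `code_type`, `encounter_type`,
#'   `age_at_encounter`); defaults `PATID`, `DX`, `DX_TYPE`, `ENC_TYPE`,
#'   `AGE`.
#' @return A data frame of class `diagnosis_table` with columns
#'   `patient_id`, `code`, `code_type`, `encounter_type`,
#'   `age_at_encounter`.
#' @export
read_diagnosis_table <- function(path, column_map = NULL) {
  defaults <- c(patient_id = "PATID", code = "DX", code_type = "DX_TYPE",
                encounter_type = "ENC_TYPE", age_at_encounter = "AGE")
  cmap <- defaults
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  idx <- match(toupper(cmap), toupper(names(raw)))
  names(idx) <- names(cmap)
  if (anyNA(idx)) {
    stop("diagnosis table is missing required column(s): ",
         paste(cmap[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    patient_id = raw[[idx[["patient_id"]]]],
    code = raw[[idx[["code"]]]],
    code_type = normalize_code_type(raw[[idx[["code_type"]]]]),
    encounter_type = normalize_encounter_type(raw[[idx[["encounter_type"]]]]),
    age_at_encounter = as.integer(raw[[idx[["age_at_encounter"]]]]),
    stringsAsFactors = FALSE
  )
  if (any(out$code == "" | is.na(out$code))) {
    stop("empty diagnosis code in input", call. = FALSE)
  }
  if (any(!is.na(out$age_at_encounter) & out$age_at_encounter < 0)) {
    stop("negative age_at_encounter in input", call. = FALSE)
  }
  class(out) <- c("diagnosis_table", "data.frame")
  out
}

normalize_code_type <- function(x) {
  key <- toupper(gsub("[^A-Za-z0-9]", "", x))
  out <- rep(NA_character_, length(x))
  out[key %in% c("09", "9", "ICD9", "ICD9CM")] <- "ICD9"
  out[key %in% c("10", "ICD10", "ICD10CM")] <- "ICD10"
  if (anyNA(out)) {
    stop("unrecognized diagnosis code type(s): ",
         paste(utils::head(unique(x[is.na(out)]), 5), collapse = ", "),
         call. = FALSE)
  }
  out
}

normalize_encounter_type <- function(x) {
  key <- toupper(trimws(x))
  ifelse(key %in% c("AV", "OA", "OUTPATIENT", "OP"), "outpatient", "other")
}
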