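# Independent brute-force oracles used by property-style tests. Each is a
# deliberately naive re-derivation (double loops, per-key scans) kept
# separate from the implementation it checks.

# Double-loop membership scan for set comparison.
oracle_pairwise <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  overlap <- character()
  ua <- character()
  for (x in a) {
    found <- FALSE
    for (y in b) if (identical(x, y)) { found <- TRUE; break }
    if (found) overlap <- c(overlap, x) else ua <- c(ua, x)
  }
  ub <- character()
  for (y in b) {
    found <- FALSE
    for (x in a) if (identical(x, y)) { found <- TRUE; break }
    if (!found) ub <- c(ub, y)
  }
  list(overlap = sort(overlap), unique_a = sort(ua), unique_b = sort(ub))
}

# Per-key scan: expected {rxcui -> sorted label set} for the ATC builder.
oracle_atc <- function(relations, vocab) {
  out <- list()
  for (key in unique(relations$rxcui)) {
    labels <- character()
    for (i in seq_len(nrow(relations))) {
      if (relations$rxcui[i] == key &&
          tolower(relations$class_name[i]) %in% names(vocab$atc_class_names)) {
        labels <- c(labels, vocab$atc_class_names[[tolower(relations$class_name[i])]])
      }
    }
    if (length(labels) > 0) out[[key]] <- sort(unique(labels))
  }
  if (length(out) == 0) return(out)
  out[order(names(out))]
}

# Two-pass scan: expected {rxcui -> sorted label set} for the MED-RT builder.
oracle_medrt <- function(relations, vocab) {
  htn <- character()
  for (i in seq_len(nrow(relations))) {
    if (relations$rela[i] == "may_treat" &&
        tolower(relations$class_name[i]) %in% vocab$may_treat_hypertension) {
      htn <- c(htn, relations$rxcui[i])
    }
  }
  out <- list()
  for (key in unique(htn)) {
    labels <- character()
    for (i in seq_len(nrow(relations))) {
      if (relations$rxcui[i] == key && relations$rela[i] == "has_MoA" &&
          tolower(relations$class_name[i]) %in% names(vocab$medrt_moa_names)) {
        labels <- c(labels, vocab$medrt_moa_names[[tolower(relations$class_name[i])]])
      }
    }
    if (length(labels) > 0) out[[key]] <- sort(unique(labels))
  }
  if (length(out) == 0) return(out)
  out[order(names(out))]
}

# Collapse a built map into the oracle's {key -> sorted label set} shape.
map_as_label_sets <- function(map) {
  out <- lapply(map$entries$classes, function(cl) sort(strsplit(cl, "+", fixed = TRUE)[[1]]))
  names(out) <- map$entries$key
  if (length(out) == 0) return(list())
  out[order(names(out))]
}

# Random relation set over a small rxcui universe, mixing accepted and
# rejected class names and both rela kinds.
random_relations <- function(n, vocab) {
  rxcuis <- as.character(sample(1000:1080, n, replace = TRUE))
  accepted_atc <- names(vocab$atc_class_names)
  accepted_moa <- names(vocab$medrt_moa_names)
  rejected <- c("lipid modifying agents", "drugs used in diabetes",
                "Serotonin Uptake Inhibitors")
  source <- sample(c("ATC", "MEDRT"), n, replace = TRUE)
  rela <- ifelse(source == "ATC", "atc_class_member",
                 sample(c("may_treat", "has_MoA"), n, replace = TRUE))
  class_name <- character(n)
  for (i in seq_len(n)) {
    class_name[i] <- if (source[i] == "MEDRT" && rela[i] == "may_treat") {
      sample(c("Hypertension", "Diabetes Mellitus", "Glaucoma"), 1)
    } else if (source[i] == "MEDRT") {
      sample(c(accepted_moa, rejected), 1)
    } else {
      sample(c(accepted_atc, rejected), 1)
    }
  }
  ahtnclass:::terminology_relations(
    rxcui = rxcuis, class_name = class_name, rela_source = source,
    rela = rela, concept_name = paste("Concept", rxcuis)
  )
}

# Random small name- or rxcui-kind entry table for round-trip properties.
random_entries <- function(n, kind, vocab) {
  labels <- vocab$labels
  keys <- if (kind == "rxcui") {
    as.character(sample(10000:99999, n))
  } else {
    unique(replicate(n, paste(sample(letters, 8, replace = TRUE), collapse = "")))
  }
  combo <- runif(length(keys)) < 0.3
  classes <- ifelse(combo,
                    vapply(seq_along(keys), function(i)
                      paste(sample(labels, 2), collapse = "+"), character(1)),
                    sample(labels, length(keys), replace = TRUE))
  data.frame(
    key = keys,
    display_name = paste("Drug", toupper(keys)),
    classes = classes,
    drug_count = ifelse(combo, 2L, 1L),
    generic_of = NA_character_,
    term_type = if (kind == "rxcui") sample(c("SCD", "SBD", NA), length(keys),
                                            replace = TRUE) else NA_character_,
    status = sample(c("active", "retired"), length(keys), replace = TRUE,
                    prob = c(0.9, 0.1)),
    stringsAsFactors = FALSE
  )
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
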