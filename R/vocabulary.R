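#' Drug-class vocabulary and terminology acceptance lists
#'
#' A `class_vocabulary` bundles everything needed to interpret terminology
#' exports and medication names as antihypertensive drug classes: the set of
#' drug-class labels, the ATC class names and MED-RT mechanism-of-action
#' (MoA) names accepted as antihypertensive (each mapped to the label(s) it
#' confers), the string(s) denoting hypertension in MED-RT `may_treat`
#' output, dose-form screening tokens, ingredient exclusion lists, the
#' RxNorm term-type policy, and name-normalization helpers (strength/dose
#' tokens, ingredient synonyms).
#'
#' Combination classes are labelled by joining component labels with `"+"`
#' (e.g. `"THIAZIDE+ACE"`); any such label is implicitly part of the
#' vocabulary whenever every component label is.
#'
#' @param path Path to a YAML configuration file. The default reads the
#'   configuration shipped with the package, whose acceptance lists are
#'   seeded with the standard antihypertensive ATC and MED-RT class names.
#' @return A `class_vocabulary` object (a validated named list).
#' @examples
#' vocab <- default_vocabulary()
#' vocab$labels
#' @export
read_vocabulary <- function(path) {
  raw <- yaml::read_yaml(path)
  required <- c("labels", "atc_class_names", "medrt_moa_names",
                "may_treat_hypertension", "dose_form_tokens")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("vocabulary config is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vocab <- list(
    labels = as.character(raw$labels),
    atc_class_names = lapply(raw$atc_class_names, as.character),
    medrt_moa_names = lapply(raw$medrt_moa_names, as.character),
    may_treat_hypertension = tolower(as.character(raw$may_treat_hypertension)),
    dose_form_tokens = tolower(as.character(raw$dose_form_tokens)),
    bph_ingredients = tolower(as.character(raw$bph_ingredients %||% character())),
    excluded_ingredients = tolower(as.character(raw$excluded_ingredients %||% character())),
    term_types_included = as.character(raw$term_types_included %||% c("SCD", "SBD", "SCDF")),
    term_types_excluded = as.character(raw$term_types_excluded %||% c("IN", "MIN", "PIN")),
    dose_tokens = tolower(as.character(raw$dose_tokens %||% character())),
    synonyms = lapply(raw$synonyms %||% list(), as.character)
  )
  names(vocab$atc_class_names) <- tolower(names(raw$atc_class_names))
  names(vocab$medrt_moa_names) <- tolower(names(raw$medrt_moa_names))
  validate_vocabulary(vocab)
}

#' @rdname read_vocabulary
#' @export
default_vocabulary <- function() {
  path <- system.file("extdata", "config", "default_vocab.yaml",
                      package = "ahtnclass", mustWork = TRUE)
  read_vocabulary(path)
}

validate_vocabulary <- function(vocab) {
  if (length(vocab$labels) == 0) {
    stop("vocabulary must declare at least one drug-class label", call. = FALSE)
  }
  bad_atc <- setdiff(unlist(vocab$atc_class_names), vocab$labels)
  bad_moa <- setdiff(unlist(vocab$medrt_moa_names), vocab$labels)
  if (length(bad_atc) > 0 || length(bad_moa) > 0) {
    stop("acceptance lists reference unknown drug-class label(s): ",
         paste(unique(c(bad_atc, bad_moa)), collapse = ", "), call. = FALSE)
  }
  structure(vocab, class = "class_vocabulary")
}

#' @export
print.class_vocabulary <- function(x, ...) {
  cat("<class_vocabulary>\n")
  cat("  labels:          ", length(x$labels), "\n")
  cat("  ATC class names: ", length(x$atc_class_names), "\n")
  cat("  MED-RT MoA names:", length(x$medrt_moa_names), "\n")
  invisible(x)
}

# Split a (possibly combination) class label into component labels.
split_label <- function(label) strsplit(label, "+", fixed = TRUE)[[1]]

# Join component labels into a single (possibly combination) class label.
join_label <- function(labels) paste(labels, collapse = "+")

# TRUE where `label` (vector) is valid under the vocabulary, combinations
# included.
label_in_vocabulary <- function(label, vocab) {
  vapply(label, function(l) {
    all(split_label(l) %in% vocab$labels)
  }, logical(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
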