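#' Construct a classification map
#'
#' A classification map assigns antihypertensive drug class(es) to keys that
#' are either normalized ingredient-name tokens (`kind = "name"`, lowercase,
#' underscore-joined for combination products) or RxNorm concept unique
#' identifiers (`kind = "rxcui"`, digit strings of length >= 4).
#'
#' @param kind `"name"` or `"rxcui"`.
#' @param entries A data frame with columns `key`, `display_name`, `classes`
#'   (class label, `"+"`-joined for combinations), and optionally
#'   `drug_count` (defaults to the number of component classes),
#'   `generic_of` (resolved generic ingredient for brand-name entries),
#'   `term_type` (RxNorm TTY) and `status`
#'   (`active`/`retired`/`remapped`/`unknown`, default `active`).
#' @param vocabulary A [class_vocabulary][read_vocabulary] used to validate
#'   class labels; `NULL` skips the closed-vocabulary check.
#' @param version_tag Free-text version string carried through
#'   [reconcile_maps()].
#' @return A `classification_map` object.
#' @examples
#' m <- classification_map(
#'   "name",
#'   data.frame(key = "lisinopril", display_name = "Lisinopril",
#'              classes = "ACE")
#' )
#' map_keys(m)
#' @export
classification_map <- function(kind = c("name", "rxcui"), entries,
                               vocabulary = NULL, version_tag = "0.1") {
  kind <- match.arg(kind)
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  required <- c("key", "classes")
  missing <- setdiff(required, names(entries))
  if (length(missing) > 0) {
    stop("entries must have column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(entries)
  if (!"display_name" %in% names(entries)) entries$display_name <- entries$key
  if (!"generic_of" %in% names(entries)) {
    entries$generic_of <- rep(NA_character_, n)
  }
  if (!"term_type" %in% names(entries)) {
    entries$term_type <- rep(NA_character_, n)
  }
  if (!"status" %in% names(entries)) entries$status <- rep("active", n)
  entries$key <- as.character(entries$key)
  entries$classes <- as.character(entries$classes)
  n_components <- vapply(entries$classes,
                         function(cl) length(split_label(cl)),
                         integer(1), USE.NAMES = FALSE)
  if (!"drug_count" %in% names(entries)) {
    entries$drug_count <- n_components
  }
  entries$drug_count <- as.integer(entries$drug_count)
  entries$drug_count[is.na(entries$drug_count)] <- n_components[is.na(entries$drug_count)]
  entries$status[is.na(entries$status) | entries$status == ""] <- "active"
  entries <- entries[, c("key", "display_name", "classes", "drug_count",
                         "generic_of", "term_type", "status")]
  map <- structure(
    list(kind = kind, entries = entries, vocabulary = vocabulary,
         version_tag = version_tag),
    class = "classification_map"
  )
  validate_classification_map(map)
}

validate_classification_map <- function(map) {
  e <- map$entries
  if (anyDuplicated(e$key)) {
    dup <- unique(e$key[duplicated(e$key)])
    stop("duplicate map key(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(e$classes) | e$classes == "")) {
    stop("every entry must carry at least one drug class", call. = FALSE)
  }
  if (map$kind == "rxcui") {
    bad <- e$key[!grepl("^[0-9]+$", e$key) | nchar(e$key) < 4]
    if (length(bad) > 0) {
      stop("rxcui-kind keys must be digit strings of length >= 4; offending: ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  } else {
    bad <- e$key[grepl("\\s", e$key) | e$key != tolower(e$key) | e$key == ""]
    if (length(bad) > 0) {
      stop("name-kind keys must be non-empty lowercase tokens without ",
           "whitespace; offending: ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  n_components <- vapply(e$classes, function(cl) length(split_label(cl)),
                         integer(1), USE.NAMES = FALSE)
  if (any(e$drug_count < n_components | e$drug_count < 1L)) {
    bad <- e$key[e$drug_count < n_components | e$drug_count < 1L]
    stop("drug_count below the number of component classes for key(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (!is.null(map$vocabulary)) {
    ok <- label_in_vocabulary(e$classes, map$vocabulary)
    if (!all(ok)) {
      stop("unknown drug-class label(s): ",
           paste(utils::head(unique(e$classes[!ok]), 5), collapse = ", "),
           call. = FALSE)
    }
  }
  map
}

#' Map accessors
#'
#' @param map A `classification_map`.
#' @return `map_keys()` returns the character vector of keys; `map_size()`
#'   the number of entries; `map_entry()` the entry row for one key (or
#'   `NULL`).
#' @export
map_keys <- function(map) map$entries$key

#' @rdname map_keys
#' @export
map_size <- function(map) nrow(map$entries)

#' @rdname map_keys
#' @param key A single key string.
#' @export
map_entry <- function(map, key) {
  i <- match(key, map$entries$key)
  if (is.na(i)) return(NULL)
  map$entries[i, , drop = FALSE]
}

#' @export
print.classification_map <- function(x, ...) {
  cat(sprintf("<classification_map kind=%s version=%s entries=%d>\n",
              x$kind, x$version_tag, nrow(x$entries)))
  tab <- sort(table(x$entries$classes), decreasing = TRUE)
  shown <- utils::head(tab, 8)
  cat("  classes:", paste(sprintf("%s (%d)", names(shown), shown),
                          collapse = ", "),
      if (length(tab) > length(shown)) "..." else "", "\n")
  invisible(x)
}

#' @export
format.classification_map <- function(x, ...) {
  sprintf("<classification_map kind=%s entries=%d>", x$kind, nrow(x$entries))
}
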