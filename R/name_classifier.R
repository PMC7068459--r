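#' Normalize a raw medication-name string to an ingredient token
#'
#' EHR raw medication names lead with the ingredient (or brand) name,
#' followed by strength and dose form ("Lisinopril 10 MG Oral Tablet").
#' Normalization extracts the first word as the ingredient token, with
#' extra handling for combination products: a leading hyphen- or
#' slash-separated pair ("HCTZ-metoprolol ...") — or two bare words that
#' both match known ingredient tokens — is joined with an underscore in
#' input order. Exception patterns (for strings where the ingredient is
#' not the first word) are checked first. Tokens are lowercase and carry
#' no whitespace; a string with no alphabetic content is `unparseable`.
#'
#' @param raw The raw medication name (one string).
#' @param exceptions Named character vector: regular expression (matched
#'   case-insensitively against the trimmed raw string) -> token. Empty by
#'   default.
#' @param known_ingredients Character vector of single-ingredient tokens
#'   used to decide whether two bare words form a combination; typically
#'   derived from a name-keyed map (see [classify_name()]).
#' @param vocab A [class_vocabulary][read_vocabulary] supplying the
#'   strength/dose tokens that terminate ingredient scanning.
#' @return A list of class `normalized_name`: `token`, `source` (the
#'   verbatim input), `rule_applied` (`first_word`, `combination_join`,
#'   `exception_list`, or `unparseable`).
#' @examples
#' normalize_raw_med_name("Lisinopril 10 MG Oral Tablet")$token
#' normalize_raw_med_name("HCTZ-metoprolol 25-50 MG Oral Tablet")$token
#' @export
normalize_raw_med_name <- function(raw, exceptions = NULL,
                                   known_ingredients = character(),
                                   vocab = default_vocabulary()) {
  stopifnot(is.character(raw), length(raw) == 1)
  s <- trimws(raw)
  result <- function(token, rule) {
    structure(list(token = token, source = raw, rule_applied = rule),
              class = "normalized_name")
  }
  if (!is.null(exceptions) && length(exceptions) > 0) {
    for (pat in names(exceptions)) {
      if (grepl(pat, s, ignore.case = TRUE)) {
        return(result(tolower(exceptions[[pat]]), "exception_list"))
      }
    }
  }
  if (!grepl("[A-Za-z]", s)) return(result("", "unparseable"))
  low <- tolower(s)
  words <- strsplit(low, "\\s+")[[1]]
  first <- words[1]

  # leading hyphen/slash-separated ingredient pair -> combination
  parts <- strsplit(first, "[-/]")[[1]]
  parts <- vapply(parts, clean_token, character(1), USE.NAMES = FALSE)
  parts <- parts[parts != "" & grepl("[a-z]", parts)]
  if (length(parts) >= 2) {
    return(result(paste(parts, collapse = "_"), "combination_join"))
  }

  tok <- clean_token(first)
  if (tok == "") return(result("", "unparseable"))

  # two bare ingredient words before the strength/dose section
  if (length(words) >= 2) {
    second <- clean_token(words[2])
    if (tok %in% known_ingredients && second %in% known_ingredients &&
        !is_dose_token(second, vocab)) {
      return(result(paste(tok, second, sep = "_"), "combination_join"))
    }
  }
  result(tok, "first_word")
}

# Strip punctuation other than internal hyphens/slashes (handled upstream);
# keeps letters and digits.
clean_token <- function(x) gsub("[^a-z0-9]", "", x)

is_dose_token <- function(tok, vocab) {
  tok %in% vocab$dose_tokens || grepl("^[0-9.%/-]+$", tok) || tok == ""
}

#' Expand all permutations of a combination-product name
#'
#' A name-keyed map can only catch a combination product if every surface
#' ordering and every ingredient abbreviation is a key: HCTZ-metoprolol,
#' hydrochlorothiazide-metoprolol, metoprolol-HCTZ and
#' metoprolol-hydrochlorothiazide must all resolve. Given the component
#' tokens and a synonym table, this returns every ordering of every
#' synonym choice, underscore-joined: for 2 components with synonym-set
#' sizes a and b, `2ab` tokens.
#'
#' @param components Character vector of >= 2 ingredient tokens, in
#'   canonical order.
#' @param synonyms Named list mapping a token to its synonym set. The
#'   closure is symmetric: `list(hydrochlorothiazide = "hctz")` makes
#'   hctz a variant of hydrochlorothiazide and vice versa.
#' @return Character vector of unique combination tokens (sorted).
#' @examples
#' expand_combination_permutations(
#'   c("hydrochlorothiazide", "metoprolol"),
#'   synonyms = list(hydrochlorothiazide = "hctz"))
#' @export
expand_combination_permutations <- function(components, synonyms = list()) {
  if (length(components) < 2) {
    stop("a combination needs at least 2 components", call. = FALSE)
  }
  components <- tolower(components)
  variants <- lapply(components, function(comp) {
    direct <- unlist(synonyms[[comp]])
    reverse <- names(synonyms)[vapply(synonyms, function(v) comp %in% tolower(v),
                                      logical(1))]
    unique(c(comp, tolower(direct), tolower(reverse)))
  })
  perms <- permutations(length(components))
  out <- character()
  for (p in seq_len(nrow(perms))) {
    ordered <- variants[perms[p, ]]
    grid <- expand.grid(ordered, stringsAsFactors = FALSE)
    out <- c(out, apply(grid, 1, paste, collapse = "_"))
  }
  sort(unique(out))
}

# All permutations of 1..n as a matrix (n is small: combination products
# have 2-3 ingredients).
permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

#' Classify a raw medication name against a name-keyed map
#'
#' Normalizes the raw string (see [normalize_raw_med_name()]) and looks the
#' token up in the map. Names that do not merge with the map — statins,
#' insulin, and every other non-antihypertensive — come back unmatched;
#' they are discarded from antihypertensive analyses but stay in coverage
#' denominators.
#'
#' @param raw Raw medication-name string.
#' @param map A [classification_map] of kind `"name"`.
#' @param exceptions Passed to [normalize_raw_med_name()].
#' @param vocab Passed to [normalize_raw_med_name()].
#' @return A `class_decision`: `matched`, `classes` (character vector of
#'   component labels, empty when unmatched), `drug_count`, `matched_key`,
#'   `key_status`, `generic_of`, `token`.
#' @examples
#' map <- load_fixture("table2")
#' classify_name("Lotensin 20 MG Oral Tablet", map)
#' @export
classify_name <- function(raw, map, exceptions = NULL,
                          vocab = default_vocabulary()) {
  stopifnot(inherits(map, "classification_map"))
  if (map$kind != "name") stop("classify_name needs a name-kind map",
                               call. = FALSE)
  norm <- normalize_raw_med_name(raw, exceptions = exceptions,
                                 known_ingredients = single_ingredient_tokens(map),
                                 vocab = vocab)
  decision_from_lookup(norm$token, map, token = norm$token)
}

# Single-ingredient tokens of a name map: keys without an underscore plus
# the components of combination keys.
single_ingredient_tokens <- function(map) {
  keys <- map$entries$key
  unique(c(keys[!grepl("_", keys)],
           unlist(strsplit(keys[grepl("_", keys)], "_", fixed = TRUE))))
}

decision_from_lookup <- function(key, map, token = NULL) {
  i <- if (is.null(key) || is.na(key) || key == "") NA_integer_
       else match(key, map$entries$key)
  if (is.na(i)) {
    return(class_decision(matched = FALSE, token = token))
  }
  e <- map$entries[i, ]
  class_decision(
    matched = TRUE,
    classes = split_label(e$classes),
    drug_count = e$drug_count,
    matched_key = e$key,
    key_status = e$status,
    generic_of = e$generic_of,
    token = token
  )
}

class_decision <- function(matched, classes = character(), drug_count = 0L,
                           matched_key = NA_character_,
                           key_status = if (matched) "active" else "absent",
                           generic_of = NA_character_, token = NULL) {
  structure(
    list(matched = matched, classes = classes,
         drug_count = as.integer(drug_count), matched_key = matched_key,
         key_status = key_status, generic_of = generic_of, token = token),
    class = "class_decision"
  )
}

#' @export
print.class_decision <- function(x, ...) {
  if (x$matched) {
    cat(sprintf("<class_decision matched key=%s classes=%s drug_count=%d status=%s>\n",
                x$matched_key, join_label(x$classes), x$drug_count,
                x$key_status))
  } else {
    cat(sprintf("<class_decision unmatched (%s)>\n", x$key_status))
  }
  invisible(x)
}
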