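# Registered fixture files and their frozen checksums. The excerpts are
# authoritative reference data; load_fixture() refuses to return a file
# whose bytes have drifted.
fixture_registry <- function() {
  list(
    table2 = list(file = "table2_name_map.csv",
                  md5 = "6bf94e6185c57ba0551c08c3368ca32b"),
    table3 = list(file = "table3_rxcui_map.csv",
                  md5 = "84e9a7f359a8febe7c412734caa12866"),
    table5 = list(file = "table5_misclassified.tsv",
                  md5 = "0538d556f3f3048596ecbc65ee3cffd6"),
    table7 = list(file = "table7_class_frequencies.csv",
                  md5 = "827d7fd9a04e3b1c879e6f73d7c6e9ab")
  )
}

#' Load a packaged reference fixture
#'
#' Four reference excerpts ship with the package, checksum-verified on
#' every load:
#'
#' * `"table2"` — an 11-entry excerpt of the name-keyed classification
#'   (ACE inhibitors, brand and generic), as a name-kind
#'   [classification_map].
#' * `"table3"` — a 13-entry excerpt of the RxCUI-keyed classification
#'   (enalapril/enalaprilat products, all ACE), as an rxcui-kind
#'   [classification_map].
#' * `"table5"` — three RxCUIs inappropriately mapped as antihypertensives
#'   by terminology-derived maps (topical minoxidil, ophthalmic timolol
#'   and betaxolol), as a data frame with columns `RxCUI`, `DrugName`,
#'   `hasMOA`, `ConceptName`, `DoseForm`.
#' * `"table7"` — per-class prescribing frequencies (12 classes, counts
#'   and percentages over 2,089,557 mapped records), as a data frame with
#'   a `total_mapped` attribute.
#'
#' @param name One of `"table2"`, `"table3"`, `"table5"`, `"table7"`.
#' @return The typed fixture object described above.
#' @examples
#' map_size(load_fixture("table3"))
#' @export
load_fixture <- function(name) {
  registry <- fixture_registry()
  if (length(name) != 1 || !name %in% names(registry)) {
    stop("unknown fixture '", paste(name, collapse = ","), "'; registered: ",
         paste(names(registry), collapse = ", "), call. = FALSE)
  }
  entry <- registry[[name]]
  path <- system.file("extdata", "fixtures", entry$file,
                      package = "ahtnclass", mustWork = TRUE)
  actual <- unname(tools::md5sum(path))
  if (!identical(actual, entry$md5)) {
    stop("fixture '", name, "' failed checksum verification (", actual,
         " != ", entry$md5, ")", call. = FALSE)
  }
  switch(name,
    table2 = read_classification_csv(path, kind = "name",
                                     version_tag = "excerpt"),
    table3 = read_classification_csv(path, kind = "rxcui",
                                     version_tag = "excerpt"),
    table5 = utils::read.delim(path, colClasses = "character",
                               check.names = FALSE),
    table7 = {
      tab <- utils::read.csv(path, stringsAsFactors = FALSE)
      tab$count <- as.integer(tab$count)
      attr(tab, "total_mapped") <- 2089557L
      tab
    }
  )
}
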