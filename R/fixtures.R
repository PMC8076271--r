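#' Load a packaged fixture table
#'
#' Four fixtures ship with the package, transcribed from the printed tables of
#' a 34-hexapeptide IR adjudication study:
#'
#' * `"reference_set"`: 10 peptides with database label, band annotations and
#'   class calls for both IR modes, plus the AFM call.
#' * `"test_set"`: 24 peptides with database label and both IR modes.
#' * `"predictor_calls_reference"`, `"predictor_calls_test"`: calls of five
#'   sequence-based predictors per peptide, the IR-microscopy call, and the
#'   printed per-peptide consensus percentage.
#'
#' Class calls are normalized to `"positive"`/`"negative"`/`"oligomer"` on
#' load (the print uses Yes/No/Yes* with inconsistent case). Band annotations
#' stay in their string notation; parse with [parse_band_string()].
#'
#' @param name one of `"reference_set"`, `"test_set"`,
#'   `"predictor_calls_reference"`, `"predictor_calls_test"`.
#' @return a data frame; set fixtures additionally carry `origin` and `subset`
#'   columns so they validate as peptide records.
#' @export
#' @examples
#' ref <- load_fixture("reference_set")
#' ref$sequence[1]
load_fixture <- function(name) {
  known <- c("reference_set", "test_set",
             "predictor_calls_reference", "predictor_calls_test")
  if (!is.character(name) || length(name) != 1 || !name %in% known) {
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; available: ", paste(known, collapse = ", "))
  }
  path <- system.file("extdata", paste0(name, ".tsv"), package = "amylir",
                      mustWork = TRUE)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character")
  call_cols <- intersect(
    c("ir_microscopy_class", "atr_ftir_class", "afm_class", "database",
      "ir_microscopy", .amylir_methods),
    names(tab))
  for (col in call_cols) {
    tab[[col]] <- normalize_call(tab[[col]])
  }
  if ("db_label" %in% names(tab)) {
    tab$db_label <- ifelse(normalize_call(tab$db_label) == "negative",
                           "non_amyloid", "amyloid")
    tab$origin <- "other"
    tab$subset <- if (name == "reference_set") "reference" else "test"
  }
  if ("consensus_ir_pct" %in% names(tab)) {
    tab$consensus_ir_pct <- as.numeric(tab$consensus_ir_pct)
  }
  tab
}

#' Long-format method calls from a predictor fixture
#'
#' Melts a predictor fixture into one row per (peptide, method) pair — the
#' canonical method-call form used by the concordance functions.
#'
#' @param name `"predictor_calls_reference"` or `"predictor_calls_test"`.
#' @return data frame with columns `peptide_id`, `method`, `call`.
#' @export
method_calls_long <- function(name) {
  tab <- load_fixture(name)
  methods <- intersect(c("ir_microscopy", .amylir_methods), names(tab))
  out <- do.call(rbind, lapply(methods, function(m) {
    data.frame(peptide_id = tab$id, method = m, call = tab[[m]],
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(out[c("peptide_id", "method")])) {
    stop("duplicate (peptide, method) pair in fixture")
  }
  out
}
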