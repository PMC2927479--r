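#' Read a delimited table of birth records
#'
#' Reads a comma- or tab-delimited text file with a header and returns the
#' mapped birthweight and gestational-age columns. Blank or non-numeric
#' gestational ages become missing; rows with malformed birthweights are
#' rejected (their count is reported). The delimiter is sniffed from the
#' header line unless given.
#'
#' @param path Path to a delimited text file with a header row.
#' @param birthweight,gestational_age Names of the columns holding
#'   birthweight (grams) and gestational age (completed weeks).
#' @param delim Field delimiter; `NULL` (default) sniffs `","` vs `"\t"`.
#' @return A tibble with columns `birthweight` (numeric) and
#'   `gestational_age` (numeric, `NA` when unknown).
#' @export
read_birth_table <- function(path, birthweight = "birthweight",
                             gestational_age = "gestational_age", delim = NULL) {
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- read.table(path, header = TRUE, sep = delim, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = character(0))
  for (col in c(birthweight, gestational_age)) {
    if (!col %in% names(raw)) abort(sprintf("Mapped column '%s' not found in '%s'.", col, path))
  }
  bw <- suppressWarnings(as.numeric(raw[[birthweight]]))
  ga <- suppressWarnings(as.numeric(raw[[gestational_age]]))
  bad <- !is.finite(bw)
  if (any(bad)) {
    message(sprintf("Rejected %d row(s) with malformed birthweight.", sum(bad)))
  }
  tibble::tibble(birthweight = bw[!bad], gestational_age = ga[!bad])
}

#' Apply the eligibility filter to birth records
#'
#' Keeps records with a known gestational age of at least `min_gestation`
#' completed weeks and a birthweight inside the window (bounds inclusive:
#' a 500 g or 5500 g birthweight is retained). Records with missing
#' gestational age are excluded — the criterion requires a *known* age. The
#' counts removed by each rule are reported. The filter is idempotent.
#'
#' @param records A data frame with columns `birthweight` and
#'   `gestational_age` (e.g. from [read_birth_table()]).
#' @param window A [trunc_window()] for the birthweight range.
#' @param min_gestation Minimum gestational age in completed weeks.
#' @return A tibble with the single column `birthweight` of eligible records.
#' @export
apply_eligibility_filter <- function(records, window = trunc_window(),
                                     min_gestation = 22) {
  if (!all(c("birthweight", "gestational_age") %in% names(records))) {
    abort("`records` must have columns 'birthweight' and 'gestational_age'.")
  }
  ga_known <- !is.na(records$gestational_age)
  ga_ok <- ga_known & records$gestational_age >= min_gestation
  bw_ok <- records$birthweight >= window[["lower"]] &
    records$birthweight <= window[["upper"]]
  keep <- ga_ok & bw_ok
  message(sprintf(
    "Eligibility filter: %d of %d record(s) kept (%d missing gestational age, %d below %g weeks, %d outside [%g, %g] g).",
    sum(keep), nrow(records), sum(!ga_known), sum(ga_known & !ga_ok),
    min_gestation, sum(!bw_ok), window[["lower"]], window[["upper"]]))
  if (!any(keep)) abort("No records survive the eligibility filter.")
  tibble::tibble(birthweight = records$birthweight[keep])
}
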