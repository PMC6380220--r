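#' Worked examples of archived PubChem discrepancies
#'
#' Returns the bundled worked-example table: InChI strings and archived
#' formulas for six public PubChem records (CIDs 91929631, 91124997,
#' 12300268, 2179800, 1551886, 130156427) that illustrate the charge,
#' connectivity and stereochemistry discrepancy mechanisms the audit
#' detects. For each cid the table may carry a structure-`derived_inchi`,
#' a `deposited_inchi` as archived, and an `archived_formula`.
#'
#' @return data.frame with columns `cid`, `field`, `value`.
#' @export
worked_examples <- function() {
  utils::read.csv(
    system.file("extdata", "pubchem_examples.csv", package = "inchiaudit"),
    colClasses = "character"
  )
}

example_value <- function(examples, cid, field) {
  v <- examples$value[examples$cid == cid & examples$field == field]
  if (length(v) != 1L) stop("no unique example for cid ", cid, " field ",
                            field, call. = FALSE)
  v
}
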