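#' Reference microtissue summary statistics for the two platforms
#'
#' Published per-(platform, day) summary statistics of microtissue size
#' distributions and empty-microwell percentages over a 21-day
#' differentiation: identified microtissues, theoretical microwells per
#' well, empty/filled percentages, mean volume per microtissue (mm^3),
#' D10/D50/D90 cutoffs (mm^3), span and predicted tissue volume per well
#' (mm^3). Values are printed at 2-4 decimals; recomputing span and
#' predicted volume from these rounded columns reproduces the printed
#' values to within a few percent, which the test suite checks.
#'
#' @return Data frame with one row per (platform, day).
#' @export
platform_summary_reference <- function() {
  read.csv(system.file("extdata", "platform_summary_reference.csv",
                       package = "microwellr"),
           stringsAsFactors = FALSE)
}
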