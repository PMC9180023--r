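# Packaged reference data.

#' Published within-zone contribution reference table
#'
#' The yearly within-zone (intra-regional) contribution rates, in
#' percent, of the Theil decomposition for China's rural three-tier
#' system, 2003-2020, as published: one column per valid tier-kind
#' combination. The yearly rows are packaged; the mean row is what
#' [format_contribution_table()] appends, so this table doubles as the
#' worked example for the contribution formatter.
#'
#' @return A tibble: `year` (2003-2020) plus eight percentage columns.
#' @examples
#' tail(format_contribution_table(reference_contribution_table()), 1)
#' @export
reference_contribution_table <- function() {
  path <- system.file("extdata", "intra_contribution_reference.csv",
                      package = "equipanel", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
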