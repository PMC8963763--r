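# Access to the reference tables shipped with the package.

#' Reference tables from the original study cohorts
#'
#' Small plain-text tables distributed with the package, taken from the
#' published summary tables of the cervical-cancer chemoradiotherapy study
#' the pipeline is modelled on. They serve as fixed inputs for worked
#' examples and cross-checks; the underlying raw arrays are not publicly
#' deposited, so these printed summaries are the only recoverable layer.
#'
#' * `"md"` — the 13 discovery-cohort marker candidates and their
#'   gene-level median differences (MD), all above the 1.4 cutoff.
#' * `"contingency"` — validation-cohort counts of MSP status (M/HM/U)
#'   against stage and tumour-size groups for the three panel genes.
#' * `"msp_frequencies"` — validation-cohort MSP status counts per
#'   response group for the three panel genes.
#' * `"densities"` — reported promoter CpG densities of the panel genes
#'   (percent). These stem from an external island-annotation tool whose
#'   parameters and coordinates are not recoverable, so they are inputs
#'   here, never a target the package tries to reproduce.
#'
#' @param which One of `"md"`, `"contingency"`, `"msp_frequencies"`,
#'   `"densities"`.
#' @return A tibble.
#' @export
#' @examples
#' reference_table("md")
reference_table <- function(which = c("md", "contingency",
                                      "msp_frequencies", "densities")) {
  which <- match.arg(which)
  file <- c(
    md = "reference_md_table.tsv",
    contingency = "reference_contingency_tables.tsv",
    msp_frequencies = "reference_msp_frequencies.tsv",
    densities = "reference_cpg_densities.tsv"
  )[[which]]
  path <- system.file("extdata", file, package = "methcascade",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}
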