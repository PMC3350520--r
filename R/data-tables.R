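#' Published counter-regulation worked example (fat tissue)
#'
#' Signed fold changes of the top genes counter-regulated by two curative
#' treatments (alpha-1 antitrypsin, "AAT", and the "Power Mix" regimen) in
#' fat of new-onset diabetic NOD mice: disease vs normal fold change and the
#' two treatment-vs-disease fold changes, as printed (rounded to one decimal)
#' in the source study's published table. All rows belong to the study's
#' counter-regulated gene set (|FC| > 2, p < 0.05, opposite sign for both
#' treatments at full precision). 29 of the 30 published rows were
#' recoverable from the article text.
#'
#' @return data.frame with columns `symbol`, `gene_name`, `fc_diabetes`,
#'   `fc_aat`, `fc_powermix`.
#' @export
counterreg_example_table <- function() {
  path <- system.file("extdata", "table1_counterreg_fat.tsv",
                      package = "counterhub", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
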