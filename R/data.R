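#' Published anchor protein concentrations
#'
#' The reference table of SIL-quantified anchor protein concentrations in
#' Clostridium autoethanogenum chemostat cultures grown on CO, syngas, or
#' high-H2 CO (mean and standard deviation over biological replicate
#' cultures, nmol/gDCW; two protein-condition entries are `NQ`, excluded by
#' the replicate-variation rule). Used as a worked reference for the
#' replicate-CV quality summary.
#'
#' @return `data.frame` with `protein_id`, `name`, `condition`, `mean`,
#'   `sd`, `n_peptides`, `status`.
#' @export
anchor_reference_table <- function() {
  read_table_checked(system.file("extdata",
                                 "anchor_protein_concentrations.tsv",
                                 package = "anchorlfq"),
                     c("protein_id", "condition", "mean", "sd", "status"))
}
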