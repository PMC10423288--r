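# Published reference tables from the original 47-pearl monitoring
# campaign, shipped as plain CSVs. Used to check that the package's metric
# arithmetic reproduces the printed values exactly.

#' Reference per-class F1 table
#'
#' Per-class F1 scores and macro-average F1 reported for the four dataset
#' variants (day, week, month, full) of the original monitoring campaign.
#'
#' @return data frame with columns `dataset`, `f1_other`, `f1_atypical`,
#'   `f1_round`, `macro_f1`.
#' @export
reference_f1_table <- function() {
  utils::read.csv(system.file("extdata", "shape_f1_reference.csv",
                              package = "pearlrot"))
}

#' Reference graft-survival counts
#'
#' One-month nucleus-retention counts by nucleus quality for the three
#' grafting experiments (a, b, c) of the original campaign, with the printed
#' percent-alive column.
#'
#' @return data frame with columns `experiment`, `label`, `n_grafted`,
#'   `percent_alive`, `n_remaining`.
#' @export
reference_survival_table <- function() {
  utils::read.csv(system.file("extdata", "graft_survival_reference.csv",
                              package = "pearlrot"))
}
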