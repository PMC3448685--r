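#' Published reference summary tables
#'
#' Two plain-text summary tables from a published genome-wide monocyte
#' interaction scan ship with the package as validation inputs:
#' `reference_interaction_table()` returns the 51 genome-wide
#' significant miSNP x 3utrSNP interactions (interaction p, Levene q,
#' weighted p per row), and `reference_utr_histogram()` the per-gene
#' distribution of 3utrSNPs (or proxies) over the 6,147 genes entering
#' that scan. They are used to validate the weighted-Bonferroni
#' arithmetic against printed numbers, not as analysis inputs.
#'
#' @return data frames; see column headers in
#'   `inst/extdata/*.tsv`.
#' @export
reference_interaction_table <- function() {
  utils::read.delim(system.file("extdata", "interaction_scan_reference.tsv",
                                package = "misnpscan"),
                    stringsAsFactors = FALSE)
}

#' @rdname reference_interaction_table
#' @export
reference_utr_histogram <- function() {
  utils::read.delim(system.file("extdata", "utr_snp_per_gene_histogram.tsv",
                                package = "misnpscan"),
                    stringsAsFactors = FALSE)
}

#' Calibrate and apply the log-Levene weight scale on a summary table
#'
#' On a published summary table the standardized weight of each row is
#' recoverable as `w = (P / P*)`; under the weighting scheme
#' `w = c * (-log10 q)` with a single normalization constant `c` shared
#' by all rows of the scan. This function calibrates `c` on one row and
#' predicts every other row's weighted p-value, which checks the
#' functional form of the weights against printed numbers.
#'
#' @param tab data frame with columns `p`, `levene_q`, `weighted_p`
#'   (e.g. [reference_interaction_table()]).
#' @param calibration_row row index used to estimate `c`.
#' @return list with `c` (the calibrated constant), `predicted_weighted_p`,
#'   `relative_error` against the table's weighted p, and `ratio`
#'   (`(P/P*) / (-log10 q)` per row, constant under the scheme).
#' @export
calibrate_weight_scale <- function(tab, calibration_row = 1) {
  stopifnot(all(c("p", "levene_q", "weighted_p") %in% names(tab)))
  neglog_q <- -log10(tab$levene_q)
  w_obs <- tab$p / tab$weighted_p
  ratio <- w_obs / neglog_q
  c_hat <- ratio[calibration_row]
  pred <- tab$p / (c_hat * neglog_q)
  list(c = c_hat,
       predicted_weighted_p = pred,
       relative_error = abs(pred - tab$weighted_p) / tab$weighted_p,
       ratio = ratio)
}
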