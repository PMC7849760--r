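#' Published national aggregates: Poland 2018 analgesic pDDI screen
#'
#' The published aggregate results of the 2018 national screen of reimbursed
#' dispensations (38,413,139 population denominator): the rule ×
#' months-of-persistence case histogram and the per-rule same-prescriber
#' attribution columns. These aggregates are mutually consistent (per rule,
#' Σ m·counts\[m\] equals the published patient-month count) and serve as the
#' reference input for fixture expansion and for validating the statistics
#' layer.
#'
#' @return List: `histogram` (9 × 12 count matrix, rule IDs as rownames),
#'   `histogram_rules` (row order), `attribution` (data.table: `rule_id`,
#'   `n_cases`, `pct_cases_same_prescriber`, `n_patient_months`,
#'   `pct_patient_months_same_prescriber`), `population`, `window` (the
#'   2018 calendar year).
#' @examples
#' ref <- poland_analgesic_2018()
#' sum(ref$histogram)        # 2,485,787 cases
#' @export
poland_analgesic_2018 <- function() {
  pdir <- system.file("extdata", package = "pddiscreen", mustWork = TRUE)
  hist_dt <- fread(file.path(pdir, "poland-2018-persistence.csv"))
  histogram <- as.matrix(hist_dt[, -1])
  rownames(histogram) <- hist_dt$rule_id
  colnames(histogram) <- seq_len(ncol(histogram))
  attribution <- fread(file.path(pdir, "poland-2018-attribution.csv"))
  list(histogram = histogram,
       histogram_rules = hist_dt$rule_id,
       attribution = attribution,
       population = 38413139,
       window = study_window("2018-01", "2018-12", population = 38413139))
}
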