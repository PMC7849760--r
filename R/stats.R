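#' @title Prevalence, persistence and attribution statistics
#' @name stats_module
#' @description Aggregates cases into the study's reporting shapes: a rule ×
#'   months-count histogram with population percentages; per-rule persistence
#'   means with normal-approximation 95% confidence intervals; per-rule and
#'   overall same-prescriber attribution; and a Kruskal-Wallis test of
#'   persistence across rules. All accumulation is at full precision;
#'   rounding happens only in display/export helpers.
NULL

#' Construct a persistence histogram object
#'
#' The central aggregate: per rule, `counts[m]` cases whose interaction was
#' present in exactly `m` calendar months of the window.
#'
#' @param counts Integer matrix, rules in rows (rownames = rule IDs), month
#'   counts 1..window length in columns.
#' @param population Population denominator for prevalence percentages.
#' @return A `pddi_persistence_table`: list with `counts`, `rule_ids`,
#'   `n_months_max`, `population`, `rule_totals`, `grand_total`.
#' @export
persistence_histogram <- function(counts, population = 38413139) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts needs rule IDs as rownames")
  if (any(counts < 0)) stop("negative counts")
  storage.mode(counts) <- "double"   # totals can exceed .Machine$integer.max
  colnames(counts) <- seq_len(ncol(counts))
  structure(list(counts = counts,
                 rule_ids = rownames(counts),
                 n_months_max = ncol(counts),
                 population = as.numeric(population),
                 rule_totals = rowSums(counts),
                 grand_total = sum(counts)),
            class = "pddi_persistence_table")
}

#' Tabulate case persistence per rule
#'
#' Builds the rule × months-count histogram from detected cases.
#'
#' @param cases Output of [build_cases()].
#' @param window A `pddi_window` (its length caps the histogram and its
#'   population feeds the prevalence percentages).
#' @param rule_ids Optional rule ordering; defaults to the rules present.
#' @return A `pddi_persistence_table`.
#' @export
persistence_table <- function(cases, window, rule_ids = NULL) {
  stopifnot(inherits(window, "pddi_window"))
  W <- window$n_months
  if (is.null(rule_ids)) rule_ids <- sort(unique(cases$rule_id))
  if (nrow(cases) && any(cases$n_months > W))
    stop("case persists longer than the study window", call. = FALSE)
  counts <- matrix(0, nrow = length(rule_ids), ncol = W,
                   dimnames = list(rule_ids, NULL))
  if (nrow(cases)) {
    tab <- cases[, .(count = .N), by = .(rule_id, n_months)]
    tab <- tab[rule_id %in% rule_ids]
    counts[cbind(match(tab$rule_id, rule_ids), tab$n_months)] <- tab$count
  }
  persistence_histogram(counts, population = window$population)
}

#' @export
print.pddi_persistence_table <- function(x, ...) {
  cat("<pddi_persistence_table> ", length(x$rule_ids), " rules x ",
      x$n_months_max, " months; total cases ",
      format(x$grand_total, big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Persistence histogram as a display data frame
#'
#' One row per rule plus a TOTAL row; counts and population percentages
#' (rounded to 2 decimals) per months-count column.
#'
#' @param ptab A `pddi_persistence_table`.
#' @return data.table in the published-table shape.
#' @export
persistence_table_df <- function(ptab) {
  counts <- rbind(ptab$counts, TOTAL = colSums(ptab$counts))
  cols <- list(rule_id = rownames(counts))
  for (m in seq_len(ncol(counts))) {
    cols[[paste0("m", m)]] <- counts[, m]
    cols[[paste0("pct", m)]] <- round(100 * counts[, m] / ptab$population, 2)
  }
  cols$total <- rowSums(counts)
  cols$total_pct <- round(100 * rowSums(counts) / ptab$population, 2)
  as.data.table(cols)
}

#' Persistence means with 95% confidence intervals
#'
#' Persistence of an interaction is the mean number of window months its
#' cases were present. The interval is the normal approximation
#' mean ± 1.96·s/√n with `s` the sample standard deviation of the per-case
#' month counts, computed exactly from the grouped histogram.
#'
#' @param ptab A `pddi_persistence_table`.
#' @return data.table per rule with ≥1 case: `rule_id`, `n_cases`,
#'   `mean_months`, `sd_months`, `ci_low`, `ci_high`, `patient_months`
#'   (Σ m·counts\[m\]). Rules with zero cases are omitted with a warning.
#' @export
persistence_summary <- function(ptab) {
  stopifnot(inherits(ptab, "pddi_persistence_table"))
  m <- seq_len(ptab$n_months_max)
  rows <- lapply(seq_along(ptab$rule_ids), function(i) {
    cnt <- ptab$counts[i, ]
    n <- sum(cnt)
    if (n == 0) return(NULL)
    mu <- sum(m * cnt) / n
    s2 <- if (n > 1) (sum(m^2 * cnt) - n * mu^2) / (n - 1) else 0
    s2 <- max(s2, 0)                       # guard fp cancellation
    se <- sqrt(s2 / n)
    data.table(rule_id = ptab$rule_ids[i], n_cases = n, mean_months = mu,
               sd_months = sqrt(s2), ci_low = mu - 1.96 * se,
               ci_high = mu + 1.96 * se, patient_months = sum(m * cnt))
  })
  empty <- ptab$rule_ids[rowSums(ptab$counts) == 0]
  if (length(empty))
    warning("omitting rule(s) with zero cases: ", paste(empty, collapse = ", "),
            call. = FALSE)
  out <- rbindlist(rows)
  if (nrow(out) == 0)
    out <- data.table(rule_id = character(), n_cases = numeric(),
                      mean_months = numeric(), sd_months = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      patient_months = numeric())
  out
}

#' Headline prevalence numbers
#'
#' Case counts divided by the population denominator, per rule and overall,
#' plus each rule's share of all cases and the short-persistence shares
#' (cases present in exactly one month, and in at most three months). Note
#' the headline percentage divides cases — (patient, rule) pairs — by the
#' population, so a patient with two interaction types counts twice; the
#' unique-patient prevalence is reported separately when patient identities
#' are supplied.
#'
#' @param ptab A `pddi_persistence_table`.
#' @param n_unique_patients Optional count of distinct patients across all
#'   cases, for the unique-patient prevalence.
#' @return List: `total_cases`, `pct_population_total`, per-rule data.table
#'   (`rule_id`, `n_cases`, `pct_population`, `pct_of_all_cases`),
#'   `pct_cases_single_month`, `pct_cases_up_to_3_months`,
#'   `n_unique_patients`, `pct_population_unique_patients`.
#' @export
prevalence_summary <- function(ptab, n_unique_patients = NA_real_) {
  stopifnot(inherits(ptab, "pddi_persistence_table"))
  tot <- ptab$grand_total
  per_rule <- data.table(
    rule_id = ptab$rule_ids,
    n_cases = ptab$rule_totals,
    pct_population = 100 * ptab$rule_totals / ptab$population,
    pct_of_all_cases = if (tot > 0) 100 * ptab$rule_totals / tot else NA_real_)
  by_m <- colSums(ptab$counts)
  list(total_cases = tot,
       pct_population_total = 100 * tot / ptab$population,
       per_rule = per_rule,
       pct_cases_single_month = if (tot > 0) unname(100 * by_m[1] / tot) else NA_real_,
       pct_cases_up_to_3_months =
         if (tot > 0) 100 * sum(by_m[seq_len(min(3, length(by_m)))]) / tot else NA_real_,
       n_unique_patients = n_unique_patients,
       pct_population_unique_patients = 100 * n_unique_patients / ptab$population)
}

#' Same-prescriber attribution summary
#'
#' Per rule: how many cases, and how many flagged patient-months, were
#' co-prescribed (both conflicting drugs from one prescriber). The overall
#' means are weighted — by cases for the case percentage and by
#' patient-months for the month percentage.
#'
#' @param cases Output of [build_cases()].
#' @return data.table per rule (`rule_id`, `n_cases`,
#'   `n_cases_same_prescriber`, `pct_cases_same_prescriber`,
#'   `n_patient_months`, `n_patient_months_same_prescriber`,
#'   `pct_patient_months_same_prescriber`) with attributes
#'   `case_weighted_mean_pct` and `month_weighted_mean_pct`.
#' @export
attribution_summary <- function(cases) {
  out <- cases[, .(
    n_cases = .N,
    n_cases_same_prescriber = sum(case_co_prescribed),
    n_patient_months = sum(n_months),
    n_patient_months_same_prescriber = sum(patient_months_co_prescribed)),
    by = rule_id]
  out[, `:=`(pct_cases_same_prescriber = 100 * n_cases_same_prescriber / n_cases,
             pct_patient_months_same_prescriber =
               100 * n_patient_months_same_prescriber / n_patient_months)]
  setorder(out, rule_id)
  wm <- attribution_weighted_means(out$n_cases, out$pct_cases_same_prescriber,
                                   out$n_patient_months,
                                   out$pct_patient_months_same_prescriber)
  setattr(out, "case_weighted_mean_pct", wm$case_weighted)
  setattr(out, "month_weighted_mean_pct", wm$month_weighted)
  out[]
}

#' Weighted overall attribution means
#'
#' Overall same-prescriber percentages from per-rule columns: the case
#' percentage weighted by case counts and the patient-month percentage
#' weighted by patient-month counts. (An unweighted mean of the per-rule
#' percentages is a different, smaller number for these data.)
#'
#' @param n_cases,pct_cases Per-rule case counts and same-prescriber case
#'   percentages (0..100).
#' @param n_patient_months,pct_patient_months Per-rule patient-month counts
#'   and same-prescriber month percentages.
#' @return List with `case_weighted` and `month_weighted` percentages.
#' @export
attribution_weighted_means <- function(n_cases, pct_cases,
                                       n_patient_months, pct_patient_months) {
  list(case_weighted = sum(n_cases * pct_cases) / sum(n_cases),
       month_weighted = sum(n_patient_months * pct_patient_months) /
         sum(n_patient_months))
}

#' Kruskal-Wallis test of persistence across rules
#'
#' Tests whether the distribution of per-case month counts differs across
#' rules (tie-corrected H, chi-square approximation with groups − 1 degrees
#' of freedom, as in [stats::kruskal.test()]). Accepts either a case table or
#' a persistence histogram; the histogram form expands the grouped counts.
#'
#' @param x Output of [build_cases()], or a `pddi_persistence_table`.
#' @return An object of class `htest` (statistic, df, p-value).
#' @export
kruskal_wallis_persistence <- function(x) {
  if (inherits(x, "pddi_persistence_table")) {
    keep <- x$rule_totals > 0
    counts <- x$counts[keep, , drop = FALSE]
    values <- rep(rep(seq_len(ncol(counts)), nrow(counts)), as.vector(t(counts)))
    groups <- rep(rownames(counts), rowSums(counts))
  } else {
    values <- x$n_months
    groups <- x$rule_id
  }
  if (length(unique(groups)) < 2)
    stop("Kruskal-Wallis needs at least 2 rules with cases", call. = FALSE)
  kruskal.test(values, factor(groups))
}
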