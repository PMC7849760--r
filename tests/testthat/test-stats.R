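ref <- poland_analgesic_2018()
ref_ptab <- persistence_histogram(ref$histogram, population = ref$population)

test_that("persistence_table builds the exact per-rule histogram", {
  cases <- data.table(
    patient_id = c("a", "b", "c"), rule_id = "r1",
    n_months = c(1L, 1L, 4L), months = "x",
    case_co_prescribed = FALSE, patient_months_co_prescribed = 0L)
  pt <- persistence_table(cases, window_2018)
  expect_equal(unname(pt$counts["r1", ]), c(2, 0, 0, 1, rep(0, 8)))
  expect_equal(pt$rule_totals[["r1"]], 3)
  expect_error(persistence_table(cases, study_window("2018-01", "2018-02")),
               "longer than the study window")
})

test_that("population percentages use the national denominator", {
  prev <- prevalence_summary(ref_ptab)
  expect_equal(round(prev$pct_population_total, 2), 6.47)
  expect_equal(prev$total_cases, 2485787)
  pr <- prev$per_rule
  expect_equal(round(pr[rule_id == "nsaid_antihypertensive", pct_population], 2), 4.12)
  expect_equal(round(pr[rule_id == "nsaid_nsaid", pct_population], 2), 1.40)
  expect_equal(round(pr[rule_id == "nsaid_gc", pct_population], 2), 0.56)
})

test_that("persistence means and normal-approximation CIs match published values", {
  ps <- persistence_summary(ref_ptab)
  get <- function(rid) ps[rule_id == rid]
  r <- get("nsaid_nsaid")
  expect_equal(round(r$mean_months, 2), 1.23)
  expect_equal(round(c(r$ci_low, r$ci_high), 2), c(1.23, 1.24))
  r <- get("nsaid_antihypertensive")
  expect_equal(round(r$mean_months, 2), 1.83)
  expect_equal(round(c(r$ci_low, r$ci_high), 2), c(1.83, 1.84))
  r <- get("opioid_gabapentinoid")
  expect_equal(round(r$mean_months, 2), 2.19)
  expect_equal(round(c(r$ci_low, r$ci_high), 2), c(2.16, 2.22))
  r <- get("tramadol_ssri_snri")
  expect_equal(round(r$mean_months, 2), 2.15)
  expect_equal(round(c(r$ci_low, r$ci_high), 2), c(1.96, 2.33))
})

test_that("a rule with zero variance gets a zero-width interval", {
  pt <- persistence_histogram(matrix(c(5, rep(0, 11)), nrow = 1,
                                     dimnames = list("r1", NULL)))
  ps <- persistence_summary(pt)
  expect_equal(ps$mean_months, 1)
  expect_equal(ps$ci_low, 1)
  expect_equal(ps$ci_high, 1)
})

test_that("rules without cases are omitted with a warning", {
  pt <- persistence_histogram(rbind(r1 = c(2, 1), r2 = c(0, 0)))
  expect_warning(ps <- persistence_summary(pt), "r2")
  expect_equal(ps$rule_id, "r1")
})

test_that("per-rule patient-months equal the published attribution column", {
  ps <- persistence_summary(ref_ptab)
  merged <- merge(ps[, .(rule_id, patient_months)],
                  ref$attribution[, .(rule_id, n_patient_months)], by = "rule_id")
  expect_equal(merged$patient_months, as.double(merged$n_patient_months))
  expect_equal(ps[rule_id == "nsaid_antihypertensive", patient_months], 2903210)
  expect_equal(sum(ps$patient_months), 4123128)
})

test_that("attribution summarizes cases and weights the overall means", {
  cases <- data.table(
    patient_id = c("a", "b"), rule_id = "r1", n_months = c(2L, 1L),
    months = "x", case_co_prescribed = c(TRUE, FALSE),
    patient_months_co_prescribed = c(1L, 0L))
  at <- attribution_summary(cases)
  expect_equal(at$pct_cases_same_prescriber, 50)
  expect_equal(at$n_patient_months, 3L)
  expect_equal(at$pct_patient_months_same_prescriber, 100 / 3)

  wm <- attribution_weighted_means(
    ref$attribution$n_cases, ref$attribution$pct_cases_same_prescriber,
    ref$attribution$n_patient_months,
    ref$attribution$pct_patient_months_same_prescriber)
  expect_equal(round(wm$case_weighted, 2), 76.63)
  expect_equal(round(wm$month_weighted, 1), 78.7)
  # weighted means sit inside the per-rule range
  expect_gte(wm$case_weighted, min(ref$attribution$pct_cases_same_prescriber))
  expect_lte(wm$case_weighted, max(ref$attribution$pct_cases_same_prescriber))
})

test_that("the persistence mean pools over arbitrary batch splits", {
  set.seed(4)
  cases <- data.table(patient_id = sprintf("p%d", 1:500), rule_id = "r1",
                      n_months = sample(1:12, 500, TRUE, prob = 12:1),
                      months = "x", case_co_prescribed = FALSE,
                      patient_months_co_prescribed = 0L)
  full <- persistence_summary(persistence_table(cases, window_2018))
  idx <- sample(rep(1:3, length.out = 500))
  parts <- lapply(1:3, function(k)
    persistence_summary(persistence_table(cases[idx == k], window_2018)))
  pooled <- sum(vapply(parts, function(p) p$mean_months * p$n_cases, 0)) /
    sum(vapply(parts, function(p) p$n_cases, 0))
  expect_equal(pooled, full$mean_months)
})

test_that("Kruskal-Wallis matches a hand-ranked oracle and symmetry limits", {
  # {1,1,1,1} vs {3,3,3,3}: ranks 2.5 and 6.5; uncorrected H = 16/3,
  # tie correction 1 - 120/504 -> H = 7 exactly
  cases <- data.table(patient_id = sprintf("p%d", 1:8),
                      rule_id = rep(c("a", "b"), each = 4),
                      n_months = rep(c(1L, 3L), each = 4), months = "x",
                      case_co_prescribed = FALSE, patient_months_co_prescribed = 0L)
  kw <- kruskal_wallis_persistence(cases)
  expect_equal(unname(kw$statistic), 7)
  expect_equal(unname(kw$parameter), 1)

  sym <- data.table(patient_id = sprintf("p%d", 1:8),
                    rule_id = rep(c("a", "b"), each = 4),
                    n_months = rep(c(1L, 2L, 3L, 4L), 2), months = "x",
                    case_co_prescribed = FALSE, patient_months_co_prescribed = 0L)
  kw0 <- kruskal_wallis_persistence(sym)
  expect_equal(unname(kw0$statistic), 0)
  expect_equal(kw0$p.value, 1)

  one <- cases[rule_id == "a"]
  expect_error(kruskal_wallis_persistence(one), "at least 2")
})

test_that("the histogram route to Kruskal-Wallis equals the case route", {
  set.seed(12)
  cases <- data.table(
    patient_id = sprintf("p%d", 1:300),
    rule_id = sample(c("a", "b", "c"), 300, TRUE),
    n_months = sample(1:12, 300, TRUE, prob = c(6, 3, rep(0.5, 10))),
    months = "x", case_co_prescribed = FALSE, patient_months_co_prescribed = 0L)
  via_cases <- kruskal_wallis_persistence(cases)
  via_hist <- kruskal_wallis_persistence(persistence_table(cases, window_2018))
  expect_equal(unname(via_hist$statistic), unname(via_cases$statistic))
  expect_equal(via_hist$p.value, via_cases$p.value)
})
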