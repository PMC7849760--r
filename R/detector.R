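#' @title Same-calendar-month co-dispensation screening
#' @name detector
#' @description The screening engine. A potential drug-drug interaction is
#'   deemed present for a patient in a calendar month iff that month contains
#'   a dispensation from each side of an interaction rule, subject to the
#'   rule's conditions (distinct substances for self-pairs; a minimum daily
#'   dose on side A where set). Each flagged patient-month records the number
#'   of qualifying substance pairs, the smallest day gap between the two
#'   dispensations, and whether some qualifying pair came from one prescriber.
NULL

#' Flag patient-months satisfying interaction rules
#'
#' For every (patient, calendar month, rule) combination, emits a flag iff the
#' month holds a dispensation `a` with class on the rule's side A and a
#' dispensation `b` with class on side B such that (i) `a` and `b` are
#' different substances when the rule requires it, and (ii) `a`'s daily dose
#' meets the rule's threshold when one is set. Records outside the study
#' window, and drugs outside the catalog, are ignored. An empty (unknown)
#' prescriber ID never matches any prescriber, so pairs with unknown
#' prescribers count as multi-prescriber.
#'
#' @param claims Canonical claims data.table (see [read_claims()]).
#' @param ruleset A `pddi_ruleset`.
#' @param window A `pddi_window`.
#' @return data.table with one row per flagged patient-month and rule:
#'   `patient_id`, `rule_id`, `year`, `month`, `co_prescribed` (some
#'   qualifying pair from one prescriber), `min_interval_days` (smallest
#'   absolute day gap over qualifying pairs; 0 if same-day), `n_pairs`
#'   (qualifying substance-pair count), sorted by rule, patient, month.
#' @examples
#' rs <- load_ruleset("default")
#' w <- study_window("2018-01", "2018-12")
#' claims <- data.table::data.table(
#'   patient_id = "p1",
#'   dispense_date = as.Date(c("2018-03-02", "2018-03-20")),
#'   drug_code = "", drug_name = c("ibuprofen", "ramipril"),
#'   prescriber_id = "drA", daily_dose_mg = NA_real_)
#' flag_months(claims, rs, w)
#' @export
flag_months <- function(claims, ruleset, window) {
  stopifnot(inherits(ruleset, "pddi_ruleset"), inherits(window, "pddi_window"))
  empty <- data.table(patient_id = character(), rule_id = character(),
                      year = integer(), month = integer(),
                      co_prescribed = logical(), min_interval_days = integer(),
                      n_pairs = integer())
  if (nrow(claims) == 0) return(empty)

  dt <- filter_window(claims, window)
  if (nrow(dt) == 0) return(empty)
  dt <- copy(dt)
  dt[, class_label := resolve_class(ruleset, drug_code, drug_name)]
  dt <- dt[!is.na(class_label)]
  if (nrow(dt) == 0) return(empty)
  mk <- month_of(dt$dispense_date)
  dt[, `:=`(year = mk$year, month = mk$month)]
  dt[, ym := .ym_index(year, month)]
  dt[, substance := resolve_substance(ruleset, drug_code, drug_name)]
  dt[, rid := .I]
  setkey(dt, patient_id, ym)

  out <- vector("list", length(ruleset$rules))
  for (k in seq_along(ruleset$rules)) {
    r <- ruleset$rules[[k]]
    a <- dt[class_label %in% r$side_a]
    if (!is.na(r$min_daily_dose_mg))
      a <- a[!is.na(daily_dose_mg) & daily_dose_mg >= r$min_daily_dose_mg]
    b <- dt[class_label %in% r$side_b]
    if (nrow(a) == 0 || nrow(b) == 0) next
    pairs <- a[, .(patient_id, ym, year, month, rid_a = rid, sub_a = substance,
                   day_a = dispense_date, pres_a = prescriber_id)][
      b[, .(patient_id, ym, rid_b = rid, sub_b = substance,
            day_b = dispense_date, pres_b = prescriber_id)],
      on = c("patient_id", "ym"), nomatch = NULL, allow.cartesian = TRUE]
    if (length(intersect(r$side_a, r$side_b)))
      pairs <- pairs[rid_a != rid_b]
    if (r$require_distinct_substance)
      pairs <- pairs[sub_a != sub_b]
    if (nrow(pairs) == 0) next
    flags <- pairs[, .(
      year = year[1L], month = month[1L],
      co_prescribed = any(nzchar(pres_a) & pres_a == pres_b),
      min_interval_days = as.integer(min(abs(as.integer(day_a - day_b)))),
      # a self-pair rule sees each unordered substance pair twice in the join
      n_pairs = if (setequal(r$side_a, r$side_b)) uniqueN(data.table(
        pmin(sub_a, sub_b), pmax(sub_a, sub_b))) else uniqueN(data.table(sub_a, sub_b))
    ), by = .(patient_id, ym)]
    flags[, rule_id := r$rule_id]
    out[[k]] <- flags[, .(patient_id, rule_id, year, month,
                          co_prescribed, min_interval_days, n_pairs)]
  }
  out <- rbindlist(out)
  if (nrow(out) == 0) return(empty)
  setorder(out, rule_id, patient_id, year, month)
  out[]
}

#' Aggregate month flags into cases
#'
#' A case is one (patient, rule) pair with at least one flagged month. The
#' case-level same-prescriber dichotomy is configurable: under the default
#' `"any"` policy a case counts as co-prescribed if any of its flagged months
#' is; `"all"` requires every month; `"majority"` requires more than half.
#'
#' @param flags Output of [flag_months()] from a single run.
#' @param policy Attribution policy: `"any"` (default), `"all"` or `"majority"`.
#' @return data.table with one row per case: `patient_id`, `rule_id`,
#'   `n_months` (distinct flagged months), `months` (semicolon-joined
#'   `YYYY-MM` keys), `case_co_prescribed`, `patient_months_co_prescribed`
#'   (count of co-prescribed months).
#' @export
build_cases <- function(flags, policy = c("any", "all", "majority")) {
  policy <- match.arg(policy)
  if (nrow(flags) == 0)
    return(data.table(patient_id = character(), rule_id = character(),
                      n_months = integer(), months = character(),
                      case_co_prescribed = logical(),
                      patient_months_co_prescribed = integer()))
  if (anyDuplicated(flags, by = c("patient_id", "rule_id", "year", "month")))
    stop("duplicate (patient, rule, month) flags: upstream detection bug",
         call. = FALSE)
  agg <- switch(policy,
    any = function(co) any(co),
    all = function(co) all(co),
    majority = function(co) sum(co) > length(co) / 2)
  cases <- flags[order(year, month),
    .(n_months = .N,
      months = paste(sprintf("%04d-%02d", year, month), collapse = ";"),
      case_co_prescribed = agg(co_prescribed),
      patient_months_co_prescribed = sum(co_prescribed)),
    by = .(patient_id, rule_id)]
  setorder(cases, rule_id, patient_id)
  cases[]
}
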