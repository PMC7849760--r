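#' @title Synthetic claims with ground truth
#' @name synthetic_data
#' @description Claims generators for validation. `simulate_claims()` plants
#'   interaction episodes with a configurable persistence distribution and
#'   co-prescribing probability, surrounded by background that can never
#'   qualify: single-substance dispensations, near-misses (a conflicting pair
#'   split across adjacent months), and sub-threshold tramadol. Generation is
#'   constructive — episodes are written directly, so the planted case count
#'   and month-count histogram are recovered exactly by the detector.
#'   `expand_histogram_fixture()` deterministically inverts a published
#'   rule × months-count histogram into claim-level records.
NULL

# largest-remainder apportionment of n into round(n * p) integer bins
apportion <- function(n, p) {
  if (abs(sum(p) - 1) > 1e-8) stop("distribution must sum to 1", call. = FALSE)
  raw <- n * p
  base <- floor(raw)
  extra <- round(sum(raw)) - sum(base)
  if (extra > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  as.integer(base)
}

#' Build a simulation configuration
#'
#' Defaults emulate the national 2018 screen at 1/1000 scale: per-rule planted
#' case counts and month-count distributions follow the published persistence
#' histogram, and the per-month co-prescribing probabilities follow the
#' published patient-month attribution percentages.
#'
#' @param seed Integer RNG seed.
#' @param window A `pddi_window`.
#' @param planted Named list (names = rule IDs). Each element: `n_cases`,
#'   `month_dist` (probability vector over 1..window months, sums to 1),
#'   `p_co_month` (probability a planted month is co-prescribed, 0..1).
#'   `NULL` selects the national-shape default above.
#' @param n_background_patients Patients carrying only non-qualifying noise.
#' @param background_rate Expected single-substance dispensations per
#'   background patient-month.
#' @param near_miss_rate,subthreshold_tramadol_rate Fractions of background
#'   patients given, respectively, a conflicting pair split across adjacent
#'   months and a sub-threshold-dose tramadol + SSRI/SNRI month.
#' @param scale Scale applied to the default planted case counts (ignored
#'   when `planted` is given).
#' @return A validated `pddi_sim_config` list.
#' @export
sim_config <- function(seed = 1L, window = study_window("2018-01", "2018-12"),
                       planted = NULL, n_background_patients = 500L,
                       background_rate = 0.3, near_miss_rate = 0.05,
                       subthreshold_tramadol_rate = 0.02, scale = 1 / 1000) {
  stopifnot(inherits(window, "pddi_window"))
  if (is.null(planted)) {
    ref <- poland_analgesic_2018()
    planted <- lapply(ref$histogram_rules, function(rid) {
      cnt <- ref$histogram[rid, ]
      list(n_cases = max(1L, as.integer(round(sum(cnt) * scale))),
           month_dist = cnt / sum(cnt),
           p_co_month = ref$attribution[rule_id == rid,
                                        pct_patient_months_same_prescriber] / 100)
    })
    names(planted) <- ref$histogram_rules
  }
  for (rid in names(planted)) {
    p <- planted[[rid]]
    if (is.null(p$n_cases) || p$n_cases < 0) stop(rid, ": bad n_cases")
    if (length(p$month_dist) != window$n_months ||
        abs(sum(p$month_dist) - 1) > 1e-8)
      stop(rid, ": month_dist must have one probability per window month and sum to 1",
           call. = FALSE)
    if (p$p_co_month < 0 || p$p_co_month > 1)
      stop(rid, ": p_co_month must lie in [0, 1]", call. = FALSE)
  }
  for (nm in c("near_miss_rate", "subthreshold_tramadol_rate"))
    if (get(nm) < 0 || get(nm) > 1) stop(nm, " must lie in [0, 1]", call. = FALSE)
  if (background_rate < 0) stop("background_rate must be >= 0", call. = FALSE)
  structure(list(seed = as.integer(seed), window = window, planted = planted,
                 n_background_patients = as.integer(n_background_patients),
                 background_rate = background_rate,
                 near_miss_rate = near_miss_rate,
                 subthreshold_tramadol_rate = subthreshold_tramadol_rate),
            class = "pddi_sim_config")
}

# expand a month-level plan (patient_id, rule_id, year, month, co) into two
# claim rows per month; assumes the RNG is already seeded by the caller
.claims_for_months <- function(plan, ruleset) {
  if (nrow(plan) == 0)
    return(data.table(patient_id = character(), dispense_date = as.Date(character()),
                      drug_code = character(), drug_name = character(),
                      prescriber_id = character(), daily_dose_mg = numeric()))
  rules <- setNames(ruleset$rules, vapply(ruleset$rules, `[[`, "", "rule_id"))
  out <- vector("list", length(unique(plan$rule_id)))
  i <- 0L
  for (rid in unique(plan$rule_id)) {
    r <- rules[[rid]]
    sub <- plan[rule_id == rid]
    n <- nrow(sub)
    roster_a <- class_roster(ruleset, r$side_a)
    roster_b <- class_roster(ruleset, r$side_b)
    ia <- sample.int(nrow(roster_a), n, replace = TRUE)
    if (r$require_distinct_substance && identical(roster_a$name, roster_b$name)) {
      # draw b from the roster minus a's pick
      ib <- sample.int(nrow(roster_b) - 1L, n, replace = TRUE)
      ib <- ib + (ib >= ia)
    } else {
      ib <- sample.int(nrow(roster_b), n, replace = TRUE)
    }
    ndays <- .days_in_month(sub$year, sub$month)
    day_a <- 1L + floor(runif(n) * ndays)
    day_b <- 1L + floor(runif(n) * ndays)
    pres_a <- paste0("D", sub$patient_id, "a")
    pres_b <- ifelse(sub$co, pres_a, paste0("D", sub$patient_id, "b"))
    dose_a <- if (!is.na(r$min_daily_dose_mg))
      rep(r$min_daily_dose_mg, n) else rep(NA_real_, n)
    mk_date <- function(day) as.Date(sprintf("%04d-%02d-%02d", sub$year, sub$month, day))
    i <- i + 1L
    out[[i]] <- rbind(
      data.table(patient_id = sub$patient_id, dispense_date = mk_date(day_a),
                 drug_code = roster_a$code[ia], drug_name = roster_a$name[ia],
                 prescriber_id = pres_a, daily_dose_mg = dose_a),
      data.table(patient_id = sub$patient_id, dispense_date = mk_date(day_b),
                 drug_code = roster_b$code[ib], drug_name = roster_b$name[ib],
                 prescriber_id = pres_b, daily_dose_mg = NA_real_))
  }
  rbindlist(out[seq_len(i)])
}

.days_in_month <- function(year, month) {
  first <- as.Date(sprintf("%04d-%02d-01", year, month))
  as.integer(format(seq(first, by = "month", length.out = 2)[2] - 1, "%d"))
}
# vectorized wrapper (seq() above is scalar)
.days_in_month <- function(year, month) {
  nd <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  out <- nd[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  out[month == 2L & leap] <- 29L
  out
}

#' Generate synthetic claims with a ground-truth sidecar
#'
#' @param config A `pddi_sim_config`.
#' @param ruleset A `pddi_ruleset` (default: the packaged rules).
#' @return List with `claims` (canonical claims data.table) and `truth`
#'   (per planted case: `patient_id`, `rule_id`, `n_months`,
#'   `case_co_prescribed`, `patient_months_co_prescribed`), both fully
#'   reproducible from `config$seed`.
#' @export
simulate_claims <- function(config, ruleset = load_ruleset("default")) {
  stopifnot(inherits(config, "pddi_sim_config"))
  w <- config$window
  ym0 <- .ym_index(w$start_year, w$start_month)
  with_seed(config$seed, {
    plans <- list(); truths <- list(); extras <- list()
    pid_counter <- 0L
    for (rid in names(config$planted)) {
      spec <- config$planted[[rid]]
      if (spec$n_cases == 0) next
      per_m <- apportion(spec$n_cases, spec$month_dist)     # cases per month-count
      n <- sum(per_m)
      m_of_case <- rep(seq_along(per_m), per_m)
      pids <- sprintf("S%07d", pid_counter + seq_len(n))
      pid_counter <- pid_counter + n
      # months per case: sampled without replacement from the window
      month_idx <- unlist(lapply(m_of_case, function(m) sample.int(w$n_months, m)))
      case_of_month <- rep(seq_len(n), m_of_case)
      ym <- ym0 + month_idx - 1L
      co <- runif(length(ym)) < spec$p_co_month
      plan <- data.table(patient_id = pids[case_of_month], rule_id = rid,
                         year = .ym_year(ym), month = .ym_month(ym), co = co)
      plans[[rid]] <- plan
      truths[[rid]] <- plan[, .(n_months = .N, case_co_prescribed = any(co),
                                patient_months_co_prescribed = sum(co)),
                            by = .(patient_id, rule_id)]
    }
    plan_all <- rbindlist(plans)
    claims <- .claims_for_months(plan_all, ruleset)

    # background patients: never form a qualifying same-month pair
    nb <- config$n_background_patients
    if (nb > 0) {
      bpids <- sprintf("B%07d", seq_len(nb))
      prof <- sample(c("near_miss", "subthreshold", "plain"), nb, replace = TRUE,
                     prob = c(config$near_miss_rate, config$subthreshold_tramadol_rate,
                              1 - config$near_miss_rate - config$subthreshold_tramadol_rate))
      extras <- list(
        .background_plain(bpids[prof == "plain"], config, ruleset),
        .background_near_miss(bpids[prof == "near_miss"], config, ruleset),
        .background_subthreshold(bpids[prof == "subthreshold"], config, ruleset))
      claims <- rbindlist(c(list(claims), extras), use.names = TRUE)
    }
    truth <- rbindlist(truths)
    if (nrow(truth)) setorder(truth, rule_id, patient_id)
    setorder(claims, patient_id, dispense_date, drug_name)
    list(claims = claims[], truth = truth)
  })
}

# one substance per patient; repeated fills can never qualify (every rule is
# cross-class or requires distinct substances)
.background_plain <- function(pids, config, ruleset) {
  if (!length(pids)) return(NULL)
  w <- config$window
  cat_n <- nrow(ruleset$catalog)
  ym0 <- .ym_index(w$start_year, w$start_month)
  rows <- list()
  n_events <- matrix(rpois(length(pids) * w$n_months, config$background_rate),
                     nrow = length(pids))
  idx <- which(n_events > 0, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  reps <- n_events[idx]
  pid <- rep(pids[idx[, 1]], reps)
  sub_i <- rep(sample.int(cat_n, length(pids), replace = TRUE)[idx[, 1]], reps)
  ym <- rep(ym0 + idx[, 2] - 1L, reps)
  year <- .ym_year(ym); month <- .ym_month(ym)
  day <- 1L + floor(runif(length(ym)) * .days_in_month(year, month))
  data.table(patient_id = pid,
             dispense_date = as.Date(sprintf("%04d-%02d-%02d", year, month, day)),
             drug_code = ruleset$catalog$code[sub_i],
             drug_name = ruleset$catalog$name[sub_i],
             prescriber_id = paste0("D", pid, "a"),
             daily_dose_mg = NA_real_)
}

# a genuinely conflicting pair, but split across adjacent months
.background_near_miss <- function(pids, config, ruleset) {
  if (!length(pids)) return(NULL)
  w <- config$window
  if (w$n_months < 2) return(NULL)
  rules <- ruleset$rules
  ri <- sample.int(length(rules), length(pids), replace = TRUE)
  ym0 <- .ym_index(w$start_year, w$start_month)
  m1 <- sample.int(w$n_months - 1L, length(pids), replace = TRUE)
  rows <- lapply(seq_along(pids), function(i) {
    r <- rules[[ri[i]]]
    ra <- class_roster(ruleset, r$side_a); rb <- class_roster(ruleset, r$side_b)
    a <- ra[sample.int(nrow(ra), 1)]
    b <- rb[sample.int(nrow(rb), 1)]
    if (r$require_distinct_substance) while (b$name == a$name)
      b <- rb[sample.int(nrow(rb), 1)]
    ya <- .ym_year(ym0 + m1[i] - 1L); ma <- .ym_month(ym0 + m1[i] - 1L)
    yb <- .ym_year(ym0 + m1[i]); mb <- .ym_month(ym0 + m1[i])
    data.table(
      patient_id = pids[i],
      dispense_date = as.Date(c(
        sprintf("%04d-%02d-%02d", ya, ma, 1L + floor(runif(1) * .days_in_month(ya, ma))),
        sprintf("%04d-%02d-%02d", yb, mb, 1L + floor(runif(1) * .days_in_month(yb, mb))))),
      drug_code = c(a$code, b$code), drug_name = c(a$name, b$name),
      prescriber_id = paste0("D", pids[i], "a"),
      daily_dose_mg = c(if (!is.na(r$min_daily_dose_mg)) r$min_daily_dose_mg
                        else NA_real_, NA_real_))
  })
  rbindlist(rows)
}

# tramadol below the high-dose threshold alongside an SSRI/SNRI: must not flag
.background_subthreshold <- function(pids, config, ruleset) {
  if (!length(pids)) return(NULL)
  w <- config$window
  tram <- class_roster(ruleset, "TRAMADOL")
  ssri <- class_roster(ruleset, c("SSRI", "SNRI"))
  ym0 <- .ym_index(w$start_year, w$start_month)
  m <- sample.int(w$n_months, length(pids), replace = TRUE)
  year <- .ym_year(ym0 + m - 1L); month <- .ym_month(ym0 + m - 1L)
  si <- sample.int(nrow(ssri), length(pids), replace = TRUE)
  d1 <- 1L + floor(runif(length(pids)) * .days_in_month(year, month))
  d2 <- 1L + floor(runif(length(pids)) * .days_in_month(year, month))
  rbind(
    data.table(patient_id = pids,
               dispense_date = as.Date(sprintf("%04d-%02d-%02d", year, month, d1)),
               drug_code = tram$code[1], drug_name = tram$name[1],
               prescriber_id = paste0("D", pids, "a"), daily_dose_mg = 100),
    data.table(patient_id = pids,
               dispense_date = as.Date(sprintf("%04d-%02d-%02d", year, month, d2)),
               drug_code = ssri$code[si], drug_name = ssri$name[si],
               prescriber_id = paste0("D", pids, "a"), daily_dose_mg = NA_real_))
}

#' Deterministic case table from a persistence histogram
#'
#' Inverts a rule × months-count histogram into one synthetic case per
#' counted unit, assigning each case a consecutive run of window months, and
#' distributes same-prescriber status so the realized case-level and
#' month-level co-prescribing fractions match requested percentages at the
#' nearest achievable integer counts (co-prescribed cases are drawn from the
#' most persistent bins first, which maximizes the reachable month
#' percentage; each co-prescribed case has at least one co-prescribed month).
#'
#' @param counts Histogram matrix (rules × month counts), or a
#'   `pddi_persistence_table`.
#' @param attribution `NULL`, or a data.frame with `rule_id`,
#'   `pct_cases_same_prescriber`, `pct_patient_months_same_prescriber`.
#' @param scale Multiplier applied to counts (rounded per cell) to shrink the
#'   expansion for fast runs.
#' @param window A `pddi_window` (months are assigned inside it).
#' @return Case table in the shape of [build_cases()] plus `start_idx` (the
#'   1-based window month where the case's run begins); attribute `realized`
#'   reports requested vs achieved attribution counts per rule.
#' @export
cases_from_histogram <- function(counts, attribution = NULL, scale = 1,
                                 window = study_window("2018-01", "2018-12")) {
  if (inherits(counts, "pddi_persistence_table")) counts <- counts$counts
  counts <- round(as.matrix(counts) * scale)
  W <- ncol(counts)
  if (W > window$n_months) stop("histogram wider than the window", call. = FALSE)
  attr_dt <- if (!is.null(attribution)) as.data.table(attribution)
  out <- vector("list", nrow(counts)); realized <- vector("list", nrow(counts))
  pid0 <- 0
  for (i in seq_len(nrow(counts))) {
    rid <- rownames(counts)[i]
    cnt <- counts[i, ]
    n <- sum(cnt)
    if (n == 0) next
    # cases ordered by month-count descending so co-prescribed selection
    # takes the most persistent cases first
    m_of_case <- rep(W:1, rev(cnt))
    total_months <- sum(m_of_case)
    if (is.null(attr_dt) || !rid %in% attr_dt$rule_id) {
      k_case <- 0; k_month <- 0
      req_case <- 0; req_month <- 0
    } else {
      row <- attr_dt[rule_id == rid]
      req_case <- round(row$pct_cases_same_prescriber / 100 * n)
      req_month <- round(row$pct_patient_months_same_prescriber / 100 * total_months)
      k_case <- min(req_case, n)
      cap <- sum(m_of_case[seq_len(k_case)])
      k_month <- min(max(req_month, k_case), cap)
    }
    co_case <- seq_len(n) <= k_case
    co_months <- as.numeric(co_case)            # one co month per co case
    extra <- k_month - k_case
    if (extra > 0) {
      spare <- pmax(m_of_case - 1, 0) * co_case
      cum <- cumsum(spare)
      take <- pmin(spare, pmax(extra - c(0, head(cum, -1)), 0))
      co_months <- co_months + take
    }
    start_idx <- ((seq_len(n) - 1L) %% (window$n_months - m_of_case + 1L)) + 1L
    out[[i]] <- data.table(
      patient_id = sprintf("F%09.0f", pid0 + seq_len(n)),
      rule_id = rid, n_months = m_of_case,
      case_co_prescribed = co_case,
      patient_months_co_prescribed = as.integer(co_months),
      start_idx = start_idx)
    pid0 <- pid0 + n
    realized[[i]] <- data.table(rule_id = rid, n_cases = n,
                                requested_co_cases = req_case, co_cases = k_case,
                                patient_months = total_months,
                                requested_co_months = req_month,
                                co_months = sum(co_months))
  }
  cases <- rbindlist(out)
  if (nrow(cases) == 0)
    cases <- data.table(patient_id = character(), rule_id = character(),
                        n_months = integer(), case_co_prescribed = logical(),
                        patient_months_co_prescribed = integer(),
                        start_idx = integer())
  setattr(cases, "realized", rbindlist(realized))
  cases[]
}

#' Expand a persistence histogram into claim-level records
#'
#' Builds the deterministic case table of [cases_from_histogram()] and writes
#' two dispensations (one per rule side) into each of a case's months:
#' substances drawn uniformly from the class rosters under `seed`, days
#' uniform within the month, one prescriber for co-prescribed months and two
#' for the rest, and the side-A dose set to the rule's threshold where one
#' applies. Running the detector on the expansion reproduces the (scaled)
#' histogram exactly.
#'
#' @inheritParams cases_from_histogram
#' @param ruleset A `pddi_ruleset`.
#' @param seed RNG seed for substance and day draws.
#' @return List: `claims` (canonical claims data.table) and `cases` (the
#'   ground-truth case table).
#' @export
expand_histogram_fixture <- function(counts, attribution = NULL, scale = 1,
                                     window = study_window("2018-01", "2018-12"),
                                     ruleset = load_ruleset("default"),
                                     seed = 1L) {
  cases <- cases_from_histogram(counts, attribution, scale, window)
  if (nrow(cases) == 0)
    return(list(claims = .claims_for_months(
      data.table(patient_id = character(), rule_id = character(),
                 year = integer(), month = integer(), co = logical()),
      ruleset), cases = cases))
  ym0 <- .ym_index(window$start_year, window$start_month)
  idx <- rep(seq_len(nrow(cases)), cases$n_months)
  off <- sequence(cases$n_months)
  ym <- ym0 + cases$start_idx[idx] + off - 2L
  plan <- data.table(patient_id = cases$patient_id[idx],
                     rule_id = cases$rule_id[idx],
                     year = .ym_year(ym), month = .ym_month(ym),
                     co = off <= cases$patient_months_co_prescribed[idx])
  claims <- with_seed(seed, .claims_for_months(plan, ruleset))
  setorder(claims, patient_id, dispense_date, drug_name)
  list(claims = claims[], cases = cases)
}
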