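library(data.table)

default_rules <- load_ruleset("default")
window_2018 <- study_window("2018-01", "2018-12")

# one dispensation row in the canonical schema
claim_row <- function(patient, date, drug, prescriber = "", dose = NA_real_,
                      code = "") {
  data.table(patient_id = patient, dispense_date = as.Date(date),
             drug_code = code, drug_name = drug, prescriber_id = prescriber,
             daily_dose_mg = dose)
}

claims_of <- function(...) rbindlist(list(...))

# random claims mixing catalog drugs, off-catalog drugs, doses, unknown
# prescribers, and dates spilling outside the window
random_claims <- function(n_patients, n_records, seed) {
  set.seed(seed)
  drugs <- c(default_rules$catalog$name, "omeprazole", "metformin", "unknownium")
  dates <- seq(as.Date("2017-11-15"), as.Date("2019-02-15"), by = "day")
  data.table(
    patient_id = sprintf("p%03d", sample.int(n_patients, n_records, replace = TRUE)),
    dispense_date = sample(dates, n_records, replace = TRUE),
    drug_code = "",
    drug_name = sample(drugs, n_records, replace = TRUE),
    prescriber_id = sample(c("", sprintf("dr%02d", 1:6)), n_records,
                           replace = TRUE, prob = c(0.2, rep(0.8 / 6, 6))),
    daily_dose_mg = ifelse(runif(n_records) < 0.5, NA_real_,
                           sample(c(50, 100, 150, 200, 300, 400), n_records,
                                  replace = TRUE)))
}

flag_key_cols <- c("patient_id", "rule_id", "year", "month",
                   "co_prescribed", "min_interval_days", "n_pairs")
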