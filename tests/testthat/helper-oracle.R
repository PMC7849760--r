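# Brute-force reference for the screening rule: enumerates every record pair
# per patient with plain loops and data frames. Deliberately quadratic and
# independent of the data.table join path in flag_months().
oracle_flag_months <- function(claims, ruleset, window) {
  df <- as.data.frame(claims, stringsAsFactors = FALSE)
  df$class <- {
    by_code <- classify_drug(ruleset, df$drug_code)
    by_name <- classify_drug(ruleset, df$drug_name)
    ifelse(!is.na(by_code), by_code, by_name)
  }
  df$substance <- pddiscreen:::resolve_substance(ruleset, df$drug_code, df$drug_name)
  df$ym <- format(df$dispense_date, "%Y-%m")
  lo <- sprintf("%04d-%02d", window$start_year, window$start_month)
  hi <- sprintf("%04d-%02d", window$end_year, window$end_month)
  df <- df[!is.na(df$class) & df$ym >= lo & df$ym <= hi, , drop = FALSE]

  rows <- list()
  for (r in ruleset$rules) {
    self_pair <- setequal(r$side_a, r$side_b)
    for (pm in split(df, list(df$patient_id, df$ym), drop = TRUE)) {
      n <- nrow(pm)
      if (n < 2) next
      pair_subs <- character(); intervals <- integer(); co <- FALSE
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        for (ord in list(c(i, j), c(j, i))) {
          a <- pm[ord[1], ]; b <- pm[ord[2], ]
          if (!(a$class %in% r$side_a) || !(b$class %in% r$side_b)) next
          if (!is.na(r$min_daily_dose_mg) &&
              (is.na(a$daily_dose_mg) || a$daily_dose_mg < r$min_daily_dose_mg)) next
          if (r$require_distinct_substance && a$substance == b$substance) next
          key <- if (self_pair)
            paste(sort(c(a$substance, b$substance)), collapse = "|")
          else paste(a$substance, b$substance, sep = "|")
          pair_subs <- c(pair_subs, key)
          intervals <- c(intervals,
                         abs(as.integer(a$dispense_date - b$dispense_date)))
          if (nzchar(a$prescriber_id) && a$prescriber_id == b$prescriber_id)
            co <- TRUE
        }
      }
      if (length(pair_subs)) {
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = pm$patient_id[1], rule_id = r$rule_id,
          year = as.integer(substr(pm$ym[1], 1, 4)),
          month = as.integer(substr(pm$ym[1], 6, 7)),
          co_prescribed = co,
          min_interval_days = min(intervals),
          n_pairs = length(unique(pair_subs)),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), rule_id = character(),
               year = integer(), month = integer(), co_prescribed = logical(),
               min_interval_days = integer(), n_pairs = integer())
  out <- out[order(out$rule_id, out$patient_id, out$year, out$month), ]
  rownames(out) <- NULL
  out
}
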