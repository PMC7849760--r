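#' @title Reading and calendar-bucketing dispensation claims
#' @name claims_io
#' @description One row of a claims file is one dispensation: a drug dispensed
#'   to a patient on a date by a prescriber, with an optional prescribed daily
#'   dose in mg. Files are delimited text with a header; a dialect config maps
#'   non-standard column names and date formats onto the canonical schema.
NULL

.claims_cols <- c("patient_id", "dispense_date", "drug_code", "drug_name",
                  "prescriber_id", "daily_dose_mg")

#' Define a study window
#'
#' A closed range of calendar months plus the population denominator used for
#' prevalence percentages. The default denominator is the national population
#' of Poland in 2018 (38,413,139).
#'
#' @param start,end Month as `"YYYY-MM"` strings (or `"YYYY-MM-DD"`, day ignored).
#' @param population Positive integer population denominator.
#' @return A `pddi_window` list: `start_year`, `start_month`, `end_year`,
#'   `end_month`, `n_months`, `population`.
#' @examples
#' study_window("2018-01", "2018-12")
#' @export
study_window <- function(start = "2018-01", end = "2018-12",
                         population = 38413139) {
  parse_ym <- function(s) {
    m <- regmatches(s, regexec("^(\\d{4})-(\\d{2})", s))[[1]]
    if (length(m) != 3) stop("month must be 'YYYY-MM': ", s, call. = FALSE)
    c(as.integer(m[2]), as.integer(m[3]))
  }
  s <- parse_ym(start); e <- parse_ym(end)
  if (s[2] < 1 || s[2] > 12 || e[2] < 1 || e[2] > 12)
    stop("month out of 1..12", call. = FALSE)
  ym0 <- .ym_index(s[1], s[2]); ym1 <- .ym_index(e[1], e[2])
  if (ym0 > ym1) stop("window start is after its end", call. = FALSE)
  if (ym1 - ym0 + 1L > 120L) stop("window longer than 120 months", call. = FALSE)
  if (!is.numeric(population) || population <= 0)
    stop("population must be a positive number", call. = FALSE)
  structure(list(start_year = s[1], start_month = s[2],
                 end_year = e[1], end_month = e[2],
                 n_months = as.integer(ym1 - ym0 + 1L),
                 population = as.numeric(population)),
            class = "pddi_window")
}

#' @export
print.pddi_window <- function(x, ...) {
  cat(sprintf("<pddi_window> %04d-%02d .. %04d-%02d (%d months), population %s\n",
              x$start_year, x$start_month, x$end_year, x$end_month,
              x$n_months, format(x$population, big.mark = ",")))
  invisible(x)
}

#' Calendar month of a date
#'
#' The screening rule operates on calendar months: two dispensations co-occur
#' iff they fall in the same (year, month). No timezone logic is applied.
#'
#' @param d A `Date` vector (or something [as.Date()] accepts).
#' @return data.table with columns `year` and `month`.
#' @examples
#' month_of(as.Date(c("2018-01-31", "2018-02-01")))
#' @export
month_of <- function(d) {
  d <- as.Date(d)
  lt <- as.POSIXlt(d)
  data.table(year = lt$year + 1900L, month = lt$mon + 1L)
}

#' Read and validate dispensation claims
#'
#' Reads delimited text (separator sniffed by [data.table::fread()]), applies
#' an optional dialect (column-name mapping and date format), validates each
#' row, and returns the valid records. Malformed rows — unparseable or
#' out-of-calendar dates, missing patient ID, rows naming no drug, negative
#' doses — are dropped, counted and reported with their row numbers in the
#' `rejects` attribute (optionally written to a CSV with a reason column).
#'
#' @param path Claims file path.
#' @param dialect `NULL` for the canonical schema, a named list, or the path
#'   of a YAML file. Recognized entries: `columns` (named list mapping
#'   canonical names `patient_id`, `dispense_date`, `drug_code`, `drug_name`,
#'   `prescriber_id`, `daily_dose_mg` to file column names) and `date_format`
#'   (a [strptime()] format, default `%Y-%m-%d`).
#' @param max_reject_frac Hard-failure threshold: if more than this fraction
#'   of data rows is malformed the read aborts (default 0.10).
#' @param rejects_path Optional path; rejected rows are written there as CSV
#'   with a `reject_reason` column.
#' @return data.table with the canonical columns (`patient_id`,
#'   `dispense_date` as `Date`, `drug_code`, `drug_name`, `prescriber_id` —
#'   `""` means unknown — and `daily_dose_mg`, `NA` if absent), plus
#'   attributes `n_read` and `rejects`.
#' @export
read_claims <- function(path, dialect = NULL, max_reject_frac = 0.10,
                        rejects_path = NULL) {
  if (!file.exists(path)) stop("cannot read claims file: ", path, call. = FALSE)
  if (is.character(dialect)) dialect <- yaml::read_yaml(dialect)
  date_format <- dialect$date_format %||% "%Y-%m-%d"
  colmap <- dialect$columns %||% list()

  raw <- fread(path, colClasses = "character", na.strings = NULL,
               keepLeadingZeros = TRUE)
  n_read <- nrow(raw)
  pick <- function(std) {
    src <- colmap[[std]] %||% std
    if (src %in% names(raw)) raw[[src]] else rep("", n_read)
  }
  dt <- data.table(
    patient_id    = trimws(pick("patient_id")),
    date_raw      = trimws(pick("dispense_date")),
    drug_code     = trimws(pick("drug_code")),
    drug_name     = trimws(pick("drug_name")),
    prescriber_id = trimws(pick("prescriber_id")),
    dose_raw      = trimws(pick("daily_dose_mg")))
  required <- c("patient_id", "dispense_date")
  missing_cols <- required[!vapply(required, function(std)
    (colmap[[std]] %||% std) %in% names(raw), TRUE)]
  if (length(missing_cols))
    stop("claims file lacks mapped column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  dt[, dispense_date := as.Date(date_raw, format = date_format)]
  has_dose_col <- (colmap$daily_dose_mg %||% "daily_dose_mg") %in% names(raw)
  dt[, daily_dose_mg := if (has_dose_col) suppressWarnings(as.numeric(dose_raw)) else NA_real_]

  reason <- rep(NA_character_, n_read)
  reason[is.na(reason) & !nzchar(dt$patient_id)] <- "missing patient_id"
  reason[is.na(reason) & is.na(dt$dispense_date)] <- "invalid dispense_date"
  reason[is.na(reason) & !nzchar(dt$drug_code) & !nzchar(dt$drug_name)] <- "no drug code or name"
  reason[is.na(reason) & has_dose_col & nzchar(dt$dose_raw) & is.na(dt$daily_dose_mg)] <- "non-numeric dose"
  reason[is.na(reason) & !is.na(dt$daily_dose_mg) & dt$daily_dose_mg < 0] <- "negative dose"

  bad <- which(!is.na(reason))
  rejects <- data.table(row = bad + 1L, reject_reason = reason[bad])  # +1: header
  if (n_read > 0 && length(bad) / n_read > max_reject_frac)
    stop(sprintf("%d of %d rows malformed (> %.0f%% allowed); first reasons: %s",
                 length(bad), n_read, 100 * max_reject_frac,
                 paste(head(unique(reason[bad]), 3), collapse = "; ")),
         call. = FALSE)
  if (length(bad))
    message(sprintf("read_claims: skipped %d malformed row(s) of %d", length(bad), n_read))
  if (!is.null(rejects_path)) fwrite(rejects, rejects_path)

  out <- dt[!seq_len(.N) %in% bad,
            .(patient_id, dispense_date, drug_code, drug_name,
              prescriber_id, daily_dose_mg)]
  setattr(out, "n_read", n_read)
  setattr(out, "rejects", rejects)
  out[]
}

#' Write claims in the canonical CSV dialect
#'
#' Inverse of [read_claims()] for valid records: writing then re-reading
#' yields equal records.
#'
#' @param claims data.table of canonical claims columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_claims <- function(claims, path) {
  stopifnot(all(.claims_cols %in% names(claims)))
  fwrite(claims[, .claims_cols, with = FALSE], path, dateTimeAs = "ISO")
  invisible(path)
}

#' Restrict claims to a study window
#'
#' Drops records dispensed outside the window's calendar months. Bucketing to
#' months and filtering commute.
#'
#' @param claims Canonical claims data.table.
#' @param window A `pddi_window`.
#' @return Filtered copy of `claims`.
#' @export
filter_window <- function(claims, window) {
  stopifnot(inherits(window, "pddi_window"))
  mk <- month_of(claims$dispense_date)
  ym <- .ym_index(mk$year, mk$month)
  lo <- .ym_index(window$start_year, window$start_month)
  hi <- .ym_index(window$end_year, window$end_month)
  claims[ym >= lo & ym <= hi]
}
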