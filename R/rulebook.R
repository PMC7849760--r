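#' @title Interaction rule sets and the drug catalog
#' @description Functions to load, validate, serialize and query the rule set
#'   that drives pDDI screening: a flat drug catalog (substance code, name,
#'   study class) plus a list of interaction rules, each pairing two sets of
#'   drug classes with an optional per-dispensation daily-dose threshold and a
#'   distinct-substance requirement for self-pairs.
#' @name rulebook
NULL

#' Closed vocabulary of study drug classes
#'
#' The thirteen drug-class labels a catalog entry may carry. Tramadol is its
#' own class (screened separately from the strong opioids, with a high-dose
#' condition); codeine is grouped with the opioids. Antihypertensives are kept
#' as three auditable subclasses (ACE inhibitors, angiotensin-receptor
#' blockers, beta-blockers) that rules union into one selector.
#'
#' @return Character vector of valid class labels.
#' @export
drug_classes <- function() {
  c("NSAID", "TRAMADOL", "OPIOID", "BENZODIAZEPINE", "GABAPENTINOID",
    "GC", "ANTIPLATELET", "ANTIHYPERTENSIVE_ACEI", "ANTIHYPERTENSIVE_ARB",
    "ANTIHYPERTENSIVE_BB", "SSRI", "SNRI", "OAC")
}

#' Severity categories for interaction rules
#' @return Character vector: C (monitor therapy), D (consider therapy
#'   modification), X (avoid combination).
#' @export
severity_categories <- function() c("C", "D", "X")

.default_rules_path <- function() {
  system.file("extdata", "rules-default.yaml", package = "pddiscreen",
              mustWork = TRUE)
}

#' Load and validate an interaction rule set
#'
#' Reads a YAML (or JSON) rule file with `catalog`, optional `aliases`, and
#' `rules` sections, validates it against the closed class vocabulary, and
#' returns a `pddi_ruleset`. The packaged default (`path = "default"`) carries
#' the nine analgesic-drug rules and a 58-substance catalog: NSAIDs paired
#' with antihypertensives (ACEI/ARB/beta-blocker), other NSAIDs (distinct
#' substances), oral glucocorticoids, SSRIs/SNRIs, oral anticoagulants and
#' antiplatelet drugs; opioids with gabapentinoids and benzodiazepines; and
#' high-dose tramadol (>= 200 mg daily dose) with SSRIs/SNRIs.
#'
#' @param path Path to a rule file, or `"default"` for the packaged rule set.
#' @return An object of class `pddi_ruleset`: a list with `catalog`
#'   (data.table: `code`, `name`, `class_label`), `aliases` (data.table:
#'   `name`, `canonical`), and `rules` (list of rule records with `rule_id`,
#'   `display_name`, `side_a`, `side_b`, `category`, `min_daily_dose_mg`,
#'   `require_distinct_substance`).
#' @examples
#' rs <- load_ruleset("default")
#' length(rs$rules)          # 9
#' classify_drug(rs, "diclofenac")
#' @export
load_ruleset <- function(path = "default") {
  if (identical(path, "default")) path <- .default_rules_path()
  if (!file.exists(path)) stop("rule file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  validate_ruleset(doc, source = path)
}

#' Validate a parsed rule-set document
#'
#' @param doc A list as parsed from a rule file (sections `catalog`,
#'   `aliases`, `rules`).
#' @param source Label used in error messages.
#' @return A validated `pddi_ruleset`.
#' @export
validate_ruleset <- function(doc, source = "ruleset") {
  fail <- function(...) stop(source, ": ", ..., call. = FALSE)
  if (is.null(doc$catalog) || !length(doc$catalog)) fail("missing 'catalog' section")
  if (is.null(doc$rules) || !length(doc$rules)) fail("missing 'rules' section")

  catalog <- rbindlist(lapply(doc$catalog, function(e) {
    if (is.null(e$code) && is.null(e$name)) fail("catalog entry needs a code or name")
    data.table(code = toupper(trimws(e$code %||% "")),
               name = tolower(trimws(e$name %||% "")),
               class_label = as.character(e$class %||% e$class_label %||% NA))
  }))
  bad <- setdiff(unique(catalog$class_label), drug_classes())
  if (length(bad))
    fail("unknown class label(s) ", paste(bad, collapse = ", "),
         "; valid labels are: ", paste(drug_classes(), collapse = ", "))
  if (anyDuplicated(catalog$code[nzchar(catalog$code)]))
    fail("duplicate catalog code: ",
         paste(unique(catalog$code[duplicated(catalog$code)]), collapse = ", "))
  if (anyDuplicated(catalog$name[nzchar(catalog$name)]))
    fail("duplicate catalog name: ",
         paste(unique(catalog$name[duplicated(catalog$name)]), collapse = ", "))

  aliases <- if (length(doc$aliases)) {
    rbindlist(lapply(doc$aliases, function(a)
      data.table(name = tolower(trimws(a$name)), canonical = tolower(trimws(a$canonical)))))
  } else data.table(name = character(), canonical = character())
  unknown <- setdiff(aliases$canonical, catalog$name)
  if (length(unknown)) fail("alias targets not in catalog: ", paste(unknown, collapse = ", "))

  rules <- lapply(doc$rules, function(r) {
    if (is.null(r$rule_id)) fail("rule missing 'rule_id'")
    side_a <- as.character(unlist(r$side_a))
    side_b <- as.character(unlist(r$side_b))
    if (!length(side_a) || !length(side_b))
      fail("rule ", r$rule_id, ": both sides must be non-empty")
    bad <- setdiff(c(side_a, side_b), drug_classes())
    if (length(bad))
      fail("rule ", r$rule_id, ": unknown class label(s) ", paste(bad, collapse = ", "),
           "; valid labels are: ", paste(drug_classes(), collapse = ", "))
    category <- as.character(r$category %||% NA)
    if (!category %in% severity_categories())
      fail("rule ", r$rule_id, ": category must be one of ",
           paste(severity_categories(), collapse = "/"))
    distinct <- isTRUE(r$require_distinct_substance)
    if (setequal(side_a, side_b) && !distinct)
      fail("rule ", r$rule_id,
           ": self-pair rules must set require_distinct_substance")
    dose <- r$min_daily_dose_mg
    if (!is.null(dose) && (!is.numeric(dose) || dose <= 0))
      fail("rule ", r$rule_id, ": min_daily_dose_mg must be a positive number")
    missing_roster <- setdiff(c(side_a, side_b), unique(catalog$class_label))
    if (length(missing_roster))
      fail("rule ", r$rule_id, ": no catalog entries for class(es) ",
           paste(missing_roster, collapse = ", "))
    list(rule_id = as.character(r$rule_id),
         display_name = as.character(r$display_name %||% r$rule_id),
         side_a = side_a, side_b = side_b,
         category = category,
         min_daily_dose_mg = if (is.null(dose)) NA_real_ else as.numeric(dose),
         require_distinct_substance = distinct,
         consequence = as.character(r$consequence %||% NA))
  })
  ids <- vapply(rules, `[[`, "", "rule_id")
  if (anyDuplicated(ids))
    fail("duplicate rule_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))

  structure(list(catalog = catalog, aliases = aliases, rules = rules),
            class = "pddi_ruleset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a rule set back to YAML
#'
#' Round-trips with [load_ruleset()]: writing a loaded rule set and re-loading
#' it yields an equal object.
#'
#' @param ruleset A `pddi_ruleset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ruleset <- function(ruleset, path) {
  stopifnot(inherits(ruleset, "pddi_ruleset"))
  doc <- list(
    catalog = lapply(seq_len(nrow(ruleset$catalog)), function(i)
      list(code = ruleset$catalog$code[i], name = ruleset$catalog$name[i],
           class = ruleset$catalog$class_label[i])),
    aliases = if (nrow(ruleset$aliases)) lapply(seq_len(nrow(ruleset$aliases)),
      function(i) list(name = ruleset$aliases$name[i],
                       canonical = ruleset$aliases$canonical[i])) else NULL,
    rules = lapply(ruleset$rules, function(r) {
      out <- list(rule_id = r$rule_id, display_name = r$display_name,
                  side_a = as.list(r$side_a), side_b = as.list(r$side_b),
                  category = r$category)
      if (!is.na(r$min_daily_dose_mg)) out$min_daily_dose_mg <- r$min_daily_dose_mg
      if (r$require_distinct_substance) out$require_distinct_substance <- TRUE
      if (!is.na(r$consequence)) out$consequence <- r$consequence
      out
    }))
  doc <- Filter(Negate(is.null), doc)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Map drug tokens to study classes
#'
#' Case-insensitive lookup: a token is matched against catalog codes first,
#' then substance names (after alias resolution). Unmatched tokens return
#' `NA` — drugs outside the catalog are simply outside the study.
#'
#' @param ruleset A `pddi_ruleset`.
#' @param token Character vector of drug codes and/or names.
#' @return Character vector of class labels, `NA` where unmatched.
#' @examples
#' rs <- load_ruleset("default")
#' classify_drug(rs, c("diclofenac", "tramadol", "omeprazole"))
#' @export
classify_drug <- function(ruleset, token) {
  stopifnot(inherits(ruleset, "pddi_ruleset"))
  token <- trimws(as.character(token))
  by_code <- ruleset$catalog$class_label[match(toupper(token), ruleset$catalog$code)]
  low <- tolower(token)
  ali <- match(low, ruleset$aliases$name)
  low[!is.na(ali)] <- ruleset$aliases$canonical[ali[!is.na(ali)]]
  by_name <- ruleset$catalog$class_label[match(low, ruleset$catalog$name)]
  ifelse(!is.na(by_code), by_code, by_name)
}

# Canonical substance identity for a (code, name) pair: the catalog name if the
# code or (alias-resolved) name matches, else the lowercased raw name, else the
# raw code. Codes win on conflict. Used for the distinct-substance test.
resolve_substance <- function(ruleset, code, name) {
  code_u <- toupper(trimws(code)); name_l <- tolower(trimws(name))
  ali <- match(name_l, ruleset$aliases$name)
  name_l[!is.na(ali)] <- ruleset$aliases$canonical[ali[!is.na(ali)]]
  by_code <- ruleset$catalog$name[match(code_u, ruleset$catalog$code)]
  out <- by_code
  out[is.na(out) & nzchar(name_l)] <- name_l[is.na(out) & nzchar(name_l)]
  out[is.na(out)] <- code_u[is.na(out)]
  out
}

# Class labels resolved the same way (code wins), vectorized over records.
resolve_class <- function(ruleset, code, name) {
  by_code <- classify_drug(ruleset, code)
  by_name <- classify_drug(ruleset, name)
  ifelse(!is.na(by_code), by_code, by_name)
}

#' Roster of substances for a set of classes
#' @param ruleset A `pddi_ruleset`.
#' @param classes Character vector of class labels.
#' @return data.table with `code`, `name`, `class_label`.
#' @export
class_roster <- function(ruleset, classes) {
  ruleset$catalog[class_label %in% classes]
}

#' @export
print.pddi_ruleset <- function(x, ...) {
  cat("<pddi_ruleset> ", length(x$rules), " rules, ",
      nrow(x$catalog), " catalog substances\n", sep = "")
  for (r in x$rules) {
    cond <- character()
    if (!is.na(r$min_daily_dose_mg))
      cond <- c(cond, sprintf("dose >= %g mg", r$min_daily_dose_mg))
    if (r$require_distinct_substance) cond <- c(cond, "distinct substances")
    cat(sprintf("  %-24s [%s] %s%s\n", r$rule_id, r$category, r$display_name,
                if (length(cond)) paste0(" (", paste(cond, collapse = ", "), ")") else ""))
  }
  invisible(x)
}
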