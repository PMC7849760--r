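# pddiscreen

Rule-based screening of pharmacy dispensation claims for potential
drug-drug interactions (pDDIs) of analgesic drugs.

In single-payer claims databases, every reimbursed dispensation is recorded:
patient, date, drug, prescriber. That makes population-scale interaction
screening possible with a simple, auditable rule: a pDDI is deemed present
for a patient in a calendar month iff both drugs of a conflicting pair were
dispensed to that patient within that same month. `pddiscreen` implements
this screen for nine analgesic-drug interaction pairs — NSAIDs with
antihypertensives (ACEI/ARB/beta-blocker), with a second distinct NSAID,
with oral glucocorticoids, SSRIs/SNRIs, oral anticoagulants and antiplatelet
drugs; opioids with gabapentinoids and with benzodiazepines; and high-dose
tramadol (daily dose ≥ 200 mg) with SSRIs/SNRIs — and computes the study
aggregates a pharmacoepidemiologist reports from it:

- **Prevalence**: cases (one patient × one interaction rule with ≥ 1 flagged
  month) and their percentage of a population denominator.
- **Persistence**: per rule, the histogram of the number of calendar months
  each case was present, its mean, and a normal-approximation 95% CI
  (mean ± 1.96·s/√n, with s computed exactly from the grouped histogram);
  a Kruskal-Wallis test compares persistence across rules.
- **Attribution**: per rule, the share of cases — and of flagged
  patient-months — where some qualifying pair came from one prescriber
  (co-prescribing), with case-weighted and patient-month-weighted overall
  means.

The package also ships a seeded synthetic claims generator with a
ground-truth sidecar (planted episodes, plus background that can never
qualify: single-substance fills, conflicting pairs split across adjacent
months, sub-threshold tramadol), and a deterministic fixture expander that
inverts published aggregate tables into claim-level records — the basis for
its end-to-end validation.

## Worked example

```r
library(pddiscreen)
library(data.table)

rs <- load_ruleset("default")     # 9 rules, 58-substance catalog
w  <- study_window("2018-01", "2018-12")   # population 38,413,139

claims <- rbindlist(list(
  data.table(patient_id = "p1",
             dispense_date = as.Date(c("2018-03-02", "2018-03-20", "2018-06-04")),
             drug_code = "", drug_name = c("ibuprofen", "ramipril", "naproxen"),
             prescriber_id = c("drA", "drA", "drB"), daily_dose_mg = NA_real_)))

flag_months(claims, rs, w)
#>    patient_id                rule_id  year month co_prescribed min_interval_days n_pairs
#> 1:         p1 nsaid_antihypertensive  2018     3          TRUE                18       1
```

March holds an NSAID and an ACE inhibitor, both from prescriber `drA`: one
flagged patient-month, co-prescribed, 18 days between the two fills. The
June naproxen has no same-month partner, so nothing else is flagged.
`build_cases()` then aggregates flags into one case per (patient, rule), and
`run_screen()` drives the whole pipeline from a claims file to report files
(`flags.csv`, `cases.csv`, `table3.csv`, `table4.csv`, `fig1.csv`,
`summary.json`):

```r
res <- run_screen(claims, out_dir = "out", ruleset = rs, window = w)
res$summary$total_cases              # 1
res$summary$pct_population_total     # 2.6e-06 (one case in 38.4 M)
```

A shell front end with the same behaviour ships at `inst/cli/pddi.R`
(subcommands `screen`, `simulate`, `fixture`, `rules`).

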