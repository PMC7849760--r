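---
title: "Screening claims for analgesic pDDIs: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening claims for analgesic pDDIs: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pddiscreen)
library(data.table)
```

## The screening model

A *potential* drug-drug interaction (pDDI) is a co-medication pattern that
could produce an interaction, regardless of whether harm occurred. In
dispensation claims the package operationalizes co-medication with a
calendar-month rule: for a patient, an interaction rule fires in month *t*
iff the month contains at least one dispensation whose drug class lies on
the rule's side A and one on side B, subject to two optional conditions —
the pair must be two *different substances* where a rule pairs a class with
itself (NSAID double use), and the side-A dispensation must meet a minimum
prescribed daily dose where one is set (tramadol, 200 mg). Each flagged
patient-month carries the smallest day gap among qualifying pairs (0 for
same-day fills, at most 30 within a month) and a prescriber dichotomy: the
month is *co-prescribed* if some qualifying pair was issued by one and the
same prescriber.

The unit of reporting is the **case**: one (patient, rule) pair with at
least one flagged month in the study window. A case contributes its number
of flagged months — its *persistence* — as patient-months, which is the
identity that ties the two reporting tables together: per rule,
$\sum_m m \cdot \mathrm{counts}[m]$ over the persistence histogram equals
the patient-month total of the attribution table. The test suite asserts
this identity exactly on the bundled national aggregates for all nine rules.

Assumptions worth making explicit:

- *Same calendar month*, not a sliding 30-day window: two fills on Jan 31
  and Feb 1 do not co-occur. This is a conservative screen; a longer gap
  between dispensations can still expose a patient, but is invisible here.
- Dispensation is taken as exposure. Non-adherence, stockpiling and
  over-the-counter purchases (NSAIDs in particular) are outside the data.
- A patient with two different interaction types is two cases. The headline
  "percentage of population" divides *cases* by the population denominator;
  a separately labelled unique-patient prevalence is also computed, because
  the two are easy to conflate.

## Rules, catalog and parameters

`load_ruleset("default")` provides the nine analgesic rules with severity
category C or D (monitor therapy / consider therapy modification; the
engine carries the category as metadata and never filters on it, so
X-category rules can be screened with the same machinery). The catalog maps
58 substances (code and lowercase name) onto thirteen class labels.
Tramadol is deliberately its own class rather than an opioid: it is the
weak opioid prescribed on ordinary prescriptions and is only hazardous with
serotonergic drugs at high doses, hence its rule carries
`min_daily_dose_mg = 200`; codeine, by contrast, sits with the strong
opioids. Antihypertensives are restricted to ACE inhibitors, angiotensin
receptor blockers and beta-blockers — the subclasses for which NSAID
antagonism of blood-pressure control is pharmacologically established —
kept as three auditable rosters unioned by the rule's class selector.

Tunable parameters, with defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `min_daily_dose_mg` (tramadol rule) | 200 mg | per-dispensation prescribed daily dose threshold |
| `population` (`study_window`) | 38,413,139 | national population denominator, Poland 2018 |
| attribution `policy` (`build_cases`) | `"any"` | a case is co-prescribed if ≥ 1 of its months is |
| `max_reject_frac` (`read_claims`) | 0.10 | hard-failure threshold for malformed input rows |

Design points that were genuinely open, and how they were settled:

- **Case-level attribution policy.** Month flags are unambiguous, but a
  multi-month case could be called co-prescribed under several readings.
  The default is the most sensitive one ("any co-prescribed month"), with
  `"all"` and `"majority"` available; patient-month-level percentages are
  unaffected by the choice.
- **Dose condition per dispensation.** The tramadol threshold applies to
  each side-A dispensation's recorded daily dose, not to a monthly sum —
  the simplest reading of a "high-dose" criterion, and the one that keeps
  the record model free of pack-size/DDD arithmetic.
- **Unknown prescribers.** An empty prescriber ID never equals any other,
  so such pairs count as multi-prescriber. This biases attribution
  downward rather than inventing agreement.
- **Distinct-substance test by substance identity.** The catalog's
  canonical substance (code wins over name) is compared, so two brands or
  strengths of one molecule never form an NSAID + NSAID pair.
- **Confidence intervals.** The normal approximation mean ± 1.96·s/√n with
  the grouped-data sample standard deviation. With case counts in the
  hundreds to millions the approximation is immaterial; it is validated by
  exact reproduction (to printed precision) of all four published
  persistence CIs derivable from the bundled histogram, including the
  smallest rule (487 cases).
- **Kruskal-Wallis across rules.** Observations are per-case month counts,
  groups are rules; the tie-corrected H with the chi-square approximation
  is used regardless of group sizes (ties are massive by construction —
  twelve distinct values). The implementation delegates to
  `stats::kruskal.test`; the test suite pins it to a hand-ranked two-group
  oracle (H = 7 exactly) and to the H = 0, p = 1 symmetry limit.

## Numerical and degenerate-input behaviour

All accumulation is in double precision at full precision; rounding (2
decimals for percentages of population and means, 1 for attribution
percentages) happens only in display and CSV export. Grouped variance is
computed as $(\sum m^2 c_m - n\bar m^2)/(n-1)$ with a clamp at zero against
floating-point cancellation in the zero-variance case. Empty inputs
propagate cleanly: an empty claims file produces zero-row outputs and exit
status 0; rules with zero cases are omitted from summaries with a warning;
fewer than two non-empty rules make the Kruskal-Wallis test an error rather
than a NaN. Duplicate (patient, rule, month) flags abort case aggregation,
since they can only arise from an upstream bug.

## What the synthetic data emulate — and what they do not

`simulate_claims()` is *constructive*: planted episodes are written
directly as one side-A and one side-B dispensation in each chosen month,
so the planted case count and month-count histogram are recovered exactly
by the detector, and recovery tests are sharp rather than statistical. Per
rule the configuration sets the case count, a month-count distribution
(allocated by largest-remainder apportionment, so the realized histogram
is deterministic), and a per-month co-prescribing probability (the one
stochastic margin, tested against binomial 99% bounds). Around the planted
signal the generator emits three kinds of structured negatives: background
patients repeatedly filling a single substance (no rule pairs a substance
with itself), near-misses that split a genuinely conflicting pair across
adjacent months, and sub-threshold tramadol months with an SSRI/SNRI.
Substances are drawn uniformly from class rosters, days uniformly within
months, and everything is reproducible from one integer seed (the
generator restores the caller's RNG state).

The default configuration reproduces the national 2018 screen at 1/1000
scale: planted counts and month-count distributions follow the bundled
persistence histogram and the co-prescribing probabilities follow the
bundled patient-month attribution column, over a 12-month window.

What the generator does **not** emulate: prescribing behaviour (visit
patterns, refill cycles, seasonality), patient demographics and
comorbidity, dose heterogeneity beyond the threshold, OTC purchasing and
non-adherence, and patients holding several interaction types at once
(each planted case has its own patient). Passing recovery tests therefore
demonstrates that the detection and aggregation machinery is exact on data
with the assumed co-occurrence structure — not that the screen is robust
to real-world data quality, which is what the reject-logging input layer
and the oracle-equivalence property (detector ≡ brute-force all-pairs
enumeration on randomized inputs mixing off-catalog drugs, unknown
prescribers and out-of-window dates) are for.

`expand_histogram_fixture()` inverts an aggregate table deterministically:
one synthetic case per counted histogram unit, each assigned a consecutive
run of months, with co-prescribed status distributed so realized case- and
month-level fractions hit the requested percentages at the nearest
achievable integer counts (co-prescribed cases are taken from the most
persistent bins first, which maximizes the reachable month percentage; the
achieved counts are reported in the `realized` attribute). A `scale`
factor shrinks the expansion cell-wise for fast runs; rules whose scaled
histogram retains fewer than ~100 cases cannot hold their month-count
shape (a 20-case rule moves its mean in steps of ~0.05 months), which the
tests acknowledge by asserting scaled-vs-full closeness only above that
mass.

## Problem sizes

The bundled aggregates describe 2,485,787 cases and 4,123,128
patient-months. The statistics layer is exercised at full scale directly
from the histogram-derived case table (seconds). Claim-level end-to-end
runs through the detector use scaled expansions — 1/500 to 1/2000 in the
acceptance script and tests, i.e. thousands of cases and tens of thousands
of dispensation rows — which is ample to verify exact recovery, since the
expansion is deterministic and the detector is additionally pinned to the
quadratic oracle on randomized inputs.

## Known limitations

- No look-ahead across month boundaries; a configurable multi-month
  overlap window is out of scope.
- Flat rosters only: no ATC hierarchy traversal, no interaction
  knowledge-base lookups.
- No deduplication of patients across rules in the headline count (by
  design, matching the case definition); the unique-patient figure is
  reported alongside.
- The dose field is taken as given; whether it represents prescribed daily
  dose or package strength is a property of the source dialect, not of the
  engine.
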