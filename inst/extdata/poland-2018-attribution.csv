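rule_id,n_cases,pct_cases_same_prescriber,n_patient_months,pct_patient_months_same_prescriber
nsaid_antihypertensive,1583575,78.3,2903210,80.2
nsaid_nsaid,538640,75.4,664985,76.2
nsaid_gc,213504,77.1,317551,79.6
nsaid_ssri_snri,62666,45.3,94525,49.0
nsaid_oac,46582,73.1,67083,75.5
nsaid_antiplatelet,22629,71.3,36340,74.2
opioid_gabapentinoid,17118,87.3,37525,85.7
opioid_benzodiazepine,586,71.3,864,74.4
tramadol_ssri_snri,487,60.2,1045,64.7
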