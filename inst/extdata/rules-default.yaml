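# Default interaction rule set: analgesic-drug pDDIs screened in reimbursed
# dispensation claims. Severity categories: C = monitor therapy, D = consider
# therapy modification, X = avoid combination (no X rule in this default set).
catalog:
  # NSAIDs (14)
  - {code: M01AB05, name: diclofenac,       class: NSAID}
  - {code: M01AE01, name: ibuprofen,        class: NSAID}
  - {code: M01AH01, name: celecoxib,        class: NSAID}
  - {code: M01AE02, name: naproxen,         class: NSAID}
  - {code: M01AH05, name: etoricoxib,       class: NSAID}
  - {code: M01AC01, name: piroxicam,        class: NSAID}
  - {code: M01AC06, name: meloxicam,        class: NSAID}
  - {code: M01AE03, name: ketoprofen,       class: NSAID}
  - {code: M01AE17, name: dexketoprofen,    class: NSAID}
  - {code: M01AB16, name: aceclofenac,      class: NSAID}
  - {code: M01AC05, name: lornoxicam,       class: NSAID}
  - {code: M01AA01, name: phenylbutazone,   class: NSAID}
  - {code: M01AG01, name: mefenamic acid,   class: NSAID}
  - {code: M01AX17, name: nimesulide,       class: NSAID}
  # Tramadol is screened as its own class (weak opioid, ordinary prescriptions);
  # codeine is grouped with the strong opioids below.
  - {code: N02AX02, name: tramadol,         class: TRAMADOL}
  # Opioids (6)
  - {code: R05DA04, name: codeine,          class: OPIOID}
  - {code: N02AA08, name: dihydrocodeine,   class: OPIOID}
  - {code: N02AA01, name: morphine,         class: OPIOID}
  - {code: N02AA05, name: oxycodone,        class: OPIOID}
  - {code: N02AE01, name: buprenorphine,    class: OPIOID}
  - {code: N02AB03, name: fentanyl,         class: OPIOID}
  # Benzodiazepines (5)
  - {code: N05BA12, name: alprazolam,       class: BENZODIAZEPINE}
  - {code: N05BA01, name: diazepam,         class: BENZODIAZEPINE}
  - {code: N05BA06, name: lorazepam,        class: BENZODIAZEPINE}
  - {code: N05CD07, name: temazepam,        class: BENZODIAZEPINE}
  - {code: N05BA08, name: bromazepam,       class: BENZODIAZEPINE}
  # Gabapentinoids (2)
  - {code: N03AX12, name: gabapentin,       class: GABAPENTINOID}
  - {code: N03AX16, name: pregabalin,       class: GABAPENTINOID}
  # Oral glucocorticoids (3)
  - {code: H02AB07, name: prednisone,          class: GC}
  - {code: H02AB06, name: prednisolone,        class: GC}
  - {code: H02AB04, name: methylprednisolone,  class: GC}
  # Antiplatelet drugs (4)
  - {code: B01AC05, name: ticlopidine,      class: ANTIPLATELET}
  - {code: B01AC04, name: clopidogrel,      class: ANTIPLATELET}
  - {code: B01AC24, name: ticagrelor,       class: ANTIPLATELET}
  - {code: B01AC22, name: prasugrel,        class: ANTIPLATELET}
  # Antihypertensives: ACEIs, ARBs and beta-blockers only (15 across 3 subclasses)
  - {code: C09CA03, name: valsartan,        class: ANTIHYPERTENSIVE_ARB}
  - {code: C09CA01, name: losartan,         class: ANTIHYPERTENSIVE_ARB}
  - {code: C09CA07, name: telmisartan,      class: ANTIHYPERTENSIVE_ARB}
  - {code: C09CA04, name: irbesartan,       class: ANTIHYPERTENSIVE_ARB}
  - {code: C09CA06, name: candesartan,      class: ANTIHYPERTENSIVE_ARB}
  - {code: C09AA02, name: enalapril,        class: ANTIHYPERTENSIVE_ACEI}
  - {code: C09AA05, name: ramipril,         class: ANTIHYPERTENSIVE_ACEI}
  - {code: C09AA06, name: quinapril,        class: ANTIHYPERTENSIVE_ACEI}
  - {code: C09AA04, name: perindopril,      class: ANTIHYPERTENSIVE_ACEI}
  - {code: C09AA15, name: zofenopril,       class: ANTIHYPERTENSIVE_ACEI}
  - {code: C07AB02, name: metoprolol,       class: ANTIHYPERTENSIVE_BB}
  - {code: C07AB12, name: nebivolol,        class: ANTIHYPERTENSIVE_BB}
  - {code: C07AG02, name: carvedilol,       class: ANTIHYPERTENSIVE_BB}
  - {code: C07AA05, name: propranolol,      class: ANTIHYPERTENSIVE_BB}
  - {code: C07AB05, name: betaxolol,        class: ANTIHYPERTENSIVE_BB}
  # SSRIs (4)
  - {code: N06AB05, name: paroxetine,       class: SSRI}
  - {code: N06AB03, name: fluoxetine,       class: SSRI}
  - {code: N06AB04, name: citalopram,       class: SSRI}
  - {code: N06AB10, name: escitalopram,     class: SSRI}
  # SNRIs (2)
  - {code: N06AX21, name: duloxetine,       class: SNRI}
  - {code: N06AX16, name: venlafaxine,      class: SNRI}
  # Oral anticoagulants (2)
  - {code: B01AA03, name: warfarin,         class: OAC}
  - {code: B01AA07, name: acenocoumarol,    class: OAC}
aliases:
  # variant spellings seen in source listings
  - {name: nebiolol, canonical: nebivolol}
rules:
  - rule_id: nsaid_antihypertensive
    display_name: "NSAIDs + Antihypertensive drugs"
    side_a: [NSAID]
    side_b: [ANTIHYPERTENSIVE_ACEI, ANTIHYPERTENSIVE_ARB, ANTIHYPERTENSIVE_BB]
    category: C
    consequence: "increased blood pressure"
  - rule_id: nsaid_nsaid
    display_name: "NSAIDs + NSAIDs"
    side_a: [NSAID]
    side_b: [NSAID]
    category: D
    require_distinct_substance: true
    consequence: "increased risk of gastrointestinal bleeding and renal failure"
  - rule_id: nsaid_gc
    display_name: "NSAIDs + GCs"
    side_a: [NSAID]
    side_b: [GC]
    category: C
    consequence: "increased risk of gastrointestinal bleeding"
  - rule_id: nsaid_ssri_snri
    display_name: "NSAIDs + SSRI/SNRI"
    side_a: [NSAID]
    side_b: [SSRI, SNRI]
    category: C
    consequence: "increased risk of gastrointestinal bleeding"
  - rule_id: nsaid_oac
    display_name: "NSAIDs + OACs"
    side_a: [NSAID]
    side_b: [OAC]
    category: C
    consequence: "increased risk of gastrointestinal bleeding"
  - rule_id: nsaid_antiplatelet
    display_name: "NSAIDs + Antiplatelet drugs"
    side_a: [NSAID]
    side_b: [ANTIPLATELET]
    category: C
    consequence: "increased risk of gastrointestinal bleeding"
  - rule_id: opioid_gabapentinoid
    display_name: "Opioids + Gabapentinoids"
    side_a: [OPIOID]
    side_b: [GABAPENTINOID]
    category: C
    consequence: "increased risk of respiratory depression"
  - rule_id: opioid_benzodiazepine
    display_name: "Opioids + Benzodiazepines"
    side_a: [OPIOID]
    side_b: [BENZODIAZEPINE]
    category: C
    consequence: "increased risk of respiratory depression"
  - rule_id: tramadol_ssri_snri
    display_name: "Tramadol + SSRIs/SNRIs"
    side_a: [TRAMADOL]
    side_b: [SSRI, SNRI]
    category: C
    min_daily_dose_mg: 200   # high-dose tramadol only
    consequence: "increased risk of seizures, arrhythmia and serotonin syndrome"
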