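rule_id,m1,m2,m3,m4,m5,m6,m7,m8,m9,m10,m11,m12
nsaid_antihypertensive,992914,290676,126927,69148,41074,26243,13719,8361,5784,4047,2888,1794
nsaid_nsaid,462379,51461,13501,5246,2639,1449,790,474,312,186,118,85
nsaid_gc,164826,25039,10222,5515,3292,2029,1078,623,386,248,149,97
nsaid_ssri_snri,45951,9739,3346,1637,893,486,244,135,95,72,50,18
nsaid_oac,34048,7775,2799,1201,459,191,63,30,6,4,4,2
nsaid_antiplatelet,15972,3542,1418,740,381,253,135,88,42,30,16,12
opioid_gabapentinoid,9470,3067,1553,1061,653,481,327,205,147,91,51,12
opioid_benzodiazepine,481,47,18,14,9,4,6,3,0,1,2,1
tramadol_ssri_snri,297,78,39,15,16,13,8,5,8,2,3,3
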