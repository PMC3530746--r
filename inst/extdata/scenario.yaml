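# Resident drinking-water ingestion scenario: population groups with size N,
# body weight BW (kg), intake rate IR (dm3/day), exposure duration ED (years)
# and averaging times AT (days; carcinogenic = 70-year lifetime, noncarcinogenic
# = ED in days), plus the scenario-wide context (fraction ingested FI, exposure
# frequency EF, averaging-time convention).
groups:
  children_0_6:
    size: 934
    bw_kg: 15
    ir_dm3_day: 0.3
    ed_years: 6
    at_cancer_days: 25550
    at_noncancer_days: 2190
  children_7_17:
    size: 2046
    bw_kg: 46
    ir_dm3_day: 1.0
    ed_years: 11
    at_cancer_days: 25550
    at_noncancer_days: 4015
  adults:
    size: 8140
    bw_kg: 70
    ir_dm3_day: 1.4
    ed_years: 30
    at_cancer_days: 25550
    at_noncancer_days: 10950
context:
  fi: 0.65
  ef: 365
  convention: epa_lifetime
  duration_matched_groups: [children_0_6, children_7_17]
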