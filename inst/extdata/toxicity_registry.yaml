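# Toxicity registry: oral slope factors SF0 (mg/(kg*day))^-1, chronic oral
# reference doses RfD and NOAELs (mg/(kg*day)), and US EPA carcinogen class.
# The PCB congener mixture is keyed SUM-PCB: one Aroclor-mixture slope factor
# applies to total PCBs. gamma-HCH carries a RAIS slope factor although EPA
# has not assigned it a carcinogen class.
analytes:
  SUM-PCB:
    name: Polychlorinated biphenyls
    class: PCB
    carcinogen_class: B2
    sf_oral: 2.0
    rfd: 2.0e-5
    noael: 0.007
  58-89-9:
    name: 1,2,3,4,5,6-Hexachlorocyclohexane (gamma-HCH)
    class: COP
    carcinogen_class: unclassified
    sf_oral: 1.10
    rfd: 3.0e-4
    noael: 0.33
  72-55-9:
    name: p,p'-Dichlorodiphenyldichloroethylene (DDE)
    class: COP
    carcinogen_class: B2
    sf_oral: 0.34
    rfd: 3.0e-3
  72-54-8:
    name: p,p'-Dichlorodiphenyl dichloroethane (DDD)
    class: COP
    carcinogen_class: B2
    sf_oral: 0.24
    rfd: 9.0e-3
  50-29-3:
    name: p,p'-Dichlorodiphenyltrichloroethane (DDT)
    class: COP
    carcinogen_class: B2
    sf_oral: 0.34
    rfd: 5.0e-4
    noael: 0.05
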