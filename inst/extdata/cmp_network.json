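{
  "comment": "Default central-metabolic-pathway network: 10 irreversible reactions over glycolysis, the pentose phosphate branch, lactate fermentation, the PDH link, TCA oxidation and ketogenesis. Six intermediates are pseudo-steady-state nodes; glucose, lactate, beta-HB and NADH are boundary-measured. Replace this file to use a different reconstruction.",
  "metabolites": [
    {"id": "glucose",   "name": "glucose",                    "role": "boundary_measured", "sign": -1},
    {"id": "G6P",       "name": "glucose-6-phosphate",        "role": "internal_pss"},
    {"id": "F6P",       "name": "fructose-6-phosphate",       "role": "internal_pss"},
    {"id": "GAP",       "name": "glyceraldehyde-3-phosphate", "role": "internal_pss"},
    {"id": "PEP",       "name": "phosphoenolpyruvate",        "role": "internal_pss"},
    {"id": "pyruvate",  "name": "pyruvate",                   "role": "internal_pss"},
    {"id": "acetyl_CoA","name": "acetyl-CoA",                 "role": "internal_pss"},
    {"id": "lactate",   "name": "lactate",                    "role": "boundary_measured", "sign": 1},
    {"id": "beta_HB",   "name": "beta-hydroxybutyrate",       "role": "boundary_measured", "sign": 1},
    {"id": "NADH",      "name": "NADH",                       "role": "boundary_measured", "sign": 1},
    {"id": "ppp_pool",  "name": "pentose phosphate pool",     "role": "sink_unmeasured"},
    {"id": "tca_out",   "name": "TCA end products",           "role": "sink_unmeasured"}
  ],
  "reactions": [
    {"id": "r1",  "substrates": [["glucose", 1]],                 "products": [["G6P", 1]],                    "pathway": "glycolysis",        "reversible": false},
    {"id": "r2",  "substrates": [["G6P", 1]],                     "products": [["F6P", 1]],                    "pathway": "glycolysis",        "reversible": false},
    {"id": "r3",  "substrates": [["G6P", 1]],                     "products": [["ppp_pool", 1]],               "pathway": "pentose_phosphate", "reversible": false},
    {"id": "r4",  "substrates": [["F6P", 1]],                     "products": [["GAP", 2]],                    "pathway": "glycolysis",        "reversible": false},
    {"id": "r5",  "substrates": [["GAP", 1]],                     "products": [["PEP", 1], ["NADH", 1]],       "pathway": "glycolysis",        "reversible": false},
    {"id": "r6",  "substrates": [["PEP", 1]],                     "products": [["pyruvate", 1]],               "pathway": "glycolysis",        "reversible": false},
    {"id": "r7",  "substrates": [["pyruvate", 1], ["NADH", 1]],   "products": [["lactate", 1]],                "pathway": "fermentation",      "reversible": false},
    {"id": "r8",  "substrates": [["pyruvate", 1]],                "products": [["acetyl_CoA", 1], ["NADH", 1]],"pathway": "other",             "reversible": false},
    {"id": "r9",  "substrates": [["acetyl_CoA", 1]],              "products": [["tca_out", 1], ["NADH", 3]],   "pathway": "TCA",               "reversible": false},
    {"id": "r10", "substrates": [["acetyl_CoA", 2], ["NADH", 1]], "products": [["beta_HB", 1]],                "pathway": "ketogenesis",       "reversible": false}
  ]
}
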