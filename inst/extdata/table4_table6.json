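{
  "n_reports": 1611,
  "consequent_count": 209,
  "consequent_label": "bradycardia",
  "cohort_drug": "dexmedetomidine",
  "literature_extra": 1050,
  "seed": 1,
  "pairs": [
    {"label": "syncope", "kind": "ade", "antecedent": 18, "joint": 11},
    {"label": "loss of consciousness", "kind": "ade", "antecedent": 27, "joint": 14},
    {"label": "cardiac arrest", "kind": "ade", "antecedent": 119, "joint": 44},
    {"label": "hypotension", "kind": "ade", "antecedent": 128, "joint": 46},
    {"label": "overdose", "kind": "ade", "antecedent": 33, "joint": 10},
    {"label": "drug interaction", "kind": "ade", "antecedent": 61, "joint": 17},
    {"label": "product administered to patient of inappropriate age", "kind": "ade", "antecedent": 47, "joint": 11},
    {"label": "cardio-respiratory arrest", "kind": "ade", "antecedent": 43, "joint": 10},
    {"label": "respiratory arrest", "kind": "ade", "antecedent": 74, "joint": 15},
    {"label": "lactated ringer's solution", "kind": "drug", "antecedent": 17, "joint": 12},
    {"label": "bupivacaine", "kind": "drug", "antecedent": 31, "joint": 12},
    {"label": "risperidone", "kind": "drug", "antecedent": 38, "joint": 12},
    {"label": "albuterol", "kind": "drug", "antecedent": 52, "joint": 13},
    {"label": "potassium chloride", "kind": "drug", "antecedent": 68, "joint": 14},
    {"label": "haloperidol", "kind": "drug", "antecedent": 83, "joint": 17},
    {"label": "sevoflurane", "kind": "drug", "antecedent": 107, "joint": 21}
  ]
}
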