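{
  "background_size": 13256,
  "list_size": 248,
  "seed": 1,
  "pathways": [
    {"name": "Ribosome", "size": 130, "overlap": 20},
    {"name": "Circadian rhythm", "size": 34, "overlap": 4},
    {"name": "Cardiac muscle contraction", "size": 87, "overlap": 8},
    {"name": "Oxidative phosphorylation", "size": 133, "overlap": 12},
    {"name": "Mitophagy-animal", "size": 68, "overlap": 6},
    {"name": "Acute myeloid leukemia", "size": 70, "overlap": 6},
    {"name": "Parkinson's disease", "size": 262, "overlap": 21},
    {"name": "Chemical carcinogenesis-reactive oxygen species", "size": 220, "overlap": 17},
    {"name": "Hypertrophic cardiomyopathy", "size": 91, "overlap": 7},
    {"name": "Coronavirus disease-COVID-19", "size": 235, "overlap": 18}
  ]
}
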