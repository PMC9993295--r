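{
  "drug_label": "ABC/3TC",
  "unit_strength_mg": 120,
  "adult_dose_mg": 600,
  "steps": [[120, "1"], [180, "1.5"], [240, "2"], [300, "2.5"],
            [360, "3"], [600, "adult"]]
}
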