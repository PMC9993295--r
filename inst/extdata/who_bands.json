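{
  "source": "WHO-2019",
  "resolution_kg": 0.1,
  "bands": [
    {"lower_kg": 3,  "upper_kg": 5.9,  "dose_mg": 120, "label": "1"},
    {"lower_kg": 6,  "upper_kg": 9.9,  "dose_mg": 180, "label": "1.5"},
    {"lower_kg": 10, "upper_kg": 13.9, "dose_mg": 240, "label": "2"},
    {"lower_kg": 14, "upper_kg": 19.9, "dose_mg": 300, "label": "2.5"},
    {"lower_kg": 20, "upper_kg": 24.9, "dose_mg": 360, "label": "3"},
    {"lower_kg": 25, "upper_kg": null, "dose_mg": 600, "label": "adult"}
  ]
}
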