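[
  {"notation": "A", "name": "chitosan type", "unit": "", "levels": ["ch1", "ch2", "ch3"]},
  {"notation": "B", "name": "pH value", "unit": "", "levels": ["5", "6", "7"]},
  {"notation": "C", "name": "chitosan dosage", "unit": "mg/L", "levels": ["45", "55", "65"]},
  {"notation": "D", "name": "rapid mixing", "unit": "rpm", "levels": ["250", "350", "450"]},
  {"notation": "E", "name": "slow mixing", "unit": "rpm", "levels": ["50", "100", "150"]}
]
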