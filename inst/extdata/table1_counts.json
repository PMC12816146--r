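{
  "description": "Printed full-sample counts from the published sample description of US dentists; used as inputs for worked-ratio checks.",
  "n_total": 56175,
  "counts": {
    "fqhc": 2591,
    "shortage": 679,
    "rural_shortage": 405,
    "male": 31007,
    "white": 37118,
    "general_practice": 43928,
    "phd_program": 24478
  },
  "printed_percent": {
    "fqhc": 4.6,
    "shortage": 1.2,
    "rural_shortage": 0.7,
    "male": 55.2,
    "white": 66.1,
    "general_practice": 78.2,
    "phd_program": 43.6
  }
}
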