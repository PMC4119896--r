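{
  "id": "table3",
  "description": "Stewart's duration class (rows) versus Ericson-Kurol difficulty class (cols), 105 impacted canines. Published counts with the published derived metrics.",
  "row_index": "Stewart",
  "col_index": "Ericson-Kurol",
  "rows": ["shorter", "longer"],
  "cols": ["easy", "difficult"],
  "counts": [[42, 36], [9, 18]],
  "positive_label": "easy",
  "reference": "cols",
  "printed": {
    "phi": 0.179,
    "phi_p": 0.303,
    "yates_chi2": 0.455,
    "yates_p": 0.500,
    "lr_positive": 1.235,
    "lr_negative": 0.529,
    "sensitivity": 0.824,
    "specificity": 0.333,
    "ppv": 0.538,
    "npv": 0.667
  }
}
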