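{
  "id": "table2",
  "description": "Treatment-difficulty dichotomies, KPG index (rows) versus Ericson-Kurol sector class (cols), 105 impacted canines. Published counts with the published derived metrics.",
  "row_index": "KPG",
  "col_index": "Ericson-Kurol",
  "rows": ["easy", "difficult"],
  "cols": ["easy", "difficult"],
  "counts": [[48, 30], [3, 24]],
  "positive_label": "easy",
  "reference": "cols",
  "printed": {
    "phi": 0.441,
    "phi_p": 0.008,
    "yates_chi2": 4.937,
    "yates_p": 0.026,
    "lr_positive": 1.694,
    "lr_negative": 0.132,
    "sensitivity": 0.941,
    "specificity": 0.444,
    "ppv": 0.615,
    "npv": 0.889
  }
}
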