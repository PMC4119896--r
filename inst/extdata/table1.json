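{
  "id": "table1",
  "description": "Treatment-duration dichotomies, KPG index (rows) versus Stewart's cusp-to-occlusal-plane distance (cols), 105 impacted canines. Published counts with the published derived metrics.",
  "row_index": "KPG",
  "col_index": "Stewart",
  "rows": ["shorter", "longer"],
  "cols": ["shorter", "longer"],
  "counts": [[66, 12], [12, 15]],
  "positive_label": "shorter",
  "reference": "cols",
  "printed": {
    "phi": 0.402,
    "phi_p": 0.017,
    "yates_chi2": 3.741,
    "yates_p": 0.053,
    "lr_positive": 1.904,
    "lr_negative": 0.277,
    "sensitivity": 0.846,
    "specificity": 0.556,
    "ppv": 0.846,
    "npv": 0.556
  }
}
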