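{
  "seed": 42,
  "tol_ppm": 5,
  "nce": [35, 75],
  "simulate": {
    "sample_id": "demo",
    "noise": {"mz_jitter_ppm": 1, "intensity_cv": 0.05, "baseline": 0},
    "formulas": [
      {
        "formula": "C14H14O6", "rt": 6.2, "width": 0.3, "height": 1000000,
        "parent_35": 0.1, "fg_co2_35": 0.15, "fg_co2_h2o_35": 0.05,
        "backbone_35": 0.3, "radical_35": 0.3, "halogen_35": 0.05,
        "parent_75": 0.0, "fg_co2_75": 0.0, "fg_co2_h2o_75": 0.0,
        "backbone_75": 0.05, "radical_75": 0.9, "halogen_75": 0.05
      },
      {
        "formula": "C10H16O6", "rt": 3.1, "width": 0.25, "height": 800000,
        "parent_35": 0.3, "fg_co2_35": 0.4, "fg_co2_h2o_35": 0.2,
        "backbone_35": 0.1, "radical_35": 0.0, "halogen_35": 0.0,
        "parent_75": 0.0, "fg_co2_75": 0.05, "fg_co2_h2o_75": 0.05,
        "backbone_75": 0.9, "radical_75": 0.0, "halogen_75": 0.0
      }
    ]
  },
  "compounds": [
    {"compound_id": "demo-aromatic", "formula": "C14H14O6", "rt": 6.2},
    {"compound_id": "demo-aliphatic", "formula": "C10H16O6", "rt": 2.8},
    {"compound_id": "demo-aliphatic", "formula": "C10H16O6", "rt": 3.4}
  ]
}
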