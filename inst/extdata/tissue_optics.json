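{
  "comment": "Optical and geometric constants for the six-layer volar fingertip model. Lengths in mm, coefficients in cm^-1, wavelengths in nm.",
  "wavelengths": [515, 660, 880],
  "ages": [23, 34.4, 44.8, 55],
  "vfm_grid": [0.03, 0.10, 0.20, 0.30],
  "epidermis": {
    "thickness_mm": 0.55,
    "mus": {"515": 388.35, "660": 303.03, "880": 227.27},
    "mua_printed_by_vfm": {
      "515": {"0.03": 1.96, "0.1": 6.28, "0.2": 12.43, "0.3": 18.58},
      "660": {"0.03": 0.86, "0.1": 2.75, "0.2": 5.44, "0.3": 8.13},
      "880": {"0.03": 0.33, "0.1": 1.06, "0.2": 2.09, "0.3": 3.13}
    }
  },
  "melanin": {"scale": 6.6e10, "exponent": -3.33, "calibration_vfm": 0.03},
  "dermis": {
    "total_anchor_mm": 0.75,
    "anchor_age": 61,
    "thinning_mm_per_year": 0.0044,
    "fractions": {
      "papillary_dermis": 0.082,
      "upper_blood_net": 0.0437,
      "reticular_dermis": 0.8197,
      "deep_blood_net": 0.0546
    },
    "mus": {"515": 389.99, "660": 208.65, "880": 118.94},
    "mua": {
      "papillary_dermis": {
        "rest":  {"515": 1.2166, "660": 0.5249, "880": 0.2344},
        "pulse": {"515": 1.2202, "660": 0.5250, "880": 0.2346}
      },
      "upper_blood_net": {
        "rest":  {"515": 1.5328, "660": 0.5398, "880": 0.2546},
        "pulse": {"515": 1.5593, "660": 0.5410, "880": 0.2558}
      },
      "reticular_dermis": {
        "rest":  {"515": 1.2167, "660": 0.5256, "880": 0.2456},
        "pulse": {"515": 1.2202, "660": 0.5257, "880": 0.2458}
      },
      "deep_blood_net": {
        "rest":  {"515": 1.2896, "660": 0.5288, "880": 0.2462},
        "pulse": {"515": 1.2985, "660": 0.5292, "880": 0.2466}
      }
    },
    "thickness_printed_mm": {
      "papillary_dermis": {"23": 0.075, "34.4": 0.071, "44.8": 0.067, "55": 0.064},
      "upper_blood_net":  {"23": 0.04,  "34.4": 0.038, "44.8": 0.036, "55": 0.033},
      "reticular_dermis": {"23": 0.75,  "34.4": 0.71,  "44.8": 0.67,  "55": 0.64},
      "deep_blood_net":   {"23": 0.05,  "34.4": 0.05,  "44.8": 0.04,  "55": 0.04}
    }
  },
  "subcutis": {
    "thickness_mm": 2.0,
    "mua": {"515": 6.0798, "660": 0.2827, "880": 0.3195},
    "mus": {"515": 336.18, "660": 249.74, "880": 191.53}
  },
  "pulse_blood_factor": {"23": 1.124, "34.4": 1.099, "44.8": 1.083, "55": 1.073},
  "anisotropy_g": 0.9,
  "n_tissue": 1.4,
  "n_ambient": 1.0
}
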