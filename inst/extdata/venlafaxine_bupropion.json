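{
  "description": "Six-compound venlafaxine/bupropion system: physicochemistry, extended-release Weibull dissolution, Michaelis-Menten metabolism with CYP2D6 competitive inhibition by the bupropion family, and renal clearances.",
  "units": {
    "mr": "g/mol",
    "km": "uM",
    "kcat": "1/min",
    "clint": "1/min",
    "ki": "uM",
    "renal_clearance": "L_h_kg",
    "t_diss50": "min",
    "t_lag": "min",
    "solubility": "mg/mL"
  },
  "cyp2d6_phenotype": "nd",
  "compounds": {
    "VEN": {
      "mr": 277.4, "logp": 2.62,
      "pka_entries": [{"value": 9.4, "kind": "base"}],
      "fu_plasma": 0.73, "solubility": 572,
      "partition_method": "berezhkovskiy", "blood_plasma_ratio": 1.0
    },
    "ODV": {
      "mr": 263.38, "logp": 2.45,
      "pka_entries": [{"value": 8.86, "kind": "base"}, {"value": 10.25, "kind": "acid"}],
      "fu_plasma": 0.70,
      "partition_method": "berezhkovskiy", "blood_plasma_ratio": 1.0
    },
    "BUP": {
      "mr": 239.74, "logp": 3.5,
      "pka_entries": [{"value": 7.9, "kind": "base"}],
      "fu_plasma": 0.16, "solubility": 312,
      "partition_method": "schmitt", "blood_plasma_ratio": 1.0
    },
    "OHB": {
      "mr": 255.74, "logp": 1.98,
      "pka_entries": [{"value": 7.7, "kind": "base"}],
      "fu_plasma": 0.23,
      "partition_method": "rodgers_rowland", "blood_plasma_ratio": 1.0
    },
    "EHB": {
      "mr": 241.76, "logp": 2.69,
      "pka_entries": [{"value": 9.6, "kind": "base"}],
      "fu_plasma": 0.58,
      "partition_method": "berezhkovskiy",
      "cell_permeability": "charge_dependent_schmitt", "blood_plasma_ratio": 1.0
    },
    "THB": {
      "mr": 241.76, "logp": 2.69,
      "pka_entries": [{"value": 9.6, "kind": "base"}],
      "fu_plasma": 0.58,
      "partition_method": "berezhkovskiy",
      "cell_permeability": "charge_dependent_schmitt", "blood_plasma_ratio": 1.0
    }
  },
  "formulations": {
    "VEN": {"t_diss50": 338, "t_lag": 81.2, "shape_b": 0.92},
    "BUP": {"t_diss50": 170, "t_lag": 0, "shape_b": 1.52}
  },
  "processes": [
    {"enzyme": "CYP2D6", "substrate": "VEN", "product": "ODV",
     "kcat": 29.16, "km": 23.2,
     "kcat_by_phenotype": {"nd": 29.16, "em": 64.8, "pm": 0},
     "vmax_reported": 6.48, "vmax_unit": "pmol/min/pmol"},
    {"enzyme": "CYP2C9", "substrate": "VEN", "product": "ODV",
     "kcat": 2.61, "km": 3119,
     "vmax_reported": 0.58, "vmax_unit": "pmol/min/pmol"},
    {"enzyme": "CYP2C19", "substrate": "VEN", "product": "ODV",
     "kcat": 17.01, "km": 293,
     "vmax_reported": 3.78, "vmax_unit": "pmol/min/pmol"},
    {"enzyme": "CYP3A4", "substrate": "VEN", "product": "SINK",
     "kcat": 5.54, "km": 556,
     "vmax_reported": 1.23, "vmax_unit": "pmol/min/pmol"},
    {"enzyme": "CYP2C9", "substrate": "VEN", "product": "SINK",
     "kcat": 46.49, "km": 2250,
     "vmax_reported": 10.33, "vmax_unit": "pmol/min/pmol"},
    {"enzyme": "CYP2C19", "substrate": "VEN", "product": "SINK",
     "kcat": 34.02, "km": 398,
     "vmax_reported": 7.56, "vmax_unit": "pmol/min/pmol"},
    {"enzyme": "UGT1A1", "substrate": "ODV", "product": "SINK",
     "clint": 0.1},
    {"enzyme": "CYP2B6", "substrate": "BUP", "product": "OHB",
     "kcat": 92.9, "km": 89, "km_sd": 14,
     "vmax_reported": 3623, "vmax_sd": 1520, "vmax_unit": "pmol/min/mg"},
    {"enzyme": "HSD11B1", "substrate": "BUP", "product": "THB",
     "kcat": 102.7, "km": 42.2, "km_sd": 3.05,
     "vmax_reported": 11800, "vmax_sd": 265, "vmax_unit": "pmol/min/mg"},
    {"enzyme": "HSD11B1", "substrate": "BUP", "product": "EHB",
     "kcat": 38.46, "km": 66.5, "km_sd": 19.9,
     "vmax_reported": 661, "vmax_sd": 54, "vmax_unit": "pmol/min/mg"},
    {"enzyme": "UGT2B7", "substrate": "OHB", "product": "SINK",
     "kcat": 33.81, "km": 488, "km_sd": 98.3,
     "vmax_reported": 5550, "vmax_sd": 507, "vmax_unit": "pmol/min/mg"},
    {"enzyme": "UGT2B7", "substrate": "OHB", "product": "SINK",
     "kcat": 5.27, "km": 172, "km_sd": 38.9,
     "vmax_reported": 739, "vmax_sd": 59.6, "vmax_unit": "pmol/min/mg"},
    {"enzyme": "CYP2C19", "substrate": "THB", "product": "SINK",
     "kcat": 1.10, "km": 13.0,
     "vmax_reported": 0.55, "vmax_unit": "pmol/min/pmol"},
    {"enzyme": "UGT1A9", "substrate": "THB", "product": "SINK",
     "kcat": 38.1, "km": 343, "km_sd": 37.5,
     "vmax_reported": 3290, "vmax_sd": 269, "vmax_unit": "pmol/min/mg"},
    {"enzyme": "UGT2B7", "substrate": "THB", "product": "SINK",
     "kcat": 4.14, "km": 248, "km_sd": 27.1,
     "vmax_reported": 358, "vmax_sd": 25.5, "vmax_unit": "pmol/min/mg"},
    {"enzyme": "CYP2C19", "substrate": "EHB", "product": "SINK",
     "kcat": 0.80, "km": 39.0,
     "vmax_reported": 0.40, "vmax_unit": "pmol/min/pmol"},
    {"enzyme": "UGT2B7", "substrate": "EHB", "product": "SINK",
     "kcat": 52.8, "km": 360, "km_sd": 55.2,
     "vmax_reported": 2280, "vmax_sd": 241, "vmax_unit": "pmol/min/mg"},
    {"enzyme": "UGT2B7", "substrate": "EHB", "product": "SINK",
     "kcat": 40.3, "km": 373, "km_sd": 63.0,
     "vmax_reported": 1740, "vmax_sd": 212, "vmax_unit": "pmol/min/mg"}
  ],
  "inhibitions": [
    {"inhibitor": "BUP", "enzyme": "CYP2D6", "ki": 0.46, "mechanism": "competitive"},
    {"inhibitor": "OHB", "enzyme": "CYP2D6", "ki": 0.41, "mechanism": "competitive"},
    {"inhibitor": "THB", "enzyme": "CYP2D6", "ki": 0.15, "mechanism": "competitive"},
    {"inhibitor": "EHB", "enzyme": "CYP2D6", "ki": 0.04, "mechanism": "competitive"}
  ],
  "renal": {
    "VEN": {"value": 0.05, "sd": 0.02},
    "ODV": {"value": 0.12, "sd": 0.03},
    "BUP": {"value": 0.17, "min": 0.12, "max": 0.21},
    "OHB": {"value": 0.02, "min": 0.02, "max": 0.03},
    "EHB": {"value": 0.50, "min": 0.39, "max": 0.61},
    "THB": {"value": 0.36, "min": 0.28, "max": 0.45}
  },
  "enzyme_reference_abundance": {
    "CYP2D6": 0.44, "CYP2C9": 2.3, "CYP2C19": 2.3, "CYP3A4": 2.3,
    "CYP2B6": 0.30, "HSD11B1": 1.0, "UGT1A1": 2.15, "UGT1A9": 0.10,
    "UGT2B7": 0.02
  },
  "inhibitor_potency": 1.0
}
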