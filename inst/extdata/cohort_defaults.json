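{
  "comment": "Default synthetic-cohort parameters: per-group sector choroidal-thickness means/SDs (um), axial-length mean/SD (mm), uniform refractive-error sampling ranges (D). Superior/inferior sectors are the mean of the same-ring nasal and temporal entries (not reported separately in the source table).",
  "low": {
    "n_eyes": 20,
    "sector_mean": {"Fovea": 273.85, "NIM": 239.64, "SIM": 250.395, "TIM": 261.15, "IIM": 250.395, "NOM": 180.65, "SOM": 207.45, "TOM": 234.25, "IOM": 207.45},
    "sector_sd":   {"Fovea": 49.01,  "NIM": 57.93,  "SIM": 54.775,  "TIM": 51.62,  "IIM": 54.775,  "NOM": 58.25,  "SOM": 50.26,  "TOM": 42.27,  "IOM": 50.26},
    "iol_mean": 24.619, "iol_sd": 0.016,
    "refractive_range": [-3.0, -0.25]
  },
  "moderate": {
    "n_eyes": 10,
    "sector_mean": {"Fovea": 180.0, "NIM": 139.96, "SIM": 167.45, "TIM": 194.94, "IIM": 167.45, "NOM": 100.84, "SOM": 142.07, "TOM": 183.3, "IOM": 142.07},
    "sector_sd":   {"Fovea": 28.25, "NIM": 31.53,  "SIM": 29.655, "TIM": 27.78,  "IIM": 29.655, "NOM": 16.75,  "SOM": 20.565, "TOM": 24.38, "IOM": 20.565},
    "iol_mean": 25.413, "iol_sd": 0.022,
    "refractive_range": [-5.75, -3.25]
  },
  "high": {
    "n_eyes": 10,
    "sector_mean": {"Fovea": 139.54, "NIM": 105.02, "SIM": 133.235, "TIM": 161.45, "IIM": 133.235, "NOM": 86.64, "SOM": 124.82, "TOM": 163.0, "IOM": 124.82},
    "sector_sd":   {"Fovea": 32.68,  "NIM": 34.14,  "SIM": 29.685,  "TIM": 25.23,  "IIM": 29.685,  "NOM": 42.6,  "SOM": 38.745, "TOM": 34.89, "IOM": 38.745},
    "iol_mean": 25.983, "iol_sd": 0.021,
    "refractive_range": [-9.0, -6.0]
  }
}
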