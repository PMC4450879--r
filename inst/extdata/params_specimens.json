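{
  "1":    {"RMS": 0.699, "E1": 0.017, "E2": 0.233, "k1": 38.49, "k2": 29.61, "eta": 582.01,  "k0": 3.96e-07, "Mk": 0.21,  "Em": 0.56, "num": 0.24},
  "2":    {"RMS": 0.834, "E1": 0.074, "E2": 1.683, "k1": 44.91, "k2": 25.97, "eta": 1103.10, "k0": 5.87e-10, "Mk": 0.59,  "Em": 0.57, "num": 0.21},
  "3":    {"RMS": 0.869, "E1": 0.017, "E2": 0.380, "k1": 44.95, "k2": 35.78, "eta": 595.58,  "k0": 1.82e-07, "Mk": 0.67,  "Em": 0.70, "num": 0.40},
  "4":    {"RMS": 0.421, "E1": 0.648, "E2": 6.251, "k1": 25.85, "k2": 9.14,  "eta": 336.59,  "k0": 7.65e-10, "Mk": 0.45,  "Em": 1.00, "num": 0.49},
  "5":    {"RMS": 0.854, "E1": 0.023, "E2": 0.452, "k1": 48.50, "k2": 37.01, "eta": 943.17,  "k0": 5.47e-10, "Mk": 0.55,  "Em": 0.56, "num": 0.14},
  "6":    {"RMS": 1.021, "E1": 0.003, "E2": 0.030, "k1": 36.13, "k2": 38.03, "eta": 537.40,  "k0": 1.39e-09, "Mk": 1.40,  "Em": 0.59, "num": 0.34},
  "7":    {"RMS": 0.819, "E1": 0.027, "E2": 3.001, "k1": 42.81, "k2": 16.50, "eta": 484.60,  "k0": 3.04e-08, "Mk": 0.001, "Em": 0.70, "num": 0.44},
  "8":    {"RMS": 0.920, "E1": 0.001, "E2": 0.054, "k1": 44.54, "k2": 34.45, "eta": 770.67,  "k0": 6.22e-10, "Mk": 0.78,  "Em": 0.65, "num": 0.20},
  "9":    {"RMS": 0.731, "E1": 0.022, "E2": 0.452, "k1": 42.96, "k2": 31.86, "eta": 897.18,  "k0": 1.39e-07, "Mk": 0.47,  "Em": 0.95, "num": 0.19},
  "mean": {"E1": 0.092, "E2": 1.393, "k1": 41.02, "k2": 28.71, "eta": 694.48, "k0": 8.34e-08, "Mk": 0.57, "Em": 0.70, "num": 0.29},
  "SD":   {"E1": 0.209, "E2": 2.063, "k1": 6.77,  "k2": 9.93,  "eta": 248.73, "k0": 1.36e-07, "Mk": 0.39, "Em": 0.17, "num": 0.13},
  "CV":   {"E1": 2.26,  "E2": 1.48,  "k1": 0.16,  "k2": 0.35,  "eta": 0.36,   "k0": 1.63,     "Mk": 0.68, "Em": 0.24, "num": 0.43}
}
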