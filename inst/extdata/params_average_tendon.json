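{
  "1-3":   {"RMS": 0.837, "E1": 0.023, "E2": 0.443, "k1": 40.00, "k2": 31.06,
            "eta": 609.34, "k0": 1.19e-07, "Mk": 0.96, "Em": 0.77, "num": 0.35},
  "10-12": {"RMS": 0.413, "E1": 0.024, "E2": 7.009, "k1": 38.00, "k2": 11.63,
            "eta": 413.23, "k0": 1.75e-09, "Mk": 0.84, "Em": 0.37, "num": 0.17}
}
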