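{
  "description": "Synthetic alpha-rhythm subject: hand-tuned Liley model parameter set, selected by scanning the physiological bounds for a single weakly stable fixed point whose noise-driven output has its normalised power-spectral peak in the 8-13 Hz alpha band. Not derived from any real recording.",
  "synthetic": true,
  "verified_psd_peak_hz_range": [8.5, 11.0],
  "fixed_point": {
    "stable": true,
    "dominant_eigenvalue_real_per_ms": -0.0055,
    "dominant_eigenfrequency_hz": 10.68
  },
  "default_seed": 11,
  "params": {
    "he_rest": -76.2,
    "hi_rest": -64.3,
    "N_ee": 3397,
    "N_ei": 3946,
    "N_ie": 132,
    "N_ii": 347,
    "Gamma_e": 1.23,
    "Gamma_i": 1.91,
    "gamma_e": 0.203,
    "gamma_i": 0.067,
    "tau_e": 96.7,
    "tau_i": 138.6,
    "Se_max": 0.49,
    "Si_max": 0.41,
    "mu_e": -40.1,
    "mu_i": -54.7,
    "sigma_e": 4.89,
    "sigma_i": 5.13,
    "he_eq": -18.8,
    "hi_eq": -70.3,
    "p_ee": 8.59,
    "p_ei": 2.14,
    "xi": 9.9
  }
}
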