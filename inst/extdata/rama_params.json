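{
  "comment": "Synthetic Ramachandran reference distributions: wrapped-Gaussian mixtures on the (phi, psi) torus approximating the favoured regions of high-quality structures. Each mode has a centre (deg), isotropic width sigma (deg) and a mixture weight. Tables are expanded on a 5-degree grid and normalized to integrate to 1; they are pluggable stand-ins, not empirical tables.",
  "grid_step": 5,
  "tables": {
    "general": [
      {"phi": -63, "psi": -43, "sigma": 14, "weight": 0.44},
      {"phi": -120, "psi": 130, "sigma": 22, "weight": 0.38},
      {"phi": -90, "psi": 170, "sigma": 20, "weight": 0.08},
      {"phi": 57, "psi": 40, "sigma": 12, "weight": 0.10}
    ],
    "glycine": [
      {"phi": 82, "psi": 8, "sigma": 22, "weight": 0.28},
      {"phi": -82, "psi": -8, "sigma": 22, "weight": 0.28},
      {"phi": -62, "psi": -41, "sigma": 18, "weight": 0.16},
      {"phi": 62, "psi": 41, "sigma": 18, "weight": 0.16},
      {"phi": 90, "psi": 180, "sigma": 25, "weight": 0.06},
      {"phi": -90, "psi": 180, "sigma": 25, "weight": 0.06}
    ],
    "proline": [
      {"phi": -61, "psi": -35, "sigma": 12, "weight": 0.45},
      {"phi": -60, "psi": 150, "sigma": 15, "weight": 0.55}
    ]
  }
}
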