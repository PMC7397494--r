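{
  "comment": "Synthetic rotamer library: per-chi preferred modes (deg) with frequencies. Full rotamers are formed as the Cartesian product of per-chi modes with product frequencies, except where an explicit 'rotamers' list is given. This is a smooth approximation to empirical rotamer tables, documented as a pluggable stand-in.",
  "types": {
    "SER": {"chi_modes": [[{"angle": 64, "freq": 0.48}, {"angle": -63, "freq": 0.29}, {"angle": 180, "freq": 0.23}]]},
    "CYS": {"chi_modes": [[{"angle": -65, "freq": 0.55}, {"angle": -177, "freq": 0.26}, {"angle": 63, "freq": 0.19}]]},
    "THR": {"chi_modes": [[{"angle": 62, "freq": 0.49}, {"angle": -61, "freq": 0.43}, {"angle": -175, "freq": 0.08}]]},
    "VAL": {"chi_modes": [[{"angle": 175, "freq": 0.73}, {"angle": -60, "freq": 0.20}, {"angle": 64, "freq": 0.07}]]},
    "LEU": {"chi_modes": [[{"angle": -65, "freq": 0.59}, {"angle": -177, "freq": 0.29}, {"angle": 62, "freq": 0.12}],
                           [{"angle": 175, "freq": 0.62}, {"angle": 65, "freq": 0.29}, {"angle": -70, "freq": 0.09}]]},
    "ILE": {"chi_modes": [[{"angle": -65, "freq": 0.62}, {"angle": -177, "freq": 0.21}, {"angle": 62, "freq": 0.17}],
                           [{"angle": 170, "freq": 0.60}, {"angle": -60, "freq": 0.28}, {"angle": 66, "freq": 0.12}]]},
    "ASP": {"chi_modes": [[{"angle": -70, "freq": 0.52}, {"angle": -177, "freq": 0.31}, {"angle": 62, "freq": 0.17}],
                           [{"angle": -15, "freq": 0.55}, {"angle": 30, "freq": 0.45}]]},
    "ASN": {"chi_modes": [[{"angle": -68, "freq": 0.53}, {"angle": -177, "freq": 0.29}, {"angle": 62, "freq": 0.18}],
                           [{"angle": -20, "freq": 0.42}, {"angle": 30, "freq": 0.33}, {"angle": -75, "freq": 0.25}]]},
    "GLU": {"chi_modes": [[{"angle": -67, "freq": 0.56}, {"angle": -177, "freq": 0.29}, {"angle": 63, "freq": 0.15}],
                           [{"angle": 180, "freq": 0.53}, {"angle": -65, "freq": 0.29}, {"angle": 65, "freq": 0.18}],
                           [{"angle": -10, "freq": 0.54}, {"angle": 30, "freq": 0.46}]]},
    "GLN": {"chi_modes": [[{"angle": -67, "freq": 0.56}, {"angle": -177, "freq": 0.29}, {"angle": 63, "freq": 0.15}],
                           [{"angle": 180, "freq": 0.52}, {"angle": -65, "freq": 0.30}, {"angle": 65, "freq": 0.18}],
                           [{"angle": 0, "freq": 0.40}, {"angle": 65, "freq": 0.31}, {"angle": -65, "freq": 0.29}]]},
    "LYS": {"chi_modes": [[{"angle": -67, "freq": 0.57}, {"angle": -177, "freq": 0.28}, {"angle": 62, "freq": 0.15}],
                           [{"angle": 180, "freq": 0.60}, {"angle": -68, "freq": 0.25}, {"angle": 65, "freq": 0.15}],
                           [{"angle": 180, "freq": 0.62}, {"angle": -68, "freq": 0.23}, {"angle": 65, "freq": 0.15}],
                           [{"angle": 180, "freq": 0.64}, {"angle": -65, "freq": 0.21}, {"angle": 65, "freq": 0.15}]]},
    "ARG": {"chi_modes": [[{"angle": -67, "freq": 0.57}, {"angle": -177, "freq": 0.28}, {"angle": 62, "freq": 0.15}],
                           [{"angle": 180, "freq": 0.58}, {"angle": -67, "freq": 0.26}, {"angle": 65, "freq": 0.16}],
                           [{"angle": 180, "freq": 0.56}, {"angle": -65, "freq": 0.27}, {"angle": 65, "freq": 0.17}],
                           [{"angle": 85, "freq": 0.40}, {"angle": 180, "freq": 0.35}, {"angle": -85, "freq": 0.25}]]},
    "MET": {"chi_modes": [[{"angle": -67, "freq": 0.56}, {"angle": -177, "freq": 0.28}, {"angle": 63, "freq": 0.16}],
                           [{"angle": 180, "freq": 0.50}, {"angle": -65, "freq": 0.32}, {"angle": 65, "freq": 0.18}],
                           [{"angle": -65, "freq": 0.40}, {"angle": 177, "freq": 0.35}, {"angle": 65, "freq": 0.25}]]},
    "HIS": {"chi_modes": [[{"angle": -65, "freq": 0.55}, {"angle": -177, "freq": 0.28}, {"angle": 62, "freq": 0.17}],
                           [{"angle": -75, "freq": 0.52}, {"angle": 78, "freq": 0.48}]]},
    "PHE": {"chi_modes": [[{"angle": -66, "freq": 0.57}, {"angle": -177, "freq": 0.30}, {"angle": 62, "freq": 0.13}],
                           [{"angle": 90, "freq": 0.55}, {"angle": -85, "freq": 0.45}]]},
    "TYR": {"chi_modes": [[{"angle": -66, "freq": 0.57}, {"angle": -177, "freq": 0.30}, {"angle": 62, "freq": 0.13}],
                           [{"angle": 90, "freq": 0.55}, {"angle": -85, "freq": 0.45}]]},
    "TRP": {"chi_modes": [[{"angle": -67, "freq": 0.55}, {"angle": -177, "freq": 0.29}, {"angle": 62, "freq": 0.16}],
                           [{"angle": 95, "freq": 0.55}, {"angle": -90, "freq": 0.45}]]},
    "PRO": {"rotamers": [{"chi": [30, -35], "freq": 0.55}, {"chi": [-27, 34], "freq": 0.45}]}
  }
}
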