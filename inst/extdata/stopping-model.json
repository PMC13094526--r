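{
  "name": "Power-law range-energy model R(E) = a * E^p (E in MeV, R in um)",
  "data_version": "1.0",
  "notes": "Coefficients fitted against published CSDA range tables: ASTAR-type alpha ranges in liquid water (anchors ~41 um at 5.49 MeV, ~74 um at 8 MeV) and in gold via a Bragg-Kleeman density/mass scaling factor of 0.222; SRIM-type heavy-ion path lengths for ~100-140 keV Rn/Po/Pb/Tl recoils (~19 nm in gold, ~88 nm in water at 104 keV); ESTAR-type electron CSDA ranges at the mean beta energies (anchors 143 um at 0.1 MeV, 1770 um at 0.5 MeV in water). Fit residuals against the anchor tables are below 5% for alphas over 4-8 MeV and recoils over 0.05-0.2 MeV, and below 20% for electrons over 0.1-1 MeV (electrons contribute negligibly to nm-scale shell deposits). Energies outside the validity window are clamped to the window edge with a warning.",
  "coefficients": [
    {"kind": "alpha",    "material": "water", "a": 3.14,   "p": 1.51,  "valid_MeV": [0.05, 10]},
    {"kind": "alpha",    "material": "gold",  "a": 0.70,   "p": 1.51,  "valid_MeV": [0.05, 10]},
    {"kind": "recoil",   "material": "water", "a": 0.562,  "p": 0.82,  "valid_MeV": [0.02, 0.3]},
    {"kind": "recoil",   "material": "gold",  "a": 0.0982, "p": 0.737, "valid_MeV": [0.02, 0.3]},
    {"kind": "beta",     "material": "water", "a": 5238,   "p": 1.563, "valid_MeV": [0.05, 2]},
    {"kind": "beta",     "material": "gold",  "a": 367,    "p": 1.563, "valid_MeV": [0.05, 2]}
  ]
}
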