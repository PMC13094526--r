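{
  "name": "Ra-223 decay chain (linear, main branches)",
  "data_version": "1.0",
  "source": "Half-lives and emission energies from standard nuclear-data compilations (ENSDF / ICRP Publication 107 style rounded values); the parent half-life uses the value printed on the clinical product label (11.4 d). The <1% Bi-211 beta branch is ignored; the chain is modelled as strictly linear. Recoil energies are not stored: they are computed at load time from alpha energies and daughter mass numbers as E_alpha * 4 / A_daughter.",
  "nuclides": [
    {
      "name": "Ra-223",
      "half_life_s": 984960,
      "mass_number": 223,
      "gamma_energy_keV": 133,
      "emissions": [
        {"kind": "alpha", "energy_keV": 5716, "probability": 1.0}
      ]
    },
    {
      "name": "Rn-219",
      "half_life_s": 3.96,
      "mass_number": 219,
      "gamma_energy_keV": 58,
      "emissions": [
        {"kind": "alpha", "energy_keV": 6819, "probability": 1.0}
      ]
    },
    {
      "name": "Po-215",
      "half_life_s": 0.001781,
      "mass_number": 215,
      "gamma_energy_keV": 0.2,
      "emissions": [
        {"kind": "alpha", "energy_keV": 7386, "probability": 1.0}
      ]
    },
    {
      "name": "Pb-211",
      "half_life_s": 2166,
      "mass_number": 211,
      "gamma_energy_keV": 64,
      "emissions": [
        {"kind": "beta", "energy_keV": 455, "probability": 1.0}
      ]
    },
    {
      "name": "Bi-211",
      "half_life_s": 128.4,
      "mass_number": 211,
      "gamma_energy_keV": 47,
      "emissions": [
        {"kind": "alpha", "energy_keV": 6623, "probability": 1.0}
      ]
    },
    {
      "name": "Tl-207",
      "half_life_s": 286.2,
      "mass_number": 207,
      "gamma_energy_keV": 2,
      "emissions": [
        {"kind": "beta", "energy_keV": 493, "probability": 1.0}
      ]
    },
    {
      "name": "Pb-207",
      "half_life_s": null,
      "mass_number": 207,
      "gamma_energy_keV": 0,
      "emissions": []
    }
  ]
}
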