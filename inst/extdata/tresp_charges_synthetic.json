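{
  "CHL_A": {
    "atoms": {
      "MG": 0.0, "NA": 0.0, "NC": 0.0,
      "NB": 0.25, "ND": -0.25,
      "C1B": 0.10, "C4B": 0.10, "C1D": -0.10, "C4D": -0.10,
      "CHA": 0.06, "CHB": 0.06, "CHC": -0.06, "CHD": -0.06,
      "C1A": 0.05, "C4A": -0.05, "C1C": 0.05, "C4C": -0.05
    },
    "target_dipole_D": 4.0,
    "provenance": "SYNTHETIC dipole-faithful pseudo-chlorin Qy charge set constructed for this package: macrocycle atom charges are mirror-symmetric in x and antisymmetric in y, so the monopole and all quadrupole moments vanish and the set converges rapidly to its point dipole in the far field. Not derived from quantum chemistry. Rescaled on assignment to an effective in-protein dipole of 4.0 D (chlorophyll a Qy)."
  },
  "CHL_C": {
    "atoms": {
      "MG": 0.0, "NA": 0.0, "NC": 0.0,
      "NB": 0.25, "ND": -0.25,
      "C1B": 0.10, "C4B": 0.10, "C1D": -0.10, "C4D": -0.10,
      "CHA": 0.06, "CHB": 0.06, "CHC": -0.06, "CHD": -0.06,
      "C1A": 0.05, "C4A": -0.05, "C1C": 0.05, "C4C": -0.05
    },
    "target_dipole_D": 3.5,
    "provenance": "SYNTHETIC pseudo-chlorin Qy charge set (see CHL_A); chlorophyll c shares the macrocycle atom set (no phytol atoms are used). Effective dipole 3.5 D reflects the weaker chlorophyll-c Qy transition."
  }
}
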