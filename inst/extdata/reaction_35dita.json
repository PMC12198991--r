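{
  "comment": "Gas-phase condensation 2 TMA + 3,5-DABA -> 3,5-DITA + 2 H2O; drS_J_molK is the literature reaction entropy at 298.15 K (per-species formation entropies of TMA, DABA and H2O are not tabulated here).",
  "stoichiometry": {"TMA": -2, "3,5-DABA": -1, "3,5-DITA": 1, "H2O": 2},
  "T": 298.15,
  "drS_J_molK": -44.72
}
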