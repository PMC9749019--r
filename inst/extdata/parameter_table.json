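{
  "provenance": "dockflex bundled synthetic mini-table for fixture chemistry; NOT a redistribution of Gromos54a7 or Amber03",
  "combination_rule": "geometric",
  "entries": [
    {"residue": "HOH", "atom": "O",   "charge": -0.82, "sigma": 3.166, "epsilon": 0.650, "vdw_radius": 1.52, "donor": true,  "acceptor": true},
    {"residue": "HOH", "atom": "H1",  "charge":  0.41, "sigma": 2.40,  "epsilon": 0.065, "vdw_radius": 1.20},
    {"residue": "HOH", "atom": "H2",  "charge":  0.41, "sigma": 2.40,  "epsilon": 0.065, "vdw_radius": 1.20},
    {"residue": "SOL", "atom": "OW",  "charge": -0.82, "sigma": 3.166, "epsilon": 0.650, "vdw_radius": 1.52, "donor": true,  "acceptor": true},
    {"residue": "SOL", "atom": "HW1", "charge":  0.41, "sigma": 2.40,  "epsilon": 0.065, "vdw_radius": 1.20},
    {"residue": "SOL", "atom": "HW2", "charge":  0.41, "sigma": 2.40,  "epsilon": 0.065, "vdw_radius": 1.20},
    {"residue": "PRB", "atom": "NZ",  "charge":  0.60, "sigma": 3.25,  "epsilon": 0.711, "vdw_radius": 1.55, "donor": true},
    {"residue": "PRB", "atom": "HZ1", "charge":  0.20, "sigma": 0.0,   "epsilon": 0.0,   "vdw_radius": 1.20},
    {"residue": "PRB", "atom": "HZ2", "charge":  0.20, "sigma": 0.0,   "epsilon": 0.0,   "vdw_radius": 1.20},
    {"residue": "SIT", "atom": "OE1", "charge": -1.00, "sigma": 3.00,  "epsilon": 0.880, "vdw_radius": 1.52, "acceptor": true},
    {"residue": "LIG", "atom": "OC1", "charge": -1.00, "sigma": 3.00,  "epsilon": 0.880, "vdw_radius": 1.52, "acceptor": true},
    {"residue": "LIG", "atom": "C1",  "charge":  0.00, "sigma": 3.40,  "epsilon": 0.360, "vdw_radius": 1.70}
  ],
  "element_defaults": {
    "C": {"charge": 0.0, "sigma": 3.40, "epsilon": 0.360, "vdw_radius": 1.70},
    "N": {"charge": 0.0, "sigma": 3.25, "epsilon": 0.711, "vdw_radius": 1.55},
    "O": {"charge": 0.0, "sigma": 3.00, "epsilon": 0.880, "vdw_radius": 1.52},
    "S": {"charge": 0.0, "sigma": 3.60, "epsilon": 1.046, "vdw_radius": 1.80},
    "H": {"charge": 0.0, "sigma": 2.40, "epsilon": 0.065, "vdw_radius": 1.20},
    "P": {"charge": 0.0, "sigma": 3.70, "epsilon": 0.840, "vdw_radius": 1.80}
  }
}
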