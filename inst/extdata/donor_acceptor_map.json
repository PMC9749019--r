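{
  "comment": "Residue-keyed hydrogen-bond donor/acceptor atom names. '*' applies to every residue (protein backbone, nucleic-acid backbone, common sugar hydroxyls). Editable.",
  "donors": {
    "*":   ["N", "O2'", "O3'", "O5'"],
    "ARG": ["NE", "NH1", "NH2"],
    "ASN": ["ND2"],
    "GLN": ["NE2"],
    "HIS": ["ND1", "NE2"],
    "LYS": ["NZ"],
    "SER": ["OG"],
    "THR": ["OG1"],
    "TYR": ["OH"],
    "TRP": ["NE1"],
    "CYS": ["SG"],
    "HOH": ["O"],
    "SOL": ["OW"],
    "A":   ["N6"],
    "G":   ["N1", "N2"],
    "C":   ["N4"],
    "U":   ["N3"],
    "DA":  ["N6"],
    "DG":  ["N1", "N2"],
    "DC":  ["N4"],
    "DT":  ["N3"],
    "GLC": ["O1", "O2", "O3", "O4", "O6"],
    "GAL": ["O1", "O2", "O3", "O4", "O6"],
    "MAN": ["O1", "O2", "O3", "O4", "O6"],
    "PRB": ["NZ"]
  },
  "acceptors": {
    "*":   ["O", "OXT", "O2'", "O3'", "O4'", "O5'", "OP1", "OP2"],
    "ASP": ["OD1", "OD2"],
    "GLU": ["OE1", "OE2"],
    "ASN": ["OD1"],
    "GLN": ["OE1"],
    "HIS": ["ND1", "NE2"],
    "SER": ["OG"],
    "THR": ["OG1"],
    "TYR": ["OH"],
    "MET": ["SD"],
    "HOH": ["O"],
    "SOL": ["OW"],
    "A":   ["N1", "N3", "N7"],
    "G":   ["N3", "N7", "O6"],
    "C":   ["N3", "O2"],
    "U":   ["O2", "O4"],
    "DA":  ["N1", "N3", "N7"],
    "DG":  ["N3", "N7", "O6"],
    "DC":  ["N3", "O2"],
    "DT":  ["O2", "O4"],
    "GLC": ["O1", "O2", "O3", "O4", "O5", "O6"],
    "GAL": ["O1", "O2", "O3", "O4", "O5", "O6"],
    "MAN": ["O1", "O2", "O3", "O4", "O5", "O6"],
    "SIT": ["OE1"],
    "LIG": ["OC1"]
  }
}
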