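# Closest-opposing inter-loop distance pairs (C-alpha to C-alpha).
# Residue numbers are identical for darcin and MUP11 (mature numbering).
pairs:
  - {name: "L4-L8", residue_a: 78, atom_a: "CA", residue_b: 122, atom_b: "CA"}
  - {name: "L2-L6", residue_a: 48, atom_a: "CA", residue_b: 97, atom_b: "CA"}
  - {name: "L1-L5", residue_a: 38, atom_a: "CA", residue_b: 85, atom_b: "CA"}
  - {name: "L3-L7", residue_a: 58, atom_a: "CA", residue_b: 110, atom_b: "CA"}
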