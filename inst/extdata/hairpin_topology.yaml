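# The 12-residue model beta-hairpin with backbone N-amination on Tyr2,
# Glu4, Lys9 and Leu11 (the tetra-aminated variant). A d-proline is
# declared with chirality D; ornithine is accepted as ORN.
residues:
  - {name: ARG}
  - {name: TYR, aminated: true}
  - {name: VAL}
  - {name: GLU, aminated: true}
  - {name: VAL}
  - {name: PRO, chirality: D}
  - {name: GLY}
  - {name: ORN}
  - {name: LYS, aminated: true}
  - {name: ILE}
  - {name: LEU, aminated: true}
  - {name: GLN}
n_term_protonated: true
c_term_amide: true
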