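Place locally downloaded coordinate files for the deposited co-crystal
structures here (PDB format) to enable the structure-geometry checks:

  6D31.pdb  - wild-type enzyme bound to AMP
  6D2Z.pdb  - H208Q mutant bound to UA RNA
  6D30.pdb  - H208Q mutant bound to UU RNA

e.g. from https://files.rcsb.org/download/6D31.pdb

No deposited coordinates are shipped with the package; all structure tests
that run offline use synthetic models built in code.
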