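# Unwanted-substructure alerts for building-block filtering: classic
# reactive/toxic groups in the spirit of Hann-style reagent filters.
# Each record: name, pattern, and optional 'unless' patterns anchored at the
# first pattern atom that excuse a match (e.g. activated alkyl halides stay
# usable as alkylation handles). Azides and sulfonyl chlorides are kept
# deliberately: they are coupling handles of the shipped reaction library.
# The list is configurable per run (--alerts).

- name: acyl_halide
  pattern: "[CX3]([F,Cl,Br,I])=[OX1]"
  unless:
    - "[CX3]([F,Cl,Br,I])(=[OX1])[OX2]"
- name: isocyanate
  pattern: "[NX2]=[CX2]=[OX1]"
- name: isothiocyanate
  pattern: "[NX2]=[CX2]=[SX1]"
- name: epoxide
  pattern: "[CX4]1[OX2][CX4]1"
- name: aziridine
  pattern: "[CX4]1[NX3][CX4]1"
- name: peroxide
  pattern: "[OX2][OX2]"
- name: diazonium
  pattern: "[#6][NX2+]#[NX1]"
- name: nitroso
  pattern: "[#6][NX2]=[OX1]"
- name: phosphorus_halide
  pattern: "[P][F,Cl,Br,I]"
- name: anhydride
  pattern: "[CX3](=[OX1])[OX2][CX3]=[OX1]"
- name: enal_michael_acceptor
  pattern: "[CX3H1](=[OX1])[CX3]=[CX3]"
- name: alpha_halo_ether
  pattern: "[CX4]([F,Cl,Br,I])[OX2]"
- name: alkyl_halide_nonactivated
  pattern: "[CX4][Cl,Br,I]"
  unless:
    - "[CX4]([Cl,Br,I])[c]"
    - "[CX4]([Cl,Br,I])[CX3]=[CX3]"
    - "[CX4]([Cl,Br,I])[CX3]=[OX1]"
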