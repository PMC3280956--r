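# Functional group addition / interconversion (FGA/FGI) templates.
# One-component reactions applied to building blocks before annotation:
# the converted block is added to the catalog, the original is kept.
# Same schema as coupling_reactions.yaml.

- id: fgi_nitro_to_amine
  name: Nitro reduction to primary amine
  components:
    - pattern: "[#6:2][NX3+:1](=[OX1])[OX1-]"
      dummy: "O=[N+]([O-])c1ccccc1"
      forbid: []
  product: "[#6:2][N+0:1]"
  ring_forming: false
  leaving_group: "2 O - 2 H"
  leaving_mass: 29.982
  reference: "Bechamp, Ann. Chim. Phys. 42 (1854) 186"

- id: fgi_nitrile_to_amine
  name: Nitrile reduction to primary amine
  components:
    - pattern: "[#6:2][CX2:1]#[NX1:3]"
      dummy: "CC#N"
      forbid: []
  product: "[#6:2][C:1]-[N+0:3]"
  ring_forming: false
  leaving_group: "-2 H2 (hydrogenation)"
  leaving_mass: -4.032
  reference: "Nishimura, Handbook of Heterogeneous Catalytic Hydrogenation (2001)"

- id: fgi_methyl_ester_to_acid
  name: Methyl ester saponification
  components:
    - pattern: "[CX3:1](=[OX1:2])[OX2][CX4H3]"
      dummy: "COC(C)=O"
      forbid: []
  product: "[C:1](=[O:2])O"
  ring_forming: false
  leaving_group: "CH2 (methanol out, water in)"
  leaving_mass: 14.027
  reference: "Org. Synth. Coll. Vol. 2, 538 (1943)"

- id: fga_aryl_halide_to_boronic_acid
  name: Aryl halide borylation (Miyaura)
  components:
    - pattern: "[c:1][Br,I]"
      dummy: "Brc1ccccc1"
      forbid: []
  product: "[c:1]B(O)O"
  ring_forming: false
  leaving_group: "Br - B(OH)2"
  leaving_mass: 35.079
  reference: "Ishiyama et al., J. Org. Chem. 60 (1995) 7508"

- id: fgi_primary_alcohol_to_bromide
  name: Primary alcohol bromination (Appel)
  components:
    - pattern: "[CX4H2:1][OX2H1]"
      dummy: "OCc1ccccc1"
      forbid: []
  product: "[C:1]Br"
  ring_forming: false
  leaving_group: "OH - Br"
  leaving_mass: -62.897
  reference: "Appel, Angew. Chem. Int. Ed. 14 (1975) 801"
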