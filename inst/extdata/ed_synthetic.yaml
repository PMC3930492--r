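# SYNTHETIC schematic of an Entner-Doudoroff-style glycolysis. Illustrative
# only (see emp_glycolysis_synthetic.yaml): invented round dG'0 values.
# Lower ATP yield than the EMP schematic but fewer near-equilibrium steps.
name: ed_synthetic
metadata:
  ph: 7.5
  provenance: synthetic schematic; energies are invented round numbers
compounds:
  - {id: atp, is_cofactor: yes}
  - {id: adp, is_cofactor: yes}
  - {id: nad, is_cofactor: yes}
  - {id: nadh, is_cofactor: yes}
  - {id: nadp, is_cofactor: yes}
  - {id: nadph, is_cofactor: yes}
  - {id: pi, is_cofactor: yes}
reactions:
  - {id: GLK,   formula: glc + atp <=> g6p + adp,         dg0_prime: -17.0}
  - {id: ZWF,   formula: g6p + nadp <=> pgl + nadph,      dg0_prime: -6.0}
  - {id: PGL,   formula: pgl <=> pgn,                     dg0_prime: -20.0}
  - {id: EDD,   formula: pgn <=> kdpg,                    dg0_prime: -40.0}
  - {id: EDA,   formula: kdpg <=> pyr + g3p,              dg0_prime: 15.0}
  - {id: GAPDH, formula: g3p + nad + pi <=> bpg + nadh,   dg0_prime: 7.0}
  - {id: PGK,   formula: bpg + adp <=> pg3 + atp,         dg0_prime: -19.0}
  - {id: GPM,   formula: pg3 <=> pg2,                     dg0_prime: 4.5}
  - {id: ENO,   formula: pg2 <=> pep,                     dg0_prime: -3.5}
  - {id: PYK,   formula: pep + adp <=> pyr2 + atp,        dg0_prime: -27.0}
atp_accounting:
  substrate_level_atp: 1
  carriers: {NADH: 1, NADPH: 1}
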