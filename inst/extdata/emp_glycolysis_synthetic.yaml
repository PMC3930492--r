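# SYNTHETIC schematic of Embden-Meyerhof-Parnas glycolysis (glucose -> 2
# pyruvate). Illustrative only: the reaction list is textbook-shaped but the
# dG'0 values are round synthetic numbers, not estimates from any
# thermodynamic database, and the second half of the pathway is written once
# (per-triose) rather than with doubled flux. Useful for exercising the
# solver, the cofactor machinery and the ATP accounting; not a reproduction
# of any published pathway model.
name: emp_synthetic
metadata:
  ph: 7.5
  ionic_strength: 0.2
  provenance: synthetic schematic; energies are invented round numbers
compounds:
  - {id: atp, is_cofactor: yes}
  - {id: adp, is_cofactor: yes}
  - {id: nad, is_cofactor: yes}
  - {id: nadh, is_cofactor: yes}
  - {id: pi, is_cofactor: yes}
reactions:
  - {id: GLK,   formula: glc + atp <=> g6p + adp,        dg0_prime: -17.0}
  - {id: PGI,   formula: g6p <=> f6p,                    dg0_prime: 2.5}
  - {id: PFK,   formula: f6p + atp <=> fbp + adp,        dg0_prime: -15.0}
  - {id: FBA,   formula: fbp <=> dhap + g3p,             dg0_prime: 20.0}
  - {id: TPI,   formula: dhap <=> g3p,                   dg0_prime: 5.5}
  - {id: GAPDH, formula: g3p + nad + pi <=> bpg + nadh,  dg0_prime: 7.0}
  - {id: PGK,   formula: bpg + adp <=> pg3 + atp,        dg0_prime: -19.0}
  - {id: GPM,   formula: pg3 <=> pg2,                    dg0_prime: 4.5}
  - {id: ENO,   formula: pg2 <=> pep,                    dg0_prime: -3.5}
  - {id: PYK,   formula: pep + adp <=> pyr + atp,        dg0_prime: -27.0}
atp_accounting:
  substrate_level_atp: 2
  carriers: {NADH: 2}
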