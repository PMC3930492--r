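# Tiny three-step chain with per-pH dG'0 tables, for exercising pH sweeps.
# R2's energy rises with pH (proton-producing-like slope); the pathway
# crosses the feasibility boundary inside the tabulated range.
name: sweep_toy
metadata:
  provenance: synthetic sweep fixture
reactions:
  - id: R1
    formula: A <=> B
    dg0_prime: -8.0
    dg0_by_ph: [[6.0, -8.0], [8.0, -8.0]]
  - id: R2
    formula: B <=> C
    dg0_prime: -2.0
    dg0_by_ph: [[6.0, -13.0], [7.0, -2.0], [8.0, 25.0]]
  - id: R3
    formula: C <=> D
    dg0_prime: -6.0
    dg0_by_ph: [[6.0, -6.0], [8.0, -6.0]]
constraints:
  use_physiological_defaults: no
  fixed:
    - {id: A, value: 1.0e-3}
    - {id: D, value: 1.0e-3}
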