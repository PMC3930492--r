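# Symmetric four-reaction chain: the canonical teaching fixture.
# Terminals fixed at 1 M, intermediates effectively unbounded, each step
# dG'0 = -4 kJ/mol => MDF = 4 kJ/mol, every reaction shadow price = 0.25.
name: chain4
metadata:
  provenance: deterministic fixture with closed-form optimum
reactions:
  - {id: R1, formula: C0 <=> C1, dg0_prime: -4}
  - {id: R2, formula: C1 <=> C2, dg0_prime: -4}
  - {id: R3, formula: C2 <=> C3, dg0_prime: -4}
  - {id: R4, formula: C3 <=> C4, dg0_prime: -4}
constraints:
  use_physiological_defaults: no
  default_lower: 1.0e-12
  default_upper: 1.0e+6
  fixed:
    - {id: C0, value: 1.0}
    - {id: C4, value: 1.0}
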