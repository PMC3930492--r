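# Shipped default run configuration (identical to the built-in defaults;
# provided as an editable template). Concentrations in molar.
temperature: 298.15
gas_constant: 8.314e-3
default_lower: 1.0e-6
default_upper: 1.0e-2
solver: simplex
tie_break: no
cofactors:
  fixed:
    - {id: pi,  value: 1.0e-2}
    - {id: ppi, value: 1.0e-3}
    - {id: coa, value: 1.0e-3}
    - {id: co2, value: 1.0e-5}
  ratios:
    - {numerator: atp,    denominator: adp,   ratio: 10}
    - {numerator: adp,    denominator: amp,   ratio: 1}
    - {numerator: nadh,   denominator: nad,   ratio: 0.1}
    - {numerator: nadph,  denominator: nadp,  ratio: 10}
    - {numerator: fd_red, denominator: fd_ox, ratio: 1}
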