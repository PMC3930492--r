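---
title: "Max-min driving force analysis: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Max-min driving force analysis: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdftools)
```

## The model

The flux–force relationship, ΔrG′ = −RT·ln(J⁺/J⁻), ties a reaction's
transformed Gibbs energy to the partitioning of its catalytic capacity
between forward and reverse events. Three closed-form quantities follow and
are implemented in `forward_reverse_ratio()`, `reverse_flux_fraction()` and
`flux_force_efficacy()`:

* J⁺/J⁻ = exp(−ΔrG′/RT),
* J⁻/(J⁺+J⁻) = 1/(1 + exp(−ΔrG′/RT)),
* efficacy = (J⁺−J⁻)/(J⁺+J⁻) = tanh(−ΔrG′/(2RT)).

For a pathway with stoichiometric matrix **S** (rows compounds, columns
reactions; signed *actual molecularities*, columns written in the net-flux
direction) and standard transformed energies **G°**, the driving-force
vector at log-concentrations **x** (natural log, molar) is
−(**G°** + RT·**S**ᵀ**x**). The Max-min Driving Force problem maximizes the
smallest entry of that vector over the concentration box, with fixed
concentrations and pinned concentration ratios as equality constraints:

    max  B
    s.t. RT·Sᵀx + B·1 ≤ −G°
         x_i ≤ ln C_max,i          (range compounds)
         x_i ≥ ln C_min,i
         x_i = ln c_i              (fixed compounds)
         x_num − x_den = ln ρ      (ratio groups)

B is a free variable, so the LP is feasible whenever the box and the
equalities are mutually consistent; "pathway infeasible" is the *verdict*
MDF ≤ 0, not a solver failure. `solve_mdf()` distinguishes the two:
`feasible = FALSE` with `solver_status = "optimal"` versus
`solver_status = "infeasible_constraints"`.

### Assumptions

* Energies are standard *transformed* energies at the stated pH and ionic
  strength. Water and protons therefore carry no concentration variable and
  must not appear in formulas; their contribution is inside ΔrG′°. The
  package never performs Legendre transforms — pH dependence enters only
  through user-supplied ΔrG′°(pH) tables (`dg0_by_ph`), linearly
  interpolated and never extrapolated.
* Stoichiometric coefficients are molecularities at the enzyme, not
  arbitrary rescalings; the flux–force relationship is not invariant to
  rescaling, so this is substantive, and the package never normalizes
  coefficients.
* Dissolved gases (e.g. CO2(aq), default fixed at 10 µM for ambient
  conditions) are ordinary compounds with user-set constraints; no
  gas-phase equilibration is modeled.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| gas constant R | 8.314e-3 | kJ·mol⁻¹·K⁻¹ | physical constant |
| temperature T | 298.15 | K | standard-condition convention; reproduces the exp(7.3/RT) = 19 identity |
| default bounds | 1e-6 – 1e-2 | M | physiological metabolite range (1 µM–10 mM) |
| fixed cofactors | Pi 1e-2, PPi 1e-3, CoA 1e-3, CO2 1e-5 | M | cytoplasm-like values |
| cofactor ratios | ATP/ADP 10, ADP/AMP 1, NADH/NAD 0.1, NADPH/NADP 10, Fd_red/Fd_ox 1 | – | ratios are better conserved than absolute pools |
| P/O-type rules | NADH/NADPH/Fd-pair 1.5, quinol 1.0 | ATP per carrier | respiratory ATP equivalents for yield accounting |
| bottleneck threshold | 1e-6 | – | numerical noise floor on shadow prices |
| LP feasibility tolerance | 1e-9 | – | problem scale is O(10) kJ/mol; tests compare at 1e-6 kJ/mol |

All of these are editable per run (`concentration_constraints()`,
`thermo_constants()`, a YAML config, or per-pathway `constraints:`
sections). A concentration ratio applies only when **both** members occur in
the pathway; a half-present pair (the ADP/AMP default in an AMP-free
pathway) is vacuous and dropped. A ratio pins only the *difference* of logs:
the pair's absolute level still moves within each member's range bounds.

## Duality and shadow prices

Each reaction row carries a dual multiplier w_j ≥ 0; stationarity in B
forces Σ w_j = 1 at the optimum, so **w** reads as a probability-like weight
of how much each reaction limits the MDF: adding δ to reaction j's ΔrG′°
changes the MDF by −w_j·δ to first order (the symmetric four-reaction chain
fixture gives w = 0.25 each, hence the 4 kJ/mol → 1 kJ/mol example
reproduced in the tests and acceptance report).

The bound rows carry duals u_max, u_min. As produced by the LP these are in
kJ/mol (the dual objective −**w**ᵀ**G°** + **u_max**ᵀln C_max −
**u_min**ᵀln C_min equals the MDF — asserted on every solved instance). The
conventional *metabolite shadow price* is unitless; the package reports
`metabolite_shadow_prices = max(|u_max|, |u_min|)/RT`, so that raising a
binding upper bound f-fold raises the MDF by price·RT·ln f (the
0.5·RT·ln 10 ≈ 3 kJ/mol two-chain example). Both conventions are exposed
(`u_max`/`u_min` raw, the scaled maximum as the headline price).
`sensitivity_check()` is the authoritative cross-check: it compares the
first-order prediction with a full re-solve.

Fixed concentrations are encoded as equality rows; their single free dual is
split by sign into the u_max/u_min slots. Ratio equalities carry free duals
reported as `ratio_duals` and included in the dual objective.

### Degeneracy

LPs do not guarantee unique duals or unique optimal concentration profiles.
When the count of active constraints at the optimum exceeds the variable
count + 1 the result is flagged `degenerate = TRUE` and the backend's duals
are reported as-is — `sensitivity_check()` decides arguments about them.
The reported per-reaction ΔrG′ values are *one* optimal profile; an
optional tie-break (`tie_break = TRUE`) re-solves with the floor fixed at
the MDF while maximizing the total driving force, giving a well-defined
profile without ever changing the MDF itself. No tie-break is applied by
default because none is canonical.

## The LP backend

No linear-programming package could be assumed available at runtime, so the
package carries a dense two-phase primal simplex (`lp_solve_dense()`):
free variables split into positive parts, slack/artificial standard form,
Bland's rule (guaranteeing termination on the routinely degenerate MDF
instances), and a final re-factorization of the optimal basis with
`solve()` so reported primal and dual values do not inherit tableau
round-off. Duals are y = c_Bᵀ B⁻¹ mapped back through the row
transformations. This is adequate because MDF instances are tiny (a pathway
of r reactions and c compounds yields ≤ r + 2c + groups rows); it is not a
general-purpose LP code. Its duals are validated in the test suite by
strong duality, complementary slackness and finite-difference checks, and
the primal against two independent oracles (below).

Other numerical choices:

* Overflow guard: `forward_reverse_ratio()` caps |ΔrG′|/RT at 700;
  efficacy and reverse fraction use `tanh`/logistic forms that saturate
  cleanly. No result changes at printed precision.
* All functions return fractions; percent formatting happens only in
  reports.
* pH sweeps re-solve from scratch at every grid point (no warm starts, no
  caching) — asserted by comparing against fresh `solve_mdf()` calls.

## Synthetic data: what it emulates, what it does not

`chain_spec()`/`make_chain()` generate linear chains with fixed terminal
concentrations and wide intermediate bounds — the geometry in which the MDF
has the closed form −(ΣΔrG′° + RT·Δln c_terminals)/n with all driving
forces equal and w_j = 1/n. `chain_mdf_closed_form()` implements that
formula *and verifies its own applicability* (it reconstructs the implied
intermediate concentrations and refuses if any bound would be violated), so
it is a genuine independent oracle for the LP. `random_instance()` draws
sparse stoichiometries with molecularities in {1, 2} and ΔrG′° uniform in
[−30, +10] kJ/mol — chosen to straddle feasibility so both verdicts are
exercised — and `brute_force_mdf()` checks the LP against an exhaustive
grid search (grid optima are feasible points, so brute force ≤ LP always;
and ≥ LP minus an explicit discretization bound).

None of this emulates real pathway thermochemistry: random energies are not
realizable chemistry, chains have no branching or conserved moieties, and
the shipped glycolysis/ED files are *synthetic schematics* with invented
round-number energies (marked as such in the files). A green suite
establishes that the solver, duals, oracles and accounting agree with each
other and with closed forms — not that any particular biological pathway
has a particular MDF. Reproducing published pathway figures would require
the separate energy-estimation machinery that is out of scope here.

## Known limitations

* ΔrG′° estimation (component contribution, group contribution) is out of
  scope; energies are inputs.
* ATP accounting is declarative (a stanza in the pathway file), never
  inferred from stoichiometry: per-glucose normalization and carrier
  identification from raw stoichiometries is error-prone and intentionally
  avoided.
* Enzyme demand (`enzyme_demand_report()`: 1/efficacy per reaction) is a
  report, not an objective; reactions at or beyond equilibrium in the
  reported profile get an infinite factor with a warning.
* Fluxes are fixed in direction; no mixed-integer direction choices, no
  flux variability.
* The brute-force oracle refuses more than 4 free concentration dimensions
  by design (exponential grid).
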