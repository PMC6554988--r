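---
title: "Methods: constraint-based analysis of a PHB-accumulating methanotroph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based analysis of a PHB-accumulating methanotroph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methanoflux)
```

## The model and its assumptions

All analyses rest on flux balance analysis: at steady state every internal
metabolite is mass balanced (`S v = 0`), fluxes respect bounds in mmol
g-DW⁻¹ h⁻¹, and a linear objective — almost always the biomass reaction,
scaled so flux 1 equals a specific growth rate of 1 h⁻¹ — is optimized.
FBA assumes the cell operates at a flux distribution optimal for the
chosen objective and says nothing about kinetics or regulation; every
conclusion drawn here is of the form "the stoichiometry permits / forbids
/ bounds this behaviour".

The packaged core model is a compact (~80 reaction) but elementally exact
reconstruction of type II methanotroph central metabolism. Its design
constraints were: both alternative pMMO electron-donor stoichiometries
must coexist (cytochrome-*c*-coupled `pMMO1`, ubiquinol-coupled `pMMO2`)
together with a forward-only complex III whose reversal expresses uphill
electron transfer; C1 oxidation proceeds methanol → formaldehyde →
formate → CO₂ with formaldehyde also condensing onto tetrahydrofolate;
carbon assimilation runs through the full serine cycle; PHB is made from
acetyl-CoA and re-enters metabolism only through the
ethylmalonyl-CoA-type route ending in l-erythro-3-methylmalyl-CoA lysis
(the acetoacetyl-CoA thiolase is curated to its condensation direction, so
direct thiolytic re-entry is impossible — this is what makes the
glyoxylate + propionyl-CoA anaplerosis the model's, not the modeller's,
choice); nitrogen enters as nitrate through assimilatory reduction (4
NADH per N), mirroring a nitrate mineral medium; and anaerobic electron
disposal exists only through the four-step denitrification chain.
`element_balance()` verifies C, H, O and N balance of every non-exchange
reaction; the biomass macromolecule's formula is defined as the exact
elemental residual of its own equation.

### Respiratory stoichiometry

Complexes I + III + IV translocate 10 H⁺ per NADH (4 + 4 + 2) and the
synthase spends 4 H⁺ per ATP, so NADH-fed respiration yields 2.5 ATP per
NADH = 5 ATP per O₂, the classical assumption also used to convert the
measured endogenous respiration (0.71 mmol O₂ g-DW⁻¹ h⁻¹) into the
non-growth maintenance of 3.5 mmol ATP g-DW⁻¹ h⁻¹. `build_core_model()`
exposes `atp_per_o2`; changing it rescales the synthase, not the pumps.
A non-pumping NADH dehydrogenase (NDH-2) and a membrane proton leak are
included so that surplus proton-motive force has physiological outlets;
without them the LP dissipates surplus ATP through storage-cycle
artifacts.

### Biomass equation and the one tuned constant

The biomass equation drains acetyl-CoA, serine, glycine, 2-oxoglutarate,
oxaloacetate and ammonium (about 39 mmol C and 12 mmol N per g DW —
textbook bacterial composition), plus 40 mmol growth-associated ATP per
g. These are fixed a priori. The single tuned constant is a lumped
anabolic reductant demand (24.651 mmol NADH per g DW), standing in for
the NADPH consumed by amino acid, lipid and nucleotide synthesis that a
compact network cannot resolve. It was fitted once
(`tools/calibrate_core_model.R`) so that redox-arm growth at the measured
methane uptake (14.9 mmol g-DW⁻¹ h⁻¹) and maintenance (3.5) equals the
measured 0.107 h⁻¹. The O₂/CH₄ consumption ratio of 1.5 is *not* tuned:
with every methane passing pMMO (1 O₂) and methanol dehydrogenase (2
cytochrome-*c* electrons, ½ O₂ at complex IV), the ratio is exactly 1.5
whenever no surplus NADH is respired, which is the situation at the
calibrated optimum.

### The uphill variant

Alongside a cytochrome-*c*-coupled pMMO, a reversible complex III is
inert — it would merely reproduce direct coupling. Uphill electron
transfer means ubiquinone is reduced at the expense of proton-motive
force, so the variant is implemented as the ubiquinol-coupled pMMO active
with the complex III lower bound opened negative. With these proton
stoichiometries its yield lands strictly between redox arm and direct
coupling.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `uptake_ch4` | 14.9 | mmol g-DW⁻¹ h⁻¹ | measured specific methane uptake, imposed as a fixed negative exchange flux |
| `ngam_atp` | 3.5 | mmol g-DW⁻¹ h⁻¹ | non-growth ATP maintenance, a fixed flux through a dedicated hydrolysis reaction |
| `atp_per_o2` | 5 | mol/mol | respiratory calibration target; must divide 20 into an integer H⁺/ATP |
| `gam` | 40 | mmol g-DW⁻¹ | growth-associated ATP |
| `nadh_demand` | 24.651 | mmol g-DW⁻¹ | lumped anabolic reductant demand (the tuned constant) |
| essentiality `threshold` | 1e-6 | relative | knockout optimum below `threshold` × wild type counts as lethal |
| pfba `eps` | 1e-6 | relative | optimality slack retained during flux-norm minimization |
| Pareto grid | 21 points | — | 0 to the product's stoichiometric maximum |
| `hub_quantile` | 0.99 | — | degree percentile above which metabolites count as hubs and are excluded from the power-law fit |

## Scenario conventions

*Exchange convention.* Exchanges are written `met_e0 →` with positive flux
= secretion; uptake is a negative flux enabled by a negative lower bound,
so "set methane uptake to 14.9" means a lower bound of −14.9.

*Bottle totals.* Co-consumption imposes the measured bottle totals (1.8
mmol CH₄, 0.083 mmol PHB) directly as flux-scale values, which linearity
and time invariance of the LP make exact. Maintenance is excluded from
this totals mode by default because how maintenance should be charged over
the 15 h incubation is not determined by the endpoint measurements; a
flag (`include_ngam`, with a trapezoidal mean-biomass argument) enables
it as a sensitivity run. Stored PHB is represented by a storage-pool
exchange whose lower bound is opened by exactly the degraded amount.

*Reported fluxes.* Raw FBA flux vectors are non-unique; every individual
flux this package reports comes from parsimonious FBA. Tie-breaking among
equal-norm optima is solver-determined and non-contractual. This matters:
at the co-consumption optimum the glycine-synthase flux is genuinely
degenerate (glycine can come from methylene-THF + CO₂ via glycine
synthase or from PHB-derived glyoxylate via transamination at identical
marginal cost), and the parsimonious solution is the package's
deterministic resolution of that degeneracy. The qualitative pattern —
glycine synthase and malyl-CoA lysis per methane decrease during
co-consumption while PHB degradation rises from zero — is asserted in the
tests under this convention.

## The LP engine

No external solver is used: `solve_lp()` is a dense two-phase
bounded-variable primal simplex with Dantzig pricing, a Bland's-rule
fallback after a cycling guard, and basis refactorization from scratch at
every iteration (numerical freshness is worth more than speed at ≤ a few
hundred reactions). Feasibility/optimality tolerances are 1e-9; all
post-hoc mass-balance checks use 1e-6. Infeasible and unbounded problems
return statuses, never exceptions. The engine is validated three ways:
exhaustive enumeration of basic solutions on networks of ≤ 8 reactions
(20 seeds, agreement to 1e-6), pracma's textbook simplex on canonical-form
problems, and an external constraint-based implementation reading the
package's SBML export and reproducing the growth rate and O₂/CH₄ ratio.

## What the generators emulate — and what they do not

`random_network(mode = "fba")` builds small connected mass-flow networks
(one source, one sink, random conversions, finite bounds) purely as LP
test substrate. `random_network(mode = "scale_free")` draws metabolite
degrees from a discrete power law `P(k) ∝ k^−γ` (default γ = 2.5, k ≤ 15)
and wires stubs into two-sided reactions; with 3000 metabolites the
degree-slope estimator recovers γ within ±0.2 per seed. These networks
have no biochemistry: passing topology tests shows the counting and
fitting are correct, not that any real network is scale free. The fitted
slope of the ~80-reaction core model itself (reported by the topology
scenario) comes from a handful of degree classes and should not be read
as an estimate of genome-scale network topology — the −2.5 slope is a
property of genome-scale reconstructions, testable here only through the
generator.

The core model itself emulates pathway structure and calibrated
physiology, not genome-scale completeness: reaction counts, essentiality
fractions (28.7% of 1326 reactions) and Venn overlaps of full
reconstructions are properties of deposited genome-scale models, which
the I/O layer can load but which are not shipped.

## Numerical choices and degenerate inputs

- Bound defaults are ±1000; irreversibility is encoded through bounds
  only.
- Round-trip fidelity: SBML and TSV writers emit 17 significant digits,
  so write-then-read restores every coefficient and bound exactly.
- `fva()` treats a reaction as blocked when both extremes are 0 at the
  given optimality fraction.
- `degree_distribution()` with a single degree class flags
  `single_point` and returns `NA` slopes instead of fitting.
- `pareto_sweep()` reports infeasible grid points with a status rather
  than dropping them.
- Power-law fits use ordinary least squares on (log₁₀ k, log₁₀ n(k)) over
  all degrees with n(k) ≥ 1 after hub exclusion; the slope is invariant
  to the logarithm base.
- Model comparison matches reactions by a canonical stoichiometric
  signature (sorted coefficient multiset over compartment-stripped
  metabolite ids, direction-normalized), because independent
  reconstructions spell ids differently; exact-id matching would
  undercount sharing.

## Problem sizes

The shipped analyses and tests run the core model (81 reactions × 72
metabolites), 20 random LP networks of ≤ 8 reactions for oracle
comparisons, and 20 scale-free networks of 3000 metabolites for slope
recovery. These sizes keep every pipeline deterministic and fast while
exercising all code paths; the same functions accept genome-scale SBML
input unchanged.

## Known limitations

- Single NAD(H) pool: NADPH-specific reactions are lumped into the
  anabolic reductant demand, so redox-partitioning questions are out of
  reach.
- No kinetics, regulation or dynamic (time-course) FBA of the bottle
  experiments; gas–liquid transfer is not modelled.
- Why cells do not divide on PHB alone is attributed to regulation and is
  outside the stoichiometric scope.
- The measured doubling time of 4.94 h corresponds arithmetically to
  ln 2 / 4.94 = 0.140 h⁻¹, while 0.154 h⁻¹ is printed alongside it in the
  source measurements; the package computes 0.140 and records the
  discrepancy rather than resolving it.
- Gene associations are plain strings (no boolean compilation to
  MILP-style gene knockouts); essentiality is reaction-level, with
  enzyme-level knockouts expressed by zeroing all reactions sharing a
  gene.
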