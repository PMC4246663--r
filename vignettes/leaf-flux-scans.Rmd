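---
title: "Minimal-flux scans of compartmented leaf metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal-flux scans of compartmented leaf metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxscan)
```

## The model and its assumptions

`fluxscan` analyses steady-state flux distributions of a compartmented
mesophyll-cell metabolic network by flux balance analysis. The constraint
set is mass balance, `N v = 0`, over the internal metabolites (external
species, marked by the `x_` prefix, are unbalanced sources and sinks),
together with reaction irreversibility. From the feasible space a unique
prediction is extracted by minimising total flux,

$$\min \sum_j |v_j| \quad \text{s.t.} \quad N v = 0,$$

a proxy for economy in enzymatic machinery: among all flux patterns able to
meet the imposed exchange constraints, the cell is assumed to use the one
requiring the least summed catalytic activity. The absolute values are
handled the standard way, by splitting every reversible reaction into a
non-negative forward/backward pair; the reported solution recombines the
pair into a net flux.

Rather than a lumped biomass equation, the metabolic output is expressed as
a set of *export transporters*, one per output component (starch, sucrose,
amino acids, ...), whose fluxes are fixed from a measured composition table.
This keeps the network structure separate from the experimental constraints
and makes the output composition swappable: the same network can be asked
to make leaf biomass, phloem sap, or any mixture of the two.

Three further constraints shape the solutions:

* **Photon uptake is an equality**, not an upper bound. At each scan point
  the cell must absorb exactly the imposed photon flux. This is what makes
  the high-light regimes observable: excess light has to go *somewhere*,
  and the solver must choose among dissipation routes. With an upper bound
  every response would simply go flat beyond saturation.
* **Cyclic photophosphorylation may not exceed the non-cyclic rate.**
  Without this rule the programme absorbs any photon excess by spinning the
  cyclic route (one cheap reaction) and hydrolysing the ATP, and the
  over-reduction response disappears. The constraint is a structural stand-in
  for the regulation that limits cyclic electron flow in vivo.
* **A cap on the summed rubisco carboxylase + oxygenase rate** implements a
  Calvin-cycle capacity limit. It is not a claim that rubisco itself is
  limiting — any enzyme in the same subset would serve — only that such a
  limit exists. Its value moves the position of the high-light transitions
  but not their existence or nature.

A fixed maintenance ATPase flux represents growth- and non-growth-associated
upkeep. It is identical for biomass and phloem runs: the polymerisation cost
of biomass and the export cost of phloem sugars are both unrepresented, and
we have no basis for giving either scenario the larger figure, so they are
treated as equivalent.

## The equal-carbon output transition

To compare biomass production with phloem-sap export fairly, the pure
phloem scenario is rescaled so that it exports exactly the carbon of the
pure biomass scenario (`scale_to_equal_carbon()`). The transition axis then
mixes the two componentwise, `(1-r)\,b + r\,p`, so the carbon fixed per
unit time is invariant in `r` (to 1e-12 relative, enforced by tests) and
every difference along the axis reflects composition, not rate. Carbon is
counted in the exported species themselves; at steady state this equals net
CO2 fixation at the cell boundary, which the test suite audits on every
solved grid cell.

## Scan machinery and derived quantities

* `find_min_photon_flux()` brackets the feasibility threshold by bisection.
  Feasibility is monotone in light because the model always contains
  dissipation routes (substrate cycles), so a single threshold exists.
* `scan_light()` / `scan_2d()` solve one programme per grid point. The
  light grid is logarithmically spaced by default, matching how the
  responses spread over a decade of photon flux.
* `detect_regions()` compares the *active set* (reactions with
  `|v| > 1e-7 * max(1, photon flux)`) between consecutive light points and
  places a breakpoint wherever the symmetric difference reaches
  `min_change`. Within a region the optimal basis is fixed, so every flux
  is affine in the photon flux; `region_linearity()` verifies this and the
  suite requires residuals below 1e-6 relative. Because no principled
  criterion separates "major" rearrangements from minor ones, both
  granularities are reported (`min_change = 1` and, as a summary of the
  large rearrangements, `min_change = 5`).
* `relative_difference()` expresses a flux against the 50:50 output mixture
  at the same light, `D = J(i,r)/J(i,r{=}0.5) - 1`. Cells whose reference
  flux sits below the activity threshold are *undefined* (NA), never
  +-Inf, so downstream summaries are not poisoned.
* `assimilatory_quotient()` is net CO2 uptake over net O2 release, both at
  the cell boundary. Gross internal fixation would be
  degenerate-optimum-dependent (refixation loops can be rerouted without
  changing the optimum), while boundary fluxes are pinned by the
  constraints; the boundary definition also makes AQ independent of how
  much respiratory CO2 is recycled, which is exactly the property the
  analysis turns on.
* `active_reaction_count()` shares the activity threshold with the region
  detector so counts and regions agree. Where alternate optima exist the
  count can depend on the vertex the solver returns; the objective value is
  unique, so tests on degenerate fixtures assert the objective, not
  individual fluxes.

## The synthetic core-leaf model

The package ships a generator (`build_core_leaf_model()`) for a ~45-reaction,
three-compartment (cytosol/chloroplast/mitochondrion) network that stands in
for a genome-scale leaf model while remaining small enough for an exact
enumeration oracle. Pathways are lumped — one Calvin pseudo-reaction, one
pyruvate-oxidation pseudo-reaction, and so on — but the energy and redox
couplings that drive every qualitative result are kept:

* non-cyclic photophosphorylation (4 photons per NADPH, with one coupled
  ATP and half an O2 from water splitting) and cyclic photophosphorylation
  (2 photons per ATP);
* a Calvin carboxylase costing 2 NADPH + 3 ATP per CO2, and an oxygenase
  branch that consumes O2 and triose phosphate and feeds a multi-step
  photorespiratory salvage route spanning the chloroplast and cytosol;
* starch and sucrose synthesis with their degradation partners — the
  substrate cycles that dissipate excess ATP;
* a malate–oxaloacetate shuttle across both organelle membranes, moving
  chloroplast reductant to the mitochondrion, where oxidative
  phosphorylation yields 2.5 ATP per NADH and an alternative oxidase
  (AOX) can oxidise NADH without ATP coupling — the overflow valve leaf
  mitochondria use under excess light;
* NH3 and NO3 assimilation, nitrate reduction costing 4 extra NADPH per
  nitrogen (8 electrons);
* a fixed maintenance ATPase and export transporters for a starch-rich
  biomass mix and an amino-acid-rich phloem mix whose N:C ratio is
  enforced to exceed the biomass one.

Energy carriers (ATP, NADPH, NADH) are conserved-moiety pairs carrying no
atoms; carbon, nitrogen and oxygen are tracked per species, and the builder
audits all three elements in every reaction, refusing to emit an unbalanced
network.

Default parameter values are textbook lumped stoichiometries, and the
remaining free choices (maintenance ATP 2, rubisco cap 8, output tables
with biomass carbon 5.4 per unit time) were fixed once so that a 100-fold
light range passes through all the regimes of interest. They are recorded
in the fixture manifest, not asserted against any published setting. At
these defaults the light response at pure biomass output runs, in order:

1. at the minimal light (photon flux 56.4; 55.6 for phloem) the
   mitochondrial ATP synthase runs on chloroplast reductant exported
   through the malate shuttle;
2. slightly above threshold the synthase flux falls to zero as surplus
   coupled ATP from the chloroplast takes over;
3. photorespiration grows as the cheapest reductant + ATP sink;
4. nitrate replaces ammonia as nitrogen source (earlier for phloem than
   for biomass, and with a larger AQ drop for phloem — both consequences
   of the phloem mix's higher nitrogen share);
5. once the rubisco cap binds, the starch substrate cycle and the
   AOX-terminated shuttle absorb the remaining excess.

One deliberate simplification shows here: in the genome-scale rice model
the nitrate switch completes at low light, before photorespiration onset,
whereas the toy places it at the rubisco-cap transition. The lumped toy has
fewer competing reductant sinks, so the flux-economy ranking that orders
the transitions differs in this one respect; all ordering properties the
test-suite asserts (mitochondrial decline, then photorespiration, then
dissipation; ammonia at threshold; nitrate at high light; earlier onset for
phloem) hold regardless.

The analytic minimal-light thresholds in the manifest come from a closed
form independent of the linear programme: NADPH demand is twice the
exported carbon (plus nitrate reduction if forced), cytosolic ATP demand is
served by the shuttle (photon-cheaper than the cyclic route whenever
`2.5 x 2 > 4`), and any remaining chloroplast ATP gap by cyclic
photophosphorylation. Bisection against the live model reproduces these
numbers to the requested 1e-6.

## Numerical choices

* The linear programmes are solved with `boot::simplex`, after removal of
  linearly dependent equality rows (mass balance plus fixed-flux rows are
  always rank-deficient, which that routine does not tolerate). Where its
  pivoting still breaks down — degenerate bases at feasibility thresholds —
  a two-phase dense simplex with Bland's anti-cycling rule takes over.
  Both paths are cross-validated against each other and against the
  enumeration oracle in the test suite.
* Steady state is enforced to `1e-9 * max(1, max|v|)` on every optimal
  solution; violations raise rather than warn.
* The activity threshold `1e-7 * max(1, photon flux)` is scale-aware: flux
  magnitudes grow linearly with the imposed light, so a fixed absolute
  cutoff would misclassify at one end of the scan.
* The brute-force oracle (`brute_force_min_flux()`) enumerates basic
  solutions of the standard-form polytope in exact rational arithmetic
  (numerator/denominator pairs with gcd reduction; exact for the small
  integer and fractional coefficients of every fixture) and is capped at
  ~14 variables. A standard-form polytope with non-negative variables has
  a vertex whenever it is non-empty, so an empty enumeration certifies
  infeasibility.
* Degenerate alternate optima are accepted as the solver returns them; the
  objective is unique and is what oracle comparisons assert.

## What the synthetic tests do and do not show

The core-leaf generator emulates the energy/redox trade-offs of a leaf
cell — photon stoichiometry, the ATP/NADPH imbalance of the Calvin cycle,
organelle shuttles, nitrogen-source energetics — and the suite demonstrates
that the pipeline recovers the qualitative physiology these imply. It does
not emulate genome-scale redundancy (isoenzymes, parallel pathways,
thousands of blocked reactions), so active-reaction counts and region
counts on the toy are illustrative only; on a genome-scale model the same
code paths apply unchanged but the numbers are model-specific. Problem
sizes used throughout (36-point light grids, 12 x 11 transition grids,
100-network oracle sweeps) were chosen as the smallest that exercise every
regime boundary.

## A worked slice

```{r scan, eval = FALSE}
model <- build_core_leaf_model()
net <- model$net
biomass <- composition_to_fluxes(net, model$biomass, 1)
cons <- leaf_constraints(biomass, photon_flux = 60,
                         rubisco_cap = 8, maintenance_atp = 2)
thr <- find_min_photon_flux(net, cons, lo = 1, hi = 100, tol = 1e-6)
scan <- scan_light(net, cons, light_grid(57, 400, 36))
detect_regions(scan, r = 0)
```

The numbered scripts under `analysis/` run exactly these steps end to end
and write their tables under `results/`.
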