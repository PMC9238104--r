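---
title: "Methods: GEM reconstruction and nutritional simulation in crabgem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GEM reconstruction and nutritional simulation in crabgem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crabgem)
```

## The modelling problem

`crabgem` reconstructs and simulates genome-scale metabolic network
models (GEMs) of cultured crustaceans, motivated by feed optimization
for juvenile Chinese mitten crab. A GEM is a set of metabolites and
stoichiometric reactions with flux bounds; flux balance analysis (FBA)
assumes the metabolite pools are at quasi steady state and solves

$$\max\ c^\top v \quad \text{s.t.}\quad S v = 0,\ \ lb \le v \le ub,$$

where $S$ is the stoichiometric matrix, $v$ the flux vector in
mmol·gDW⁻¹·h⁻¹, and $c$ selects an objective reaction — usually the
biomass pseudo-reaction, whose flux is read in gDW·h⁻¹. The steady-state
assumption is the standard constraint-based idealization: it ignores
metabolite concentrations, kinetics and regulation, and treats the
animal as a single well-mixed compartment pair (cytosol `c`,
extracellular `e`).

## Reconstruction pipeline and its assumptions

**Draft assembly.** `build_draft()` uses KEGG Orthology (KO) ids as the
bridge between transcriptome unigenes and a universal reaction pool:
a pool reaction enters the draft iff its KO set intersects the
annotation table's KO set, and its gene list becomes the unigenes mapped
to the shared KOs. Matching is exact string matching on `Kxxxxx` ids; no
fuzzy EC-number inference is attempted, so the draft inherits whatever
incompleteness the annotation has. All draft metabolites live in the
cytosol; compartments appear only when transfer reactions are added,
mirroring how curation typically proceeds.

**Balance checking.** `check_balance()` enforces element and charge
conservation from metabolite formulas. Species with indeterminate
composition (polymers such as amylose/starch with an unspecified repeat
count) carry the formula `UNKNOWN`; reactions touching them get verdict
`unknown` rather than a failure, because such species cannot be audited
by atom counting — they are precisely the ones that later cause
network-level leaks. Charges are mostly unknown for this kind of
reconstruction, so charge deltas are only computed where every charge is
declared.

**Redundancy and chirality.** `prune_redundant()` removes (i) pool
entries flagged `general`/`incomplete`, (ii) lumped multi-step reactions
whose net stoichiometry equals the sum of one or two retained elementary
steps (searching pairs is a deliberate cap: lumped triples are rare and
the search is quadratic already), and (iii) exact duplicate
stoichiometries, keeping the lexicographically smallest id so the result
is deterministic. Chirality standardization is an alias→canonical id
map supplied by the curator (`standardize_chirality()`); no algorithm
can infer it from the data, so the package makes the mapping explicit
and reuses duplicate pruning afterwards.

**Transfer reactions.** `add_transfer_reactions()` creates, per
nutrient, an extracellular twin, one transport and one exchange
reaction. Nutrients the organism can synthesize are made irreversible
outward (lb = 0): if the animal does not need to import a compound, the
feed must not be allowed to supply it, otherwise every requirement
simulation would simply eat the medium.

## Flux bounds

`bounds_policy()` encodes the standard bound classes (all in
mmol·gDW⁻¹·h⁻¹):

| class | bounds | meaning |
|---|---|---|
| reversible internal | (−1000, 1000) | effectively unbounded |
| irreversible internal | (0, 1000) | forward only |
| synthesizable nutrient | (0, 1000) | no import allowed |
| feed nutrient | (−5, 1000) | uptake capped at 5 |
| trace element | (−1, 1000) | uptake capped at 1 |
| semi-essential | (−3, 1000) | synthesizable but insufficient (cysteine, tyrosine) |

Per-reaction overrides win over class bounds. The ±1000 "infinity" and
the class caps are the conventional magnitudes for this model family and
are configurable; what matters for the simulations is their ratios, and
the acceptance-level results (growth-rate range, requirement table
structure) are insensitive to the infinity choice.

## Biomass objective

`content_to_coefficient()` converts a measured content (g per 100 g
fresh weight) to mmol·gDW⁻¹ via
$(\text{content}/100) / (1 - w) / M \times 1000$, i.e. mg per gram dry
weight divided by mg per mmol, with $w$ the tissue water fraction
(default 0.516 for juvenile crab hepatopancreas) and $M$ the molar mass
of the measured form. Coefficients are therefore homogeneous in content
and depend on water only through $1/(1-w)$ — both properties are tested.

Molar masses ship in `molar_mass_table` (free amino acids, free fatty
acids, elements, and literature carrier compounds such as calcium
carbonate). Two entries deserve a note. The EPA feed conversion
published for juvenile crab is not reproduced by the free-acid molar
mass (302.45 g/mol gives 0.0093, not the published 0.0083 mmol·gDW⁻¹·h⁻¹);
the measured carrier form was evidently esterified but unstated, so the
table records the free acid and this caveat. Similarly the magnesium
carrier is recorded as monomagnesium L-aspartate (155.39 g/mol), which
reproduces the published conversion only approximately (0.0242 vs
0.0239); no hydrate matches exactly.

`build_biomass()` consumes each precursor at its coefficient, adds
maintenance ATP with hydrolysis stoichiometry
(ATP + H₂O → ADP + Pi) and produces 1 gDW of a biomass pseudo-metabolite;
`attach_objective()` wires in the reaction plus a biomass demand and
selects it as objective. The maintenance coefficient default is
30 mmol·gDW⁻¹ — a typical animal-cell magnitude, configurable, because
measured maintenance coefficients for this species are unpublished. An
NADPH maintenance term is deliberately omitted by default for the same
reason.

## Gap analysis

Producibility is flux-based (`is_producible()`: maximize a drain of the
target; producible iff the optimum exceeds ε = 10⁻⁶ mmol·gDW⁻¹·h⁻¹), not
graph reachability, so cofactor coupling and reversibility are honored;
a graph-reachability oracle is used only in tests on networks where the
two notions provably coincide (irreversible, unit coefficients).
`find_breakpoints()` walks breadth-first backwards over producing
reactions and reports non-producible upstream metabolites as `orphan`
(no producer at all) or `blocked` (producers exist but are themselves
starved); the orphans are the actionable repair sites.

`gapfill()` adds, per target, the smallest pool subset that restores
producibility, iterating over set sizes 1 then 2 with lexicographic
candidate order — a deterministic greedy choice, made explicit because
published reconstructions rarely state their gap-filling algorithm. At
`pathway` scale candidates must share a pathway with the current model;
`global` scale uses the whole pool. Added reactions always admit zero
flux, so previously producible metabolites stay producible, and the
weakly-connected-component count (`connectivity()`, computed on the
bipartite metabolite–reaction graph with igraph) can only decrease or
stay equal — both are asserted as invariants in the test suite. MILP
gap filling and thermodynamic filtering are out of scope.

## Sanity suite

`sanity_suite()` runs the ten standard basic-property checks in fixed
order: closed-model exchange leaks; per-metabolite demand leaks; energy
from water; matter from a reversed ATP demand; flux through the
cytosolic proton demand; ATP yield from glucose against a plausibility
cap (default 40 ATP/glucose — generous against the textbook ~32);
duplicated reactions; empty stoichiometry columns; demand lower bounds;
and a single-gene-deletion smoke test. Checks whose role metabolites
(water, ATP, ADP, Pi, proton, glucose; `gem_roles()`) are missing from
the model are skipped with a notice rather than failed. ε = 10⁻⁶
throughout.

## Nutrition analysis

`simulate_requirements()` fixes the biomass flux (lb = ub, default
1 gDW·h⁻¹), optimizes, and reports per-nutrient uptake as positive
requirements; nutrients exported at the optimum are reported negative
and flagged as accumulations (the situation where an essential
byproduct is produced in excess of need and has no consuming reaction).
Raw FBA optima are degenerate; a `parsimonious = TRUE` flag switches to
the minimal-total-flux solution. Isomer routes are reported per
metabolite id and never summed. Display conventions mirror the field
(four decimals for mmol, integer percent for deposition rates) while
full precision is kept internally; `deposition_rate()` returns the raw
fraction and leaves rounding to the caller.

`sgr()` implements the specific-growth-rate calculation
$[\ln(m_1 + f\,m_1 x/(1-w)) - \ln m_1]\times 100$ for daily feed
fractions $f$ between 3% and 5% of an 8.41 g juvenile, water fraction
51.6%: increasing and concave in the synthesis rate $x$, with
`sgr_min <= sgr_max` always. At the published $x = 0.1203$ gDW·d⁻¹ this
gives 0.74–1.24 %·d⁻¹ (the lower figure prints as 0.75 when $x$ is
carried at full precision; the difference is within the rounding of
$x$ itself).

## The LP engine

No linear-programming package is available in the supported R
environment, and the two general-purpose simplex routines that do ship
(in `boot` and `pracma`) failed on a substantial fraction of the FBA
instances generated by this package (NaN pivots, non-convergence).
The engine is therefore an internal dense bounded-variable two-phase
primal simplex with Bland's smallest-index anti-cycling rule
(`R/lp-solver.R`): variables start at the finite bound nearest zero,
artificial variables absorb the equality residuals, and redundant rows
keep their artificials basic at zero with frozen bounds. Requested
tolerances: 10⁻⁹ on reduced costs and ratio tests; reported solutions
satisfy ‖Sv‖∞ ≤ 10⁻⁶ (observed ≈10⁻¹⁵ on the test models) and bounds to
10⁻⁹. The test suite cross-checks objective values against
`pracma::linprog` on every instance where that routine converges and
against closed-form optima on all generated models. All bounds are
finite by construction, so unboundedness cannot arise; infeasibility is
reported as a status, never as silent zeros.

Parsimonious FBA (`pfba()`) minimizes $\sum_i |v_i|$ at a fixed
objective flux via the standard positive/negative split with bounds
chosen so the difference spans exactly $[lb, ub]$. `flux_compare()`
uses parsimonious solutions at both growth rates so the comparison is
well-defined despite degenerate optima.

## What the synthetic generator emulates — and what it does not

`make_toy_gem()` builds, from a single seed, a balanced network with:
a glucose/ATP core (proton-free fermentation
glc + 2 ADP + 2 Pi → 2 lactate + 2 ATP + 2 H₂O, elementally exact with
real formulas), essential nutrients with import-only routes
(exchange → transport → activation chain), nutrients synthesizable from
glucose carbon, optional disconnected islands, and an optional
polymer-leak motif reproducing the classic pattern of two polymeric
species with mismatched repeat counts plus an internal water-releasing
pseudo-cycle. Biomass consumes the activated precursors (coefficients
drawn once per seed from [0.5, 2] for essentials, [0.1, 0.8] for
synthesizables) plus maintenance ATP (default 2 mmol·gDW⁻¹ in the
generator, small enough that both the nutrient-limited and
carbon-limited regimes occur across seeds).

The recorded ground truth is analytic: the biomass optimum is the
Liebig minimum of uptake/coefficient over essential nutrients and of
the shared glucose budget $5/(m/2 + \sum_j c_j)$; requirements at unit
growth equal the biomass coefficients; the component count is
1 + islands. These values are what the FBA, gap-filling, sanity and
nutrition tests are checked against.

What passing these tests shows: the solver, the producibility logic,
the gap-filling search and the requirement accounting are correct on
networks whose answers are known exactly. What it does not show:
realism of KEGG-scale reconstructions — the toys have no cofactor
promiscuity, no alternate pathways beyond what is planted, pool sizes
far below 10⁴ reactions, and no gene-association logic beyond flat
lists (AND/OR rules are out of scope, as the source reconstructions
publish none). Conclusions about a real animal still require a real
annotation, a measured composition and literature feed data.

## Problem sizes and determinism

All stochastic choices flow from explicit seeds through a local RNG
(the caller's RNG state is untouched). The shipped test suite uses 50
generated models for the solver checks, 20 single-gap and 10 double-gap
instances for recovery, and toy fixtures elsewhere; the full suite runs
in well under a minute on one CPU, and the acceptance script is
milliseconds (its targets are closed-form evaluations at published
inputs).

## Known limitations

* SBML support is a self-contained reader/writer (level-3 core with
  flux-bound attributes and key/value notes); it round-trips this
  package's models but does not parse arbitrary fbc/groups extensions.
* Deposition rates inherit the uncertainty of literature feed demands;
  where a literature value is zero or missing the rate is undefined
  (`NA`), matching how such rows are published ("-").
* The maintenance ATP coefficient and the atp-yield cap are conventions,
  not measurements; both are arguments, not constants.
* Gap filling is greedy and capped at two additions per target; it
  returns *a* minimal set under lexicographic tie-breaking, not all
  minimal sets.
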