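---
title: "Methods: prospective LCA with nano-specific toxicity characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prospective LCA with nano-specific toxicity characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbdlca)
```

# The model

## Inventory

A product system is described by its technology matrix $A$ (product flows
$\times$ processes, outputs positive, inputs negative), its intervention
matrix $B$ (elementary flows $\times$ processes, emissions positive,
resource draws negative) and a functional-unit demand vector $f$. The
process scaling $s$ and life cycle inventory $g$ follow from

$$A\,s = f, \qquad g = B\,s .$$

This is the standard computational formulation of LCA; we require $A$
square and invertible, which means one reference product per process and
each product flow produced by exactly one process. That restriction fits
the linear production chains this toolkit targets (catalyst manufacture
feeding a reactor); co-production and allocation are deliberately out of
scope. The solver also keeps the per-process contribution matrix
$B\,\mathrm{diag}(s)$, which is what makes contribution (hotspot) analysis
possible downstream.

The sign conventions matter for cumulative energy demand: primary-energy
draws are negative in $B$ (they are resource extractions), so the CED
multiplier supplied in the registry is $-1$ MJ per MJ drawn, yielding a
positive energy demand. GWP multipliers act on positive emissions in the
ordinary way.

**Releases.** Nanomaterial emissions do not come from measured emission
inventories but from *release models*: per life-cycle stage, the fraction
of handled nanomaterial mass released to each compartment. Fractions must
each lie in $[0,1]$ and sum to at most one (mass balance is enforced, not
assumed). Because toxicity factors characterize freshwater while plant
effluents leave via the sewer, an explicit routing step moves the sewer
load to freshwater with a transfer coefficient (default 1). The default
credits no removal to wastewater treatment — a worst-case stance
consistent with the precautionary defaults used elsewhere in the method;
users with treatment data can lower it.

## Toxicity characterization

Nano characterization factors follow the fate $\times$ exposure
$\times$ effect chain

$$\mathrm{CF} = \mathrm{FF}\,[\mathrm{d}] \times \mathrm{XF}\,[-]
  \times \mathrm{EF}\,[\mathrm{PAF\cdot m^3/kg}],$$

with a human effect factor (HEF, cases/kg) in place of EF for human
toxicity. Resolution against the registry is a strict cascade:

1. a direct entry for the nanoform (literature or database CF, or its
   components);
2. a read-across surrogate — an *explicit, user-supplied* mapping to
   another nanoform of the same substance, never inferred automatically
   from physicochemical similarity;
3. composition from whatever components exist, with missing FF or XF
   defaulted to 1;
4. otherwise a hard error instructing a KPI-only assessment.

Setting an unknown XF (or FF) to 1 is precautionary in a precise sense:
for fixed effect factor, the composed CF with defaults dominates the CF
under any admissible $\mathrm{XF} \le 1$, $\mathrm{FF} \le 1$, so the
impact estimate cannot understate risk through a data gap. Every default
and every surrogate hop is recorded in the resolution trace, and the
resulting provenance tier is the *highest-uncertainty* tier touched on
the way (a literature value reached through read-across is tier
`read_across`, a composition that needed a default is
`default_precautionary`). That rule is what lets the heat maps surface
data substitutions without any extra bookkeeping.

Two unit choices deserve a note. First, HTP totals are reported in the
registry's CF unit (cases·d per kg emitted), even though human-toxicity
results are often quoted in plain cases; the source values for the case
factors do not state where the day dimension cancels, and we prefer
carrying the printed unit to silently dividing by an undocumented time.
Second, the case registry applies the same CF to air and freshwater
emissions of a nanoform: the available factors are not
compartment-resolved, and dropping air emissions entirely would be the
opposite of precautionary. Both choices are visible in the registry
tables, not buried in code.

## The decision engine

The stepwise framework is a pure function from a *data-availability
profile* to a mode, a data plan and a decision trace. Answers must be
explicit booleans — no nulls — which is what makes identical profiles
yield byte-identical traces. The preliminary part decides feasibility: if
process-level data cannot be collected, or the system boundaries are
unknown, the assessment is `kpi_only` and stops after recording that
choice. Otherwise the cascade assigns one provenance tier to each
required quantity: release rate, and per nanoform the effect, exposure
and fate tiers. A nanoform's CF tier is the worse of its effect and fate
tiers; the exposure tier is carried separately because an exposure
default (XF = 1) does not degrade a directly sourced CF. Steps of the
underlying flowchart that the available description does not enumerate
are represented as an explicit "not modelled" trace row rather than
invented semantics, and the scale-up step is a data-need stub only.

The five green-chemistry KPIs (solvent mL/g, electricity kWh/g, heat
kJ/g, pollutants g/g, waste g/g) are plain ratios over the batch's
nanomaterial mass. Comparisons stay per indicator — no aggregate score is
computed, because no defensible weighting across them exists.

## Screening, hotspots, comparison, heat maps

Design screening encodes numeric thresholds where the underlying
safe-by-design guidance states them — particle size below 50 nm, aspect
ratio beyond 1:5 (the HARN fibre class) — and categorical rules for
coating stability, persistence, reactivity, ROS generation,
agglomeration and exposure route. An `"unknown"` attribute produces an
information-gap flag ("needs characterization"), never a silent pass;
this is the screening-level analogue of the precautionary CF defaults.
Two thresholds are tool defaults with no external source: the
release-rate flag (any stage releasing more than 1 % of handled mass,
configurable) and the dominance share for process hotspots (a single
process carrying more than 50 % of an indicator). Hotspot rankings sort
by contribution descending with ties broken by process id, so permuting
the input order cannot change the report.

System comparison treats all four indicators as lower-is-better
potentials and raises the trade-off flag exactly when at least one
indicator improves while another worsens. The relative delta is reported
as undefined when the reference value is zero. Swapping the two systems
flips every verdict and preserves the flag (antisymmetry), which the test
suite checks.

The two heat maps are complete grids by construction: processes
$\times$ indicators with the process data tier in each cell, and
nanoforms $\times$ toxicity indicators with the tier at which
`resolve_factors()` actually resolved each factor. Building the CF map
from live resolution (rather than from the framework plan) is a
deliberate design choice: it is what lets one nanoform show different
tiers per indicator — e.g. a directly sourced human-toxicity factor next
to a read-across ecotoxicity factor — which a single per-nanoform plan
tier cannot express.

# The synthetic case fixture

`make_case_fixture()` builds a paired scenario shaped like a
photocatalytic-hydrogen development project: a reference system using an
uncoated 20 nm, 50 m²/g nano-TiO₂ photocatalyst and an original system
using a Cu₂O-coated variant, functional unit 1 g H₂. What is real in it:
the four toxicity characterization factors (FEP 3443 and HTP 222 for the
uncoated form; FEP 17 700 read across from copper oxide nanomaterials and
HTP 0.99 for the coated form) and the availability pattern they imply
(literature tier for the uncoated form, read-across for the coated form's
ecotoxicity, precautionary exposure defaults for both). Everything else —
catalyst, methanol and electricity demands, background CO₂ and
primary-energy multipliers, release fractions — is synthetic: the values
are plausible for a lab-scale photoreactor and are chosen once, not
fitted.

Defaults and the reasoning behind them:

* `catalyst_per_g_h2 = 0.002` kg, `methanol_per_g_h2 = 0.1` kg: methanol
  is the sacrificial scavenger and lab runs over-dose it heavily, which
  is also why methanol production dominates the bulk indicators of the
  reference system — the pattern a contribution analysis should find.
* `efficiency_gain = 0.45`: the coated catalyst's better photocatalytic
  activity reduces the H₂ process's catalyst, electricity *and methanol*
  demand by the same factor. The gain is applied to methanol as well
  because scavenger consumption scales with reactor runtime per gram of
  product; with methanol held fixed the energy indicators would barely
  move and the fixture would not exhibit the qualitative
  improve-energy/worsen-ecotoxicity pattern it exists to exercise.
* `release_fractions`: 0.4 % to air and 10 % to sewer during manufacture
  and coating; zero during use (no release expected during operation);
  5 % to freshwater at disposal. Disposal is the genuinely open one — a
  leak-free recycling filtration chain would make it zero, while surface
  water is otherwise the main receiving compartment — so it is an
  explicit parameter with a nonzero precautionary default rather than a
  hard-coded answer.
* `sewer_transfer = 1`: precautionary pass-through, as above.

What the fixture does *not* emulate: real background databases (two
synthetic aggregate rows stand in for grid electricity and methanol
production), multimedia fate modelling (FF/XF are registry inputs, never
simulated), compartment-resolved CFs, and any absolute impact magnitudes
— the totals it produces are internally consistent but deliberately not
comparable to published case-study results, which depend on proprietary
background inventories. Passing tests on this fixture therefore
demonstrates that the *machinery* (solver, cascade, trace, comparison) is
correct, not that any particular real material is safe or sustainable.

The random-system generator used for property tests draws column
diagonally dominant technology matrices (inputs per process scaled to
20–80 % of the diagonal), which guarantees invertibility by construction;
generated systems go through the same public constructors and validators
as user input.

# Numerical choices

* The inventory solve uses LAPACK via `solve()`, guarded by a reciprocal
  condition estimate: `rcond(A) < 1e-12` is an error naming the product
  flow most aligned with the near-null space (via SVD), not a silent
  garbage result. A post-solve residual check (`1e-9` relative) backs
  this up.
* The solver's correctness oracle in the tests is an adjugate/cofactor
  solve — $O(n!)$, fine at $n \le 6$ — sharing no code with the LAPACK
  path. Agreement is required to `1e-9` relative error over 200 seeded
  systems of up to 5 processes.
* Unit handling is label-based with exactly two documented conversions
  (g↔kg, MJ↔kWh); any other mismatch is an error rather than a guess.
* CSV serialization uses 12 significant digits, which keeps round-trips
  within `1e-11` relative while making repeated runs byte-identical (the
  idempotence property the CLI tests check).
* Contribution conservation (contributions summing to the total within
  `1e-9` relative) is asserted at construction time of every impact
  result, so a violation fails fast inside `characterize()` rather than
  surfacing as a wrong report.
* All randomness (fixtures, property tests) flows through explicit seeds
  under a save/restore wrapper, so generators never disturb the caller's
  RNG stream.

# Problem sizes

The shipped tests and the acceptance script run the case fixture (4- and
5-process systems), 200 random solver-oracle comparisons at up to 5
processes, and 1000 random KPI batches — sizes chosen so the full suite
completes in seconds while still exercising every cascade branch and
every property over a meaningful sample.

# Known limitations

* One reference product per process: no allocation, by-products or loops.
* No background-database importers (ecospold/ILCD) and no multimedia fate
  simulation; both are upstream of this toolkit's scope.
* HTP units carry the day dimension of the source factors (see above).
* The framework's iterative refinement loop is represented by re-running
  with an updated availability profile; the package does not manage
  iteration state itself.
* Trade-off detection is qualitative by design: with no defensible
  weighting across indicators, the package flags conflicts instead of
  scoring them.
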