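# ssbdlca

Prospective life cycle assessment (LCA) for safe-and-sustainable-by-design
(SSbD) nanomaterials.

## The problem

When a nanomaterial developer modifies a material — say, coating a
photocatalyst to boost its activity — the modification can cut energy use
and greenhouse-gas emissions while simultaneously making the material more
toxic to people or freshwater ecosystems. Conventional LCA tooling handles
the first half well and the second half poorly: characterization factors
for engineered nanoforms are scarce, and the little data that exist are
scattered across literature values, database entries, read-across
surrogates and outright precautionary guesses.

`ssbdlca` is a toolkit for doing this assessment honestly at the design
stage, for R&D teams and LCA practitioners working on nano-enabled
products. It keeps track not only of *what* each impact score is but of
*where every number came from*, so the uncertainty introduced by each data
substitution stays visible in the final report.

## The method

1. **Inventory.** A product system is a technology matrix `A` (product
   flows × processes; outputs positive, inputs negative) and an
   intervention matrix `B` (elementary flows × processes; emissions
   positive, resource draws negative). For a functional-unit demand `f`,
   the process scaling is `s = A⁻¹ f` and the life cycle inventory is
   `g = B s`. Nanomaterial releases enter `B` through per-stage release
   fractions (to air and sewer during manufacture and coating; sewer loads
   are routed to freshwater with a configurable transfer coefficient,
   default 1, precautionary).
2. **Characterization.** Four indicators: global warming potential (GWP,
   kg CO₂-eq), cumulative energy demand (CED, MJ), human toxicity
   (non-cancer) potential (HTP) and freshwater ecotoxicity potential (FEP,
   PAF·m³·d). Nano toxicity factors follow the fate × exposure × effect
   chain `CF = FF · XF · EF` (or HEF for HTP). When a factor is missing,
   a deterministic cascade applies: direct entry → read-across surrogate →
   composition with missing FF/XF defaulted to 1 (precautionary) → error
   instructing a KPI-only assessment. Every fallback is recorded with a
   data-provenance tier (`measured_industrial` … `assumption`).
3. **Decision engine.** A stepwise framework walks a data-availability
   profile: if process-level data cannot be collected (or system
   boundaries are unknown) the assessment drops to five green-chemistry
   KPIs (solvent, electricity, heat, pollutants, waste — each per gram of
   nanomaterial); otherwise it produces a data plan and a complete,
   deterministic decision trace.
4. **Reporting.** Design screening against safe-by-design rules (size
   < 50 nm, aspect ratio > 1:5 (HARN), unstable coatings, persistence,
   reactivity, ROS, agglomeration, inhalation exposure, high release
   rate), per-process contribution hotspots with a dominance flag,
   reference-vs-alternative comparison with a trade-off flag, and
   uncertainty heat maps (process × indicator and nanoform × indicator,
   cells colored by provenance tier).

## Worked example

The package ships a fully synthetic case scenario: hydrogen production
from water and sunlight with a nano-TiO₂ photocatalyst (reference system)
versus a Cu₂O-coated variant with better photocatalytic activity (original
system), functional unit 1 g H₂. The registry carries published toxicity
characterization factors for the two nanoforms; inventory magnitudes are
synthetic lab-scale values.

```r
library(ssbdlca)

fx  <- make_case_fixture(case_params())
ref <- characterize(solve_inventory(fx$reference$system),
                    fx$reference$registry, fx$reference$assignment)
org <- characterize(solve_inventory(fx$original$system),
                    fx$original$registry, fx$original$assignment)
compare_systems(ref, org)
```

```
<comparison_report>
 indicator reference    original        delta  relative_delta verdict      unit
  GWP.bulk      0.12      0.0825      -0.0375         -0.3125  better kg CO2-eq
  GWP.nano         0           0            0               0   equal kg CO2-eq
  CED.bulk      4.58      2.8754      -1.7046 -0.372183406114  better        MJ
  CED.nano         0           0            0               0   equal        MJ
  HTP.bulk     1e-10     5.5e-11     -4.5e-11           -0.45  better   cases.d
  HTP.nano  0.068376 0.025564506 -0.042811494 -0.626118725869  better   cases.d
  FEP.bulk     3e-05    1.65e-05    -1.35e-05           -0.45  better  PAF.m3.d
  FEP.nano  1.060444   3.3922592    2.3318152   2.19890460977   worse  PAF.m3.d
trade-off flag: TRUE; overall: mixed
```

Read: the coated catalyst cuts GWP by 31 % and CED by 37 % per gram of
hydrogen (less catalyst, electricity and methanol per unit of product),
and even lowers nano human toxicity — but its freshwater ecotoxicity
factor (read across from copper oxide nanomaterials, 17 700 vs
3 443 PAF·d·m³/kg) more than triples the nano-basis FEP. The trade-off
flag marks exactly this pattern: an alternative that improves some
indicators while worsening another, i.e. a candidate that needs redesign,
not celebration.

When process data are missing entirely, the same package scores the batch
on green-chemistry KPIs instead:

```r
compute_kpis(solvent_ml = 250, electricity_kwh = 1.6, heat_kj = 900,
             waste_g = 12, nm_mass_g = 5)
#>   solvent_consumption                50 mL/g
#>   electricity_consumption          0.32 kWh/g
#>   heat_consumption                  180 kJ/g
#>   pollutant_emissions                 0 g/g
#>   waste_production                  2.4 g/g
```

A shell interface wraps the same pipeline
(`Rscript inst/cli/ssbdlca.R run --config config.yaml`, plus `kpi`,
`compare`, `fixture` and `validate` subcommands; exit codes 0/1/2 for
ok/validation/computation errors).

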