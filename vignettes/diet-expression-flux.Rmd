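---
title: "Modelling diet- and expression-constrained fluxes with sydicos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling diet- and expression-constrained fluxes with sydicos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sydicos)
```

## The model

sydicos treats a tissue as a stoichiometric network at steady state. A
`MetabolicModel` holds metabolites (with chemical formulas where known),
reactions (stoichiometry, flux bounds in mmol/mouse/day, a
gene-protein-reaction boolean rule, a subsystem label), genes, and one
biomass pseudo-reaction that consumes precursors in fixed proportions.
Flux balance analysis (`fba()`) maximises biomass flux subject to
`S v = 0` and the bounds; `pfba()` then fixes that optimum and minimises
the sum of absolute fluxes, which removes futile cycles and most
alternate-optimum ambiguity. All comparisons between conditions are made
on these parsimonious flux vectors.

Three constraint layers carry the biology, each produced as a *bound map*
(reaction, lower, upper; `NA` leaves a side untouched) and stacked with
`applyConstraints()`:

* **Diet** (`dietBounds()`). Each nutrient's maximum uptake is
  `b = (P/100) * W / M * 1000`, with `P` its % w/w in the diet, `W` the
  daily intake (default 3 g/day, the standard mouse figure) and `M` its
  molecular weight. The factor 1000 converts mol to mmol; this is the only
  dimensionally consistent reading of the mass-to-flux conversion. The
  bound caps only the *uptake* direction — the model may always take less,
  and secretion of a diet metabolite remains possible, so that boundary
  effluxes (glycerol, succinate) can be observed through the same
  exchanges. The diet's available carbon is `C_moles = sum C_j b_j`
  (`dietCarbonFlux()`); the same weighting applied to solved exchange
  fluxes gives the influx/efflux carbon totals
  (`effluxInfluxSummary()`).
* **Respiration** (`gasBounds()`). A measured gas volume becomes
  `b = p V / M * 1000` and is imposed as the *minimum* rate of O2
  consumption or CO2 production. Which direction a gas constrains is
  configurable, since that assignment is condition-specific.
* **Expression** (`efluxBounds()`, an adapted E-flux). A reaction's bound
  is its GPR rule evaluated on mean expression across biological
  replicates: OR nodes (isozymes) sum, AND nodes (complex subunits) take
  the minimum, a missing gene contributes 0 (so a reaction whose only
  catalyst was not measured is blocked; both choices are arguments).
  Irreversible reactions get `(0, b)`, reversible ones `(-b, +b)`.
  Orphan reactions and exchanges are never expression-constrained. Raw
  expression values are used as bounds (units declared as
  expression-units/day); no flux-unit rescaling is attempted, so
  expression bounds are meaningful relative to one another and to the
  diet bounds' order of magnitude, not absolutely.

The AND-as-minimum rule and the raw-unit choice are the two genuinely open
conventions here; both are the field's standard E-flux practice and are
isolated behind `efluxBounds()` so alternatives are one function away.

## SyDiCoS

`swapDiet()` builds the effective diet of a `SwapPlan`: every metabolite
whose component class (carbohydrate, lipid, amino acid) is being swapped
takes its % w/w from the reference diet (zero if absent there), everything
else keeps its base value, and the base intake is retained. Swapping
operates at the metabolite level; class totals swap as a consequence. This
makes the full swap an exact identity — swapping all three classes
reproduces the reference diet's bounds entrywise — and makes swaps
involutive. `restrictSugars()` additionally zeroes all carbohydrates
outside a kept set. `runSydicos()` crosses a list of (typically
expression-constrained) models with a list of plans, solves each cell with
`pfba()`, and records per-cell status so one infeasible cell does not
abort a batch.

Divergence between conditions is quantified by the Euclidean distance
between flux vectors over their shared (id-sorted) reactions, presented
relative to the maximum pairwise distance (`distanceMatrix()`), by
per-reaction flux ratios with epsilon-coded "new"/"off" categories instead
of infinities (`fluxRatio()`), and per subsystem by the fraction of
flux-carrying reactions with higher flux in one condition
(`subsystemReactionRatio()`; a ratio of 1 means the whole subsystem runs
higher). `differentialSubnetwork()` turns the differential reactions of
selected subsystems into a reaction-metabolite bipartite graph — excluding
a configurable currency-metabolite list (water, protons, ATP/ADP, NAD(H),
CO2, phosphate by default), which would otherwise connect everything to
everything — and returns the connected component containing the biomass
reaction.

## Curation

Model assembly follows the usual merge-then-clean sequence.
`mapMetaboliteIds()` renames metabolites onto a common namespace (e.g.
KEGG), merging same-compartment collisions and re-pointing reactions;
identical target ids in different compartments are kept apart and
compartment-qualified. `mergeModels()` unions models id-wise and records
reaction provenance. `removeDuplicates()` collapses reactions with
identical canonicalised stoichiometry — terms sorted by metabolite, the
orientation of reversible reactions normalised so reverse-written
duplicates collapse too — OR-joining their GPRs and keeping the widest
bounds. `elementalBalance()` checks C, N, O, S and P (hydrogen is
excluded: proton bookkeeping is not tracked); reactions touching a
formula-less metabolite are "undetermined", never "balanced", and
exchanges are skipped as imbalanced by construction.
`pruneImbalanced()` removes imbalanced reactions one at a time in
lexicographic id order — the order is a determinism choice, as any fixed
order gives reproducible results — keeping a removal only if the biomass
optimum stays within `biomass_tolerance` (default 1e-6 relative, the
strictest reading of "unchanged") and all previously passing metabolic
tasks still pass; otherwise the reaction is reinstated and flagged for a
human. Task checking (`checkTasks()`) is feasibility-only: all exchanges
are closed, the task's inputs opened up to their caps, required outputs
imposed as minimum production, and temporary exchanges added for task
metabolites lacking one. `stoichiometricConsistency()` solves
`max sum z` s.t. `t(S_int) m = 0`, `0 <= z <= min(m, 1)`, `m >= 0` and
reports metabolites with `z < 1 - 1e-6` — those that cannot carry a
positive molecular mass. `expressionGateExtraction()` is a deliberately
simple context-specific extraction (documented as *not* a task-driven
MILP such as tINIT): reactions whose genes are all below the "none"
expression threshold (< 1 FPKM) are dropped one by one in id order, each
drop kept only if every task still passes and biomass stays feasible.
This per-candidate variant of "remove, then greedily reinstate" is
equivalent in guarantee, deterministic, and never reinstates a reaction
that was not needed.

Expression classes follow the FPKM convention: high >= 50,
medium 10-50, low 1-10, none < 1 (the bins partition the axis; the
medium bin is read as `10 <= v < 50`).

## Linear programming

No LP library is assumed: `solveLP()` is a dense two-phase primal simplex
with Dantzig pricing and an automatic switch to Bland's rule after an
iteration budget, which guarantees termination on degenerate problems.
Finite lower bounds are shifted out, finite upper bounds become explicit
rows, and equality rows get phase-1 artificials. Pivot and feasibility
tolerances default to 1e-9. This is appropriate for the problem sizes the
package targets (tens to a few hundred variables); it is not a
replacement for an industrial solver on genome-scale inputs.

`pfba()` splits `v = v+ - v-` and minimises `sum(v+ + v-)` subject to the
stage-1 objective held within `objective_fix_tolerance` (relative). The
default is 1e-9: the minimisation stage always exhausts whatever slack it
is given, so a loose fix tolerance would systematically bias the reported
objective low; 1e-9 keeps the two stages' objectives numerically
identical while preserving feasibility. Residual degeneracy after L1
minimisation is acknowledged; determinism of the solver (fixed pivoting
order) makes repeated runs bit-identical, which the distance analyses
rely on.

## The synthetic fixtures

The generators stand in for a real study's deposited data and define the
conditions every test runs under.

`makeToyHepaticModel()` builds a fixed ~47-reaction hepatocyte-like
network over extracellular/cytosol/mitochondria compartments: glucose and
fructose uptake, glycolysis, fructolysis branching to glycerol efflux, a
TCA cycle with succinate efflux, fatty-acid uptake and activation with
the choice of carnitine-shuttle beta-oxidation or acylglycerol synthesis,
a serine-synthesis branch, O2/CO2/water exchange, and a biomass reaction
consuming triacylglycerol, serine and hexose phosphate. Metabolite
formulas are small, slightly simplified compositions (phosphate moieties
implicit), chosen so every internal reaction balances C, N and O exactly;
oxygen stoichiometries are the device that closes the oxidative reactions,
so gas exchange has the usual meaning. Every internal reaction carries a
GPR with pathway-tagged genes; gas/water diffusion and biomass are
orphans.

`makeSyntheticDiets()` returns two fixed compositions over the toy
nutrients (values in % w/w, intake 3 g/day): a control-like diet (glucose
60, fructose 0, palmitate 6, alanine 18) and a western-style-like diet
(glucose 25, fructose 25, palmitate 20, alanine 18). The western-style
fixture therefore has more lipid, less total carbohydrate, contains
fructose, and offers more total carbon (105.6 vs 89.4 mmol C/day). Diets
are constants, not samples, so identity properties hold exactly.

`makeSyntheticGas()` supplies O2/CO2 volumes of 0.045/0.050 L/day. These
are scaled to the toy network's magnitudes (its diet supplies ~100 mmol
C/day, two orders below a real mouse), keeping the forced respiration
(~2 mmol/day) binding but satisfiable under every diet plan.

`makeSyntheticExpression()` draws a log-normal baseline per gene
(meanlog `log(5)`, sdlog 0.35) as the peritumoral-like profile and scales
beta-oxidation genes by 0.25 and lipid- plus serine-synthesis genes by 4
for the tumor-like profile. Pathway-level baseline multipliers (lipid
synthesis 0.1, serine synthesis 0.2, beta-oxidation 0.5) place the
regulated pathways' capacities at the scale of the diet-driven demands
while central-carbon enzymes stay in excess; without that, expression
bounds would never bind at toy flux scales and the two conditions would
be computationally indistinguishable. With it, the designed qualitative
behaviour emerges: on the western-style diet the tumor-like model's extra
lipid/serine capacity is usable and the two flux distributions diverge,
while after a full swap to the control composition the scarce dietary fat
limits both models identically and the divergence collapses. This is a
designed property of the fixtures, not an empirical claim about any real
tissue.

`perturbModel()` injects machine-checkable flaws for the curation tests:
carbon-imbalanced dead-end reactions (an existing metabolite converted to
a new one whose formula gains a carbon), exact duplicates under new ids,
and a self-amplifying `X -> 2X` reaction on a fresh formula-less
metabolite (formula-less so the elemental ground truth stays exact).
Dead-end and self-amplifying constructions keep the injected flaws
independent of each other and of the network's function.

What the fixtures do *not* emulate: real nutrient panels (no attempt to
match actual rodent diet sheets), realistic FPKM distributions or
replicate noise, digestion/absorption or microbiome transformation of
nutrients (diet components are assumed directly available to the tissue),
multi-tissue exchange, or genome-scale network size. Passing tests on
these fixtures demonstrates the correctness and the designed qualitative
behaviour of the machinery, not quantitative predictions for real livers.

## Problem sizes and runtime

The test-suite and the acceptance script run entirely on the toy scale:
the 47-reaction network (LPs with up to ~170 variables in the
parsimonious stage), 50 random networks of at most 12 reactions for the
solver cross-checks, 20 seeds for the stochastic properties, 100 random
GPR rules, and 1000 random vector triples for the metric properties.
Each LP solves in well under a second; the full suite takes about a
minute on one core.

## Known limitations

* The simplex is dense; genome-scale models need an external solver.
* Tabular and SBML I/O cover the constructs this package produces
  (fbc bounds, gene associations, notes-based subsystems), not the full
  SBML zoo (no RDF annotations, units, or groups extension).
* `flux ratio` and subsystem statistics inherit pFBA's residual
  degeneracy: reactions interchangeable at identical L1 cost may flip
  between equivalent solutions on different platforms.
* Elemental balance trusts the stated formulas; there is no automatic
  formula inference or correction, by design — irreparable reactions are
  flagged for a human.
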