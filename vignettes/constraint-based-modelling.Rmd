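---
title: "Constraint-based modelling of a citric-acid fermentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based modelling of a citric-acid fermentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citflux)
```

`citflux` models the metabolism of citric-acid-producing filamentous fungi
with the standard constraint-based toolkit: a stoichiometric network with
flux bounds and Boolean gene rules, a measured-composition biomass
objective, linear-programming flux analysis, and a dynamic extension for
batch fermentations. This vignette explains the models and the design
decisions; the README shows the quick tour.

## The steady-state model

A metabolic network with $m$ metabolites and $n$ reactions is summarised by
its stoichiometric matrix $S \in \mathbb{R}^{m\times n}$. Flux balance
analysis assumes the intracellular metabolite pools are at steady state and
solves

$$\max_{v}\; c^\top v \quad \text{s.t.}\quad S v = 0,\quad l \le v \le u,$$

usually with $c$ selecting the biomass reaction, whose flux then *is* the
specific growth rate $\mu$ (h$^{-1}$). Boundaries are modelled as exchange
pseudo-reactions on extracellular metabolites (negative flux = uptake);
transporters are reactions whose participants span two compartments. The
model vocabulary is fixed at four compartments — extracellular, cytosol,
mitochondria, peroxisome — which is how fungal genome-scale
reconstructions in this family are laid out.

Gene–protein–reaction rules are Boolean trees over gene ids: `and` encodes
an enzyme complex (every member required), `or` encodes isozymes (any
suffices), with `and` binding tighter than `or`. A gene deletion closes
exactly the reactions whose rule evaluates false without it. Enzyme
complexes are counted as the distinct ALL-OF gene sets (with at least two
members) of the rules' disjunctive normal forms, deduplicated at set level
across reactions — the conservative reading when a published complex count
does not state its deduplication rule.

### The LP solver

No linear-programming backend is assumed: the package carries a
two-phase bounded-variable primal simplex (Bland's anti-cycling rule,
periodic refactorisation of the basic solution to shed floating-point
drift). All model bounds are finite by construction (the conventional
±1000 mmol gDW⁻¹ h⁻¹ defaults), so every solve terminates either at an
optimal vertex or with a certificate of infeasibility; unboundedness
cannot arise. The solver is validated in the test suite against brute-force
vertex enumeration (all basic solutions of the toy network) to $10^{-8}$.
The optimal *objective value* is unique and is what the package asserts
on; the returned flux vector is one optimal vertex and is not unique under
degeneracy.

## Curation procedures

*Dead ends.* A metabolite is a dead end when it cannot support steady-state
flux: no producer, no consumer, or its only producer and consumer are one
and the same (non-exchange) reaction — a lone reversible reaction cannot
both make and clear a metabolite at steady state, while a boundary exchange
is a genuine source *and* sink. Reversibility is honoured via the bounds.
`prune_dead_ends()` iterates detection and removal of the (non-exchange,
non-objective) reactions touching dead ends until a fixed point; the result
is provably idempotent and never changes the FBA optimum, because the
removed reactions can carry no flux in any feasible solution. The pruner is
tested for equivalence against a remove-one-reaction-and-recheck oracle on
50 seeded random networks.

*Generic reactions* touch metabolites without an exact mass: missing
formulas or residue markers (e.g. `R-COOH`), detected by a strict
element-count parser. *Mass balance* reports per-reaction net elemental
imbalances, with exchanges and the biomass reaction exempt (they are
unbalanced by design). *Producibility* opens a temporary demand per biomass
substrate and asks for flux above $10^{-6}$ mmol gDW⁻¹ h⁻¹ (the LP noise
floor). Currency metabolites are exempt by default: water/protons (no C, no
N) and any consumed metabolite whose C/N backbone matches a co-produced
partner (the ATP/ADP maintenance couple) can never show *net* production —
the moiety is conserved — and testing them would only ever report false
gaps. *Blocked reactions* are those whose flux range under FVA at zero
objective requirement is exactly $\{0\}$. Cofactor-specificity curation
(e.g. removing NADH variants where the enzyme is NADPH-specific) is a data
edit, not an algorithm, and is handled by declarative TSV patch files with
a reason column.

## The biomass objective

Measured bulk fractions (g per g dry weight) of DNA, protein, lipid, cell
wall, RNA, ash and a small-molecule pool are converted to stoichiometric
coefficients through a monomer table: monomer $j$ of component $k$ enters
with $-f_k\,x_{jk}/M_{jk}$ mmol gDW⁻¹, where $f_k$ is the bulk fraction,
$x_{jk}$ the molar fraction within the macromolecule and $M_{jk}$ the
residue molar mass (g/mmol). The shipped measured composition for
*A. tubingensis* DJU120 covers both growth morphologies; the pelleted
column (the one relevant for citric-acid production) is the default. The
component fractions sum to 0.94724 (pelleted) and 0.97214 (filamentous)
g/gDW, within 0.002/0.005 of the published column totals — the residual is
rounding of the individually printed components, and both totals are
reported rather than reconciled. RNA, ash and pool fractions are
carried over from published *A. niger* biomass equations (RNA from
iDU1756; ash and pool from iJB1325), as the measured assays covered DNA,
protein, lipid and cell wall.

Monomer-level splits are not part of the measured data, so the default
monomer table works at pseudo-monomer granularity (one representative
residue per macromolecule class, a glucan/chitin cell-wall split) and is a
user-editable CSV; organism-specific amino-acid or lipid spectra can be
dropped in without code changes. Ash and pool are non-metabolic drains.
Growth-associated ATP maintenance is a configurable coefficient on an
`atp + h2o -> adp + pi` couple — published fungal models differ on its
value, so it is an explicit argument (`gam`), not a constant. Vitamins and
trace cofactors are deliberately excluded from the equation: they
contribute negligibly to dry weight, though the pathway content to make
them can still exist in a model. `phosphorus_content()` sums coefficient ×
P atoms over the consumed monomers; it is what couples growth to
extracellular phosphate drawdown in the dynamic model.

## Phenotype simulation

Carbon-source growth screens are simulated on a minimal base medium:
inorganic exchanges open without limit, all carbon exchanges closed, the
single tested source opened at 10 mmol gDW⁻¹ h⁻¹, and growth called when
the FBA optimum exceeds $10^{-3}$ h$^{-1}$. Neither the simulated uptake
rate nor the in-silico growth threshold is something a plate assay pins
down, so both are arguments with these defaults. A source whose exchange
reaction is absent is classified `no_exchange` — a modelling gap surfaced
to the curator, not adjudicated as right or wrong. The comparison report
keeps the full TP/TN/FP/FN/no-exchange classification per source.

## Dynamic FBA

Batch fermentation is simulated with the static-optimisation approach:
at each step the exchange bounds are set from the current extracellular
state, the LP is solved, and concentrations are advanced by explicit Euler:

- glucose uptake bound: high-affinity Michaelis–Menten term
  $V^{hi}_{max} S/(K^{hi}_m + S)$ always, plus a low-affinity term once
  glucose exceeds 75 g/L (two-transporter physiology of high-sugar
  fermentations);
- xylose uptake bound: passive, linear-in-concentration entry
  $k_{passive} S_{xyl}$ always; the transporter-mediated Michaelis–Menten
  term only when external glucose is at or below 5 mM (glucose
  repression). With 80 g/L initial glucose the repression threshold is
  never crossed, so xylose moves by passive uptake alone — the sequential
  sugar use the model family is built to capture, asserted directly on the
  per-step bounds in the tests;
- phosphate uptake: demand-driven below a configurable cap while
  extracellular phosphate remains, zero after depletion (the main-text
  sources do not specify phosphate kinetics, so the cap is a config
  value);
- maintenance: the ATP-hydrolysis reaction's lower bound is pinned at
  NGAM = 1.9 mmol gDW⁻¹ h⁻¹;
- updates: $X \leftarrow X(1+\mu\,\Delta t)$; sugars and citrate in g/L via
  molar masses (180.16, 150.13, 192.12 g/mol), phosphate in mM directly;
  the 5 mM glucose threshold is compared in mM (5 mM ≈ 0.90 g/L). All unit
  conversions are centralised in one constant table.

The objective policy is two-phase: maximise growth; when optimal $\mu$
falls below $10^{-4}$ h$^{-1}$ (typically at phosphate exhaustion),
maximise citrate secretion under the same uptake bounds. The citrate
overflow mechanism itself is inherited from the dynamic-modelling
tradition this design follows; the policy is configurable and each step's
phase is logged. Runs start at `t_start = 10` h — a lag-phase offset after
inoculation — and states before it can be reported as constant for
plotting. An infeasible step (maintenance unsatisfiable after substrate
exhaustion) truncates the trajectory cleanly with the reason recorded;
concentrations are clamped at zero with the clamp logged, never silently
negative.

Integration uses $\Delta t = 0.1$ h by default. A refinement check is part
of the tests: with slow phosphate-limited growth, halving $\Delta t$ moves
endpoints by under 1%; near discrete events (depletion, phase switch) the
first-order Euler error is dominated by event-time quantisation, which is
why the convergence check is run in a window that crosses no event.
`carbon_balance()` audits every run: cumulative carbon into biomass,
citrate and vented CO₂ over cumulative carbon from consumed sugars, which
stays at $1 \pm 10^{-3}$ on the balanced toy model.

### Kinetic parameters

The uptake $V_{max}/K_m$ values are supplementary-only in the source
study and are therefore configuration, not constants. The defaults
(`kinetic_parameters()`: $V^{hi}_{max}=1.0$, $K^{hi}_m=0.5$ g/L,
$V^{lo}_{max}=1.5$, $K^{lo}_m=20$ g/L, $V^{xyl}_{max}=0.8$,
$K^{xyl}_m=2$ g/L, $k_{passive}=0.005$ mmol gDW⁻¹ h⁻¹ per g/L, phosphate
cap 0.1 mmol gDW⁻¹ h⁻¹) are physiologically plausible magnitudes for a
sugar-fermenting fungus, chosen once; the switching thresholds (75 g/L,
5 mM), NGAM (1.9) and start offset (10 h) are the stated study
conditions. Passive xylose uptake is assumed linear in concentration
(configurable), the simplest reading consistent with "passive means".

## The synthetic study system

`make_toy_model()` builds a ~39-reaction, four-compartment caricature with
lumped, elementally balanced reactions and small (half-)integer
coefficients, so every optimum used in testing is hand-derivable: lumped
glycolysis (2 ATP/glucose), lumped respiration (14 ATP/pyruvate),
xylose isomerisation (6 xyl → 5 glc, carbon-exact), a mitochondrial
citrate branch (2 pyr + ½ O₂ → citrate) with shuttle and secretion, and a
biomass equation built from the measured pelleted composition through a
toy monomer table (glucan-mass precursor, 1-P nucleotide, 1-P
phospholipid; P demand 0.309 mmol/gDW). Optional decoy dead-end appendages
(peroxisomal) exist solely so the pruner has exactly `n_decoy_deadends`
reactions to find. The closed-form growth yield on glucose
(`(30·uptake − NGAM)/(30·prec + ATP-per-μ)` from the lumped ATP budget) is
frozen into the tests as an arithmetic oracle independent of the solver.

The phenotype fixture is a designed 10-source panel with known classes
(3 TP, 3 TN, 1 FP, 1 FN, 2 no-exchange). The fermentation generator runs
the toy dFBA under known kinetics, subsamples ~10 time points, and adds
multiplicative Gaussian noise (CV 2%, truncated at zero) per replicate,
emulating triplicate offline sampling with s.d. error bars. All fixtures
regenerate byte-identically from `(spec, seed)`.

What the toy does *not* emulate: the scale of a real reconstruction
(thousands of reactions), redundant isoenzyme routes, secondary
metabolism, pH/oxygen dynamics, or morphology effects. Green tests
demonstrate the *algorithms* (pruning, LP optimality, switching rules,
carbon conservation, estimator consistency) — not that the shipped
defaults reproduce any particular organism's fermentation curve, which
requires the real model and measured kinetic parameters as inputs.

## Problem sizes and numerical choices

The suite runs the toy model (≤ 39 reactions), 50 random 50-reaction
networks for the pruning oracle, vertex enumeration on the 19-reaction
core network, dFBA horizons of 10–40 h at $\Delta t$ 0.2–0.5 h, and a
one-dimensional least-squares fit (golden-section search) for the glucose
$V_{max}$ from 10-point triplicate data — sizes at which every check is
exact or hand-derivable. Tolerances: LP feasibility $10^{-6}$ (steady
state) / $10^{-9}$ (bounds and reduced costs), producibility and
blocked-reaction calls at $10^{-6}$ flux, growth calls at $10^{-3}$
h$^{-1}$, objective-phase switch at $10^{-4}$ h$^{-1}$. Ties in the
simplex are broken by smallest variable index (Bland), making every solve
deterministic; the only randomness anywhere is the synthetic noise and
panel shuffling, always behind an explicit seed.

## Known limitations

- The returned flux vector under degeneracy is solver-dependent; only the
  objective value is asserted.
- The pure-R simplex is built for networks up to a few thousand reactions;
  genome-scale FVA (two LPs per reaction) is minutes, not seconds.
- Euler integration is first-order; near depletion events the step size,
  not the kinetics, sets the local error. The refinement utility
  (`run_dfba()` at two step sizes) is the intended check.
- The biomass monomer table defaults are convention-level, not measured;
  conclusions about monomer-resolved demands need an organism-specific
  table.
- Phenotype simulation calls growth from stoichiometric capability alone;
  regulation, toxicity and kinetic limitations — common causes of in-vivo
  no-growth on capable networks — are out of scope, which is why
  false-positive sources are surfaced rather than "fixed".
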