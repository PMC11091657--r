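---
title: "Methods: constraint-based flux inference for a GABA-producing knockout strain"
author: "fluxgaba"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based flux inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxgaba)
```

## The problem

A recombinant *Escherichia coli* strain producing gamma-aminobutyrate
(GABA) carries two gene deletions, *sucA* and *gabT*, which remove
2-oxoglutarate dehydrogenase (AKGDH) and 4-aminobutyrate aminotransferase
(ABTA) from its metabolic network. The strain is grown in batch
fermenters under three condition sets -- neutral pH with 2 g/l succinate,
acidic pH with 2 g/l succinate, and acidic pH with 4 g/l succinate -- and
for each condition the specific growth rate and the exchange rates of
five metabolites (glucose, succinate, GABA, glutamate, acetate) are
measured during the exponential phase. The question is what happens
*inside* the cell: which central-carbon reactions speed up, slow down or
change direction when the pH drops or more succinate is fed.

Intracellular fluxes cannot be measured directly here, so they are
inferred by constraint-based modelling: a stoichiometric model of
metabolism is constrained by the measured rates and a flux distribution
is selected by optimisation. This package implements that pipeline end
to end, from raw fermentation time courses to a per-reaction,
per-pathway classification of flux changes.

## The model and the optimisation cascade

A metabolic model is a stoichiometric matrix $S$ (metabolites x
reactions), per-reaction flux bounds $lb \le v \le ub$ (mmol/gDCW/h),
gene-protein-reaction (GPR) boolean rules, and one biomass reaction
whose flux is the specific growth rate (h$^{-1}$). Steady state imposes
$S\,v = 0$. Exchange reactions follow the usual sign convention:
negative flux is uptake, positive is secretion.

**Knockouts.** A gene deletion set inactivates every reaction whose GPR
evaluates false (AND for complex subunits, OR for isozymes); inactivated
reactions get bounds $[0, 0]$. Because the study names the affected
reactions directly, reaction-level knockouts are provided as a separate
explicit list, and both paths are available (`apply_knockouts()`); on
this network `{sucA, gabT}` and `{AKGDH, ABTA}` close the same two
reactions.

**Measured rates.** One culture condition contributes six numbers: five
exchange-rate magnitudes with fixed physiological directions (glucose
and succinate are consumed, GABA, glutamate and acetate are secreted)
plus the growth rate. They can either be pinned as hard bounds
(`set_exchange_bounds(..., mode = "hard")`) or attached as references
for fitting.

**The default strategy, `lad-then-pfba`** (`simulate_condition()`):

1. *Least-absolute-deviation (LAD) reconciliation.* Measured rates are
   noisy and need not be jointly consistent with stoichiometry, so the
   pipeline first solves
   $\min \sum_i w_i\,|v_i - \hat v_i|$ subject to $S v = 0$ and the
   bounds, linearised with split deviation variables. When the
   measurements are jointly feasible the residual is zero and every
   referenced flux equals its measurement; otherwise the fit moves the
   smallest total amount of flux needed to reach the feasible polytope.
   All six references carry weight 1 by default, and the growth rate is
   a reference like the others rather than a hard constraint (the study
   does not state either choice; both are configurable).
2. *Pinning.* The six fitted values are fixed as hard bounds (half-width
   `pin_tol`, default $10^{-8}$, absorbing solver round-off).
3. *Parsimonious FBA.* Among the remaining flux states the pipeline
   maximises growth and then minimises total absolute flux
   $\sum_i |v_i|$ via the split $v = v^+ - v^-$ (two-stage LP,
   `optimum_fraction` of the stage-1 optimum retained; default 1.0, as
   no relaxation is stated for the study). Parsimony kills every
   stoichiometrically balanced internal cycle and gives a reproducible,
   minimal representative of the optimal set.

The alternative `hard-pfba` strategy pins the measured values directly
and skips reconciliation; with jointly feasible measurements the two
strategies coincide (this is a test in the suite).

**Degeneracy.** LP optima need not be unique in flux space. All
reported comparisons operate on the returned vertex, which is
deterministic for a fixed backend. This is a real limitation shared
with the original analysis (single flux values per reaction are
reported); conclusions should rest on reactions whose classification is
robust, e.g. those forced by the pinned exchanges.

## Solving the linear programs

All three methods are expressed as abstract LP descriptions
(`lp_problem()`) and handed to a pluggable backend (`solve_lp()`):

* `"simplex"` (default): a dense bounded-variable two-phase primal
  simplex implemented in the package. Non-basic variables rest at a
  bound rather than being split into slack rows, artificials are driven
  out in phase 1, and the entering rule switches from Dantzig to Bland
  when degeneracy is detected, guaranteeing termination. It is designed
  for the problem sizes of this analysis (tens to a few hundred
  variables), not for genome-scale matrices.
* `"highs"`: SciPy's HiGHS solver, called through the system `python`.
  It serves as the independent cross-check: the test suite asserts
  agreement of both backends to $10^{-6}$ on batches of random small
  networks, and the worked examples were additionally verified against
  COBRApy reading the very same model file.

Numerical tolerances: reduced-cost/ratio tolerance $10^{-9}$, phase-1
feasibility $10^{-7}$ (scaled), mass-balance acceptance $10^{-6}$,
reporting zero-tolerance $10^{-6}$; all configurable at the call sites.

## From fermentation curves to rates

`select_log_phase()` scans every contiguous window of the requested
width (default 4 h, matching the study's 3-5 h log phases) and keeps
the one maximising the least-squares slope of $\ln(\mathrm{OD600})$
against time, ties broken toward the earliest start; an exhaustive-scan
oracle in the tests confirms the choice. Within the window:

* $\mu$ = slope of $\ln(\mathrm{OD600})$ vs time;
* for each species, concentration (g/l converted to mmol/l via the
  molar masses: glucose 180.16, succinic acid 118.09, GABA 103.12,
  glutamate 147.13, acetic acid 60.05 g/mol, all overridable) is
  regressed against biomass $X(t) = f_X \cdot \mathrm{OD600}(t)$ and
  the specific rate is $q = \mu \, dC/dX$.

The yield-times-growth form is exact under balanced exponential growth
and therefore recovers the generator's truth to machine precision on
noiseless profiles; the alternative $(dC/dt)/\bar X$ agrees with it
exactly in that regime, which is why the closed form was chosen. The
OD-to-dry-weight factor $f_X$ defaults to 0.36 gDCW/l per OD unit; the
study does not state its factor, so all worked examples route rates
through the printed table rather than through $f_X$, and the estimator
tests only ever compare against the generator's own truth (where $f_X$
cancels by construction).

## The synthetic data

**Profiles** (`generate_profile()`) follow closed-form exponential
trajectories, $X(t) = x_0 e^{\mu t}$ and
$C_s(t) = C_s(0) + q_s \frac{M_s}{1000} f_X\, x_0 (e^{\mu t}-1)/\mu$,
with multiplicative lognormal noise (mean-corrected, coefficient of
variation `noise_cv`) drawn from a private seeded stream. Defaults
emulate the study's cultures: hourly sampling over 0-12 h, initial
OD 0.1, 20 g/l glucose and 2 g/l succinate, and the printed rate rows
as truth. They deliberately do *not* emulate lag or stationary phases,
substrate depletion kinetics, the pH shift itself, or induction
transients -- so passing the recovery tests shows the estimator is
correct for clean exponential growth, not that it is robust to the
pathologies of real curves (window selection is the only guard against
those).

**The network** (`build_toy_core()`) is a hand-curated, fixed
central-carbon model: PTS glucose uptake and glycolysis, the pentose
phosphate pathway, a TCA cycle with anaplerosis (PPC), malic enzyme
(ME2) and the glyoxylate shunt, acetate (PTAr/ACKr) and D-lactate
overflow, the GABA shunt (GLUDy, GLUDC, and the ABTA/SSALy route that
the knockout closes), a proton-pumping lumped respiratory chain, and a
lumped biomass drain. Every reaction except the biomass lump is
elementally balanced over CHNOPS with explicit protons and water (a
build-time check). Design choices worth knowing:

* *Biomass is carbon-light* (~9.6 mmol C/gDCW vs ~40 for real
  *E. coli*): the neutral-pH rate row secretes so much glutamate
  carbon that a realistic biomass would be infeasible; with the light
  biomass all three measured rows are jointly feasible for the
  knockout, which the builder verifies by feasibility LPs at build
  time. A consequence is that absolute growth yields are not
  comparable with real cells; only the constrained simulations are.
* *Biomass NADPH demand is 6 mmol/gDCW*, inside the biologically
  reported range; this routes growth-proportional flux through the
  oxidative PPP in every condition, so the pathway-level comparisons
  respond to the measured rates rather than to cofactor bookkeeping
  accidents.
* *D-lactate overflow* (visible in the study's fermentation profiles,
  though not in its rate table) is the free overflow valve that absorbs
  excess carbon; without it the pinned exchanges would force infeasible
  carbon balances.
* *A small biomass succinyl-CoA term* (lysine/diaminopimelate
  precursors) keeps SUCOAS flux-carrying. Its direction is therefore
  fixed on this network; the direction inversion of SUCOAS reported for
  the genome-scale model is a degenerate-optimum phenomenon that this
  fixture intentionally does not reproduce (the `inverted` class is
  exercised with constructed solutions instead).
* Unconstrained exchange caps default to 10 mmol/gDCW/h for the carbon
  feeds and 1000 elsewhere; internal reversible bounds are +-1000.

## Classifying flux changes

`classify_change()` is a pure function of the two fluxes, a ratio
threshold $T$ (default 0.20) and a zero tolerance $\epsilon$ (default
$10^{-6}$): both magnitudes below $\epsilon$ is `unchanged`; flux
appearing or vanishing across $\epsilon$ is `de-novo` / `abolished`;
a sign flip is `inverted`; otherwise `induced` iff $|b| > (1+T)|a|$ and
`suppressed` iff $|b| < |a|/(1+T)$. The ratio form (rather than a
one-sided relative change against $\pm T$) is what makes the
classification exactly antisymmetric under swapping the conditions --
a property the test suite checks over randomised inputs -- while still
reading as "changed by more than 20%". The three extra classes beyond
induced/suppressed/unchanged exist because a sign flip is not
expressible in a three-way scheme; `collapse = TRUE` folds them back
(inverted, de-novo into induced; abolished into suppressed) for
three-group pathway maps. `summarize_by_pathway()` partitions the
change set over a reaction-to-pathway map (glycolysis, pentose
phosphate pathway, TCA cycle, acetate fermentation, GABA shunt,
other).

## Problem sizes and runtime choices

The bundled network has 65 reactions and 59 metabolites; a condition
simulation solves three LPs of a few hundred variables and finishes in
seconds with the built-in solver. The property suites run on random
networks of at most 12 reactions (100 instances for the backend
agreement checks) and on 20-50 seeded noise replicates for the
estimator -- sizes chosen so the whole battery documents the claimed
tolerances while remaining quick to run routinely.

## Known limitations

* No flux variability analysis, loopless FBA, MOMA/ROOM or
  gene-essentiality scans; single-vertex reporting as discussed above.
* No thermodynamic or loop-law constraints; the respiratory lumping
  fixes the P/O ratio implicitly.
* The SBML reader covers Level 3 + FBC version 2 as used by
  constraint-based models (species, stoichiometry, fbc bounds,
  objectives, gene associations), not arbitrary SBML (no rules,
  events, or kinetic laws).
* The built-in simplex is dense; loading a genome-scale model works,
  but solving one is outside its design envelope -- plug in the
  `"highs"` backend for anything large.
* Conditions differ only through their measured rate vectors, exactly
  as in the computational treatment of the study; pH itself, induction
  and regulator effects are not modelled.
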