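---
title: "Methods: diet optimisation against nutrient reference values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet optimisation against nutrient reference values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dietopt)
```

# The model

`dietopt` frames weekly diet design as a mixed-integer linear program over
integer serving counts `x_i` per food item. Working at the food-item level
(rather than food groups) keeps serving sizes realistic and lets the solver
trade off individual foods against nutrient targets, price, and
greenhouse-gas emissions (GHGE).

**Supply.** One serving of food `i` supplies
`comp[i, n] * serving_g[i] / 100` of nutrient `n` (compositions are per
100 g edible portion, cooked form where cooking is required; a food eaten
both raw and cooked is two items sharing a name stem). For protein and the
nine essential amino acids the supply is further multiplied by a
bioavailability coefficient in `[0, 1]`, so requirement bounds for those
nutrients apply to *absorbable* supply; all other nutrients are constrained
on gross amounts. The coefficient map is extensible — minerals such as
iron, zinc and calcium are obvious future candidates — but ships applying
only to protein and the amino acids.

**Constraints.** Requirement sets hold daily recommended intakes (RDI,
lower bounds) and upper limits (UL, upper bounds, present only where
defined) per sex and adult age group (19–30, 31–50, 51–69, 70+). Diets are
weekly, so bounds are scaled by 7 (`to_weekly()`, linear in the bounds).
Bounds are closed: a supply exactly at a bound is adequate. Energy is an
ordinary nutrient whose bounds are absent by default — nothing in the
requirement machinery treats it specially, and a config can bound it.
Optional cap rows limit total price and/or emissions to a fraction of the
baseline diet's totals (0.7 in the stock scenarios).

**Objectives.** `MIN_DEVIATION` minimises the L1 distance in serving
counts from a baseline diet, linearised with one continuous auxiliary and
two inequalities per food. L1 is the standard linearisable choice for
"minimal change from current habits"; L2 would destroy linearity, and L∞
ignores how many foods change. Deviation is measured per food item, not
per group. `MIN_PRICE` and `MIN_GHGE` are plain linear costs.

**Integrality.** Serving counts are integer — people eat whole servings —
which together with the continuous deviation auxiliaries makes the program
genuinely mixed-integer. `decision_spec(db, integer = FALSE)` relaxes to
the LP for sensitivity analysis. Each food has a weekly serving ceiling
(default 200), a modelling guard that keeps minimum-price/-emission
scenarios bounded and the enumeration oracle finite; it is not a
nutritional claim.

**Exclusions.** Foods excluded by scenario policy (alcoholic beverages in
every optimised scenario: a dietary model should never recommend more
alcohol) are fixed at zero *and dropped from the deviation objective* —
their removal is forced, not a choice the optimiser should be charged for.

# Solving and verification

No MILP solver is available in the target R environment, and solving is
infrastructure rather than the scientific contribution, so models built in
R (dense constraint matrices; instances here are tens of variables) are
solved by HiGHS through `scipy.optimize.milp` in a `python` subprocess
(`inst/python/milp_solve.py`), batched so a whole scenario battery costs
one interpreter start. Three safeguards keep the bridge honest:

* every "optimal" vector is rounded (integrality residual must be < 1e-5)
  and re-audited **in R** from the serving vector alone — nutrient rows and
  caps to an absolute tolerance of 1e-6 in each constraint's natural units;
  a violation raises an internal-consistency error rather than returning;
* the reported objective is recomputed from the serving vector, never
  copied from the solver;
* an independent pure-R exhaustive-enumeration oracle
  (`brute_force_optimum`, budget-guarded at 1e7 candidates) must agree
  exactly — status and objective to 1e-9 — on randomized small instances
  (≤ 5 foods, ceiling 4, ≤ 6 bound nutrients, all objective kinds, with
  and without caps).

On infeasibility the model is re-solved with elastic slack (one
non-negative slack per finite bound side, minimising total slack) and the
minimal-violation nutrients are reported — diagnosis plumbing, useful when
a requirement set is unattainable for a given database.

HiGHS is deterministic for a fixed model, so the seed threaded through
`run_battery()` governs only fixture generation; the audit means solver
nondeterminism could not silently alter reported totals anyway. Ties
between optima are legal; tests compare objective values, never argmin
vectors, except where the optimum is unique by construction.

# Database compilation

The compilation utilities mirror how national food databases are assembled:

* `average_compositions()` — nutrient-wise arithmetic mean of the top
  `cap` (default 3) ranked matches; records flagged must-retain (grouped
  items like "onion/garlic/leeks" needing one composition per constituent)
  enter the mean even beyond the cap. Matching *rank is an input*, not an
  algorithm — how "best-matching" is scored is a curation decision upstream
  of this package. Missing nutrient values are excluded from that
  nutrient's mean rather than read as 0, which would bias compositions
  downward.
* `normalise_amino_acids()` — amino-acid profiles (often from a
  supplementary source) are stored per g protein so they rescale with any
  protein content; zero protein with non-zero amino acids is rejected as
  inconsistent.
* `average_price()` — store observations (package price, package mass)
  are converted to currency/kg and averaged. Per-kg is chosen so price and
  emission factors share a mass basis; currency is an opaque label
  (default NZD).
* `load_food_database()` — joins compositions, prices, emission factors
  and serving data; foods missing auxiliary data are dropped and reported,
  while auxiliary rows naming unknown foods are hard errors. Loading is
  deterministic: identical files give a byte-identical serialised
  database.

Baseline diets accept fractional weekly serving counts (survey-derived
simulated diets are averages); `remove_items()` handles the
contaminant-monitoring items such baselines carry but diet models should
not.

# The synthetic world

Real national composition databases, survey baselines and retail price
collections are not redistributable, so every test runs on a seeded
synthetic world (`synth_spec()` / `synth_generate()`). Its defaults are a
stated world, chosen once:

* 32 foods across the eleven groups (scaled down from the hundreds of a
  national list), 13 nutrients with realistic units and bound kinds
  (sodium UL-only, energy unbounded);
* group-archetype densities (dairy calcium-rich, meat/seafood dense in
  protein/B12/zinc and emission-heavy at ~14 kg CO2-eq/kg, grains cheap
  and fibre-rich, oils nearly pure fat) with log-normal spread 0.4;
* log-normal prices and emission factors correlated at 0.3 within foods;
* bioavailability 0.85–0.95 for animal-source foods, 0.6–0.85 otherwise;
* ~10% of foods fortified (one nutrient ×10), echoing the fortified
  products that dominate real minimum-emission solutions.

**Feasibility by planting.** A known integer, alcohol-free diet within the
serving ceilings is drawn first; requirement lower bounds are set at
55–80% of its supply (scaled mildly by age group) and upper limits at 3×,
so the planted diet is a feasibility certificate for every demographic —
including capped scenarios, because the baseline is the planted diet
inflated ×2 (plus alcohol), putting the certificate at ≤ 50% of baseline
price and emissions, below the 70% caps. Construction, not rejection
sampling: feasibility holds at any size and seed. `infeasible_on` worlds
instead push one nutrient's lower bound 1.5× above the maximum attainable
supply under the ceilings, so solver and oracle must both report
infeasibility.

The baseline additionally omits a dropout set of planted foods — chosen
concentrated-nutrient-sources-first, capped at 20% of planted price and
emission share so the cap guarantee survives — mimicking how survey
baselines miss specialty items. Some seeds therefore show baseline
nutrient inadequacies and "new items" in optimised diets; many do not,
and generated baselines are still gentler than real survey diets, which
are pervasively inadequate. A green battery on this world therefore
establishes the *mechanics* (constraint satisfaction, cap handling,
dominance, variety collapse), not nutritional realism — the generator
makes no claim to emulate any country's actual values.

`percent_change()` reports scenario-vs-baseline shifts; a quantity absent
at baseline but present in an optimised diet is flagged `"new"` rather
than given an undefined percent.

# Numerical choices

* constraint audit: 1e-6 absolute per constraint; solver-vs-oracle
  objective: 1e-9; integrality residual: 1e-5; oracle feasibility uses
  1e-9 closed bounds.
* enumeration ties: all optima returned, so tie-dependent tests cannot
  pass by luck.
* JSON serialisation uses full precision (`digits = NA`); CSV round-trips
  are tested to 1e-12.
* infinities cross the Python bridge as ±1e30 sentinels (JSON has no Inf).

# Known limitations

* Single-objective only: no Pareto frontiers across price/emissions, no
  acceptability terms beyond L1 deviation, no robustness to price
  volatility.
* The deviation metric treats a serving of any food equally; a diet
  swapping 5 servings of one staple is "as acceptable" as one swapping 5
  condiment servings.
* Bioavailability is a per-food scalar per nutrient; meal-context effects
  (e.g. enhancers/inhibitors of mineral absorption) are out of scope.
* The solver dependency is an external `python` + scipy; without it model
  *construction*, evaluation, audits and the enumeration oracle still work,
  but `solve_model()` does not.
* Requirement sets cover non-pregnant adults only; EAR/probability-of-
  adequacy modelling is out of scope.
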