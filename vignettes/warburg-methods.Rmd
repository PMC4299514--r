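---
title: "Modelling forced lactate secretion and the glycolytic-to-oxidative ATP ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling forced lactate secretion and the glycolytic-to-oxidative ATP ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warburgfba)
```

## The model

Aerobic glycolysis — lactate secretion despite available oxygen — is the
classic Warburg phenotype of cancer cells. `warburgfba` studies it with
constraint-based metabolic models: a stoichiometric matrix $S$ over $m$
metabolites and $n$ reactions, a flux vector $v$ constrained by steady-state
mass balance $S\,v = 0$ and per-reaction capacity bounds
$v_{\min} \le v \le v_{\max}$, and linear-programming optimisation of a
biomass flux (flux balance analysis, FBA). Three quantities organise the
whole package:

* **Forced lactate secretion** — the *minimal* feasible lactate-export flux
  at maximal biomass. If it is strictly positive, the model cannot grow
  optimally without fermenting; that dichotomy (positive in tumour-derived
  models, zero in normal proliferating ones) is the structural signature the
  pipeline reproduces and exploits.
* **ECAR / OCR / EOR** — the mean lactate-secretion flux (a proxy of the
  extracellular acidification rate), the mean oxygen-uptake flux, and their
  ratio, all averaged over flux distributions sampled from the
  maximal-biomass face of the flux polytope.
* **AFR** — the ratio of mean glycolytic ATP-producing flux to mean
  oxidative ATP-producing flux, each reaction weighted by its ATP
  stoichiometric coefficient. Larger AFR means a more "Warburgian"
  bioenergetic state.

Because every quantity beyond the plain optimum is an average over the
*optimal face* — the sub-polytope of flux vectors attaining maximal biomass —
the package ships a hit-and-run sampler restricted to that face
(`sample_optimal_face()`): the objective is fixed exactly at its optimum,
flux-variability analysis pins the coordinates the face determines, and the
walk moves in the null space of the remaining equality constraints, starting
from the mean of the flux-variability vertices. Uniformity of the sampler is
approximate and never load-bearing: tests rely on degenerate faces (where
the answer is exact), interval containment, and sign/monotonicity structure.

## Solving the linear programs

The package carries its own dense two-phase primal simplex
(`lp_solve()`, internal) with bounded variables and Bland's anti-cycling
rule. FBA problems here are small (10–40 reactions) but systematically
degenerate — closed cofactor pairs such as ATP/ADP and NAD/NADH make $S$
rank-deficient, and knockouts pin many variables to zero — so the solver
re-factorises the basis at every iteration and keeps artificial variables
pinned at zero to tolerate rank deficiency. Only objective values and flux
extrema are contractual; individual flux vectors at an optimum are one
vertex among possibly many. Mass-balance residuals of accepted solutions
are below $10^{-6}$ and bound violations below $10^{-9}$; "fixing a flux"
(e.g. biomass at its maximum) always means a two-sided bound
$v^\*(1 \pm 10^{-9})$.

## Oxygen calibration, hypoxia, dose-response

A yield-maximising model given unlimited oxygen stops fermenting, so
normoxic simulations cap oxygen uptake: `calibrate_oxygen()` finds the
largest uptake bound at which the minimal lactate secretion is still
positive (coarse scan for the forcing region, then bisection to a relative
resolution of $10^{-3}$). Hypoxia scales that bound, by default to 50% of
its normoxic value. `dose_response()` emulates inhibitor titrations: the
capacity bound of a target reaction is lowered linearly from its full value
to zero over (by default) 21 levels, and biomass, ECAR and OCR are
recomputed at each level by re-solving and re-sampling.

## Expression-tailored cell-line models

Cell-line-specific models are built from one generic scaffold by mapping
enzyme expression to maximal flux capacities (`tailor_cohort()`):
per reaction, expression is aggregated over the gene–protein–reaction rule
(isoenzymes/OR sum, complex members/AND take the minimum), min–max
normalised across the cohort, and mapped linearly onto
$[\varepsilon, 1] \cdot \text{base bound}$ for the designated
growth-associated reaction subset. The floor $\varepsilon$ (default 0.1)
keeps every reaction minimally open; the default base bound is 12 in model
flux units. The published method this emulates sets expression-derived
maximal capacities on a growth-associated subset but its exact bound map is
not public, so the linear min–max map is this package's explicit,
documented stand-in; whether normalisation acts per gene or per reaction,
and the floor value, are declared choices, not inferences. A target
reaction with zero cross-line variance is left unpenalised.

## The fixtures and what they do (and do not) show

`build_warburg_mini()` is a 10-reaction network solved completely by hand:
glucose uptake capped at 10, oxygen at 2.5, lumped glycolysis
(2 ATP + 2 NADH per glucose), respiration (2 ATP per NADH at 0.5 O2), an
isoenzyme-backed lactate dehydrogenase, and a biomass reaction costing
6 ATP. Its maximal growth is 5 with a forced lactate secretion of 15; with
unlimited oxygen growth reaches 110/7 and the forcing vanishes; knocking
out lactate dehydrogenase leaves 55/26 ≈ 42% of growth and an AFR at
7/52 ≈ 13.5% of wild type. Every one of these numbers is re-derived in the
test suite by an independent vertex-enumeration oracle. The maximal-biomass
face is a single point, which makes the sampled metrics exact.

`build_toy_core()` is the desk-scale stand-in for a genome-scale model:
25 reactions spanning glycolysis (with a small low-NADH bypass and a
pentose-like shunt), capacity-capped respiration, an uncapped
non-phosphorylating NADH oxidase, capped oxidative glutamine ATP, an
oxygen-costly glutamine-to-pyruvate route, and serine/methionine branches
feeding a biomass reaction that costs 8 ATP. The design places the
wild-type optimum in the regime where growth is ATP-limited with glycolysis
saturated and respiration at capacity, so the NADH excess must leave as
lactate; the NADH oxidase makes unlimited oxygen dissolve the forcing and
gives the optimal face a genuine oxygen range. Under glycolytic inhibition
the oxygen-costly glutamine routes take over ATP and pyruvate supply while
the serine/methionine uptakes keep biomass alive, so sampled ECAR falls and
OCR rises towards the oxygen cap. The shipped oxygen bound is 42% of the
calibrated zero-forcing threshold — a deliberate normoxic margin that makes
the forced-lactate signal substantial (about 6.4 flux units) rather than
marginal. The builder self-checks all of this at construction time and
refuses to return a network that violates any requirement.

Two caveats the fixtures make explicit. First, sampled means on a polytope
are Monte-Carlo estimates with a small systematic skew; monotonicity of
dose-response curves is therefore asserted within a few percent of each
curve's dynamic range (ECAR is exactly monotone here; OCR shows deviations
of about 1% of its level). Second, passing tests on these networks show the
*method* behaves as designed — they say nothing about any real cell line,
whose genome-scale models, measured exchange rates and noise structure are
far richer than anything a 25-reaction network emulates.

## Synthetic cohorts and planted structure

`generate_cohort()` draws, per line, a latent glycolytic character
$w \sim U(0,1)$ and generates expression as
$100 \cdot \text{base}(w) \cdot e^{\sigma Z}$ with $\sigma = 0.15$:
glycolytic genes scale with $1 + w$, respiratory genes with
$0.4 + 0.4(1-w)$, branch genes with $0.8 + 0.2w$. Phenotypes follow the
planted relations growth $= 1 - 0.5w + \mathcal N(0, 0.05)$ and migration
$= 0.2 + w + \mathcal N(0, 0.05)$; 30% of drug-response profiles equal
$w + \mathcal N(0, 0.15)$ and the rest are standard-normal noise. These
defaults were chosen as a realistic signal-to-noise regime: the planted
drug associations run at $\rho \approx 0.8$ against $w$, which after
attenuation through the sampled AFR leaves a decisively detectable
$\rho \approx 0.7$ at 20 lines and are the conditions all cohort-level tests run
under. The "normal" mode emulates untransformed proliferating cells:
$w \approx 0.5$ with low variance, a glycolysis-low / respiration-high
signature whose tailored models retain enough oxidative and bypass capacity
that no oxygen bound forces them to ferment.

For the cancer/normal contrast (`forced_lactate_contrast()`), both cohorts
are tailored **jointly** — one normalisation context, as for a single
expression platform — each cancer line's oxygen bound is calibrated
per line, and every normal line is evaluated at the median of the cancer
bounds, i.e. under the panel's shared normoxic medium. Calibrating the
normal lines themselves would be circular: the calibration *constructs* a
forcing oxygen level whenever one exists, so the meaningful question is
whether the normal models ferment under the oxygen economy that forces the
cancer models.

The per-line metric pipeline (`cohort_warburg()`) simulates every line
under the panel's shared normoxic oxygen bound by default — per-line
calibration would equalise precisely the bioenergetic differences the AFR
is meant to expose, since it finds each line's own forcing point. A
per-line mode (90% of each line's calibrated threshold) is available for
analyses that need each model individually forced.

## The knockout screen

`run_screen()` constrains each candidate reaction's flux to zero in every
cell-line model and applies three filters in order: (1) the knockout must
abolish forced lactate secretion (minimal lactate at maximal growth below
$10^{-6}$) in all lines; (2) it must retain strictly more than 10% of
wild-type growth (in all lines by default; a mean-based mode is available);
(3) the sampled AFR must fall strictly below 60% of its wild-type level
(mean fraction across lines by default, per-line unanimity optional). Ties
at either threshold fail — the thresholds are printed as strict
inequalities and are implemented that way. An optional normal cohort adds a
fourth requirement: the knockout must spare normal growth at the same 10%
threshold. Exchange reactions are screened by default and the biomass
export itself is never tested. `map_targets_to_genes()` then lifts
surviving reactions to genes, flagging whether a single-gene knockdown
suffices (AND position) or an isoenzyme backup survives it (OR sibling).

On toy-core the screen's behaviour is fully characterised: seven knockouts
abolish lactate while sparing growth (the glycolytic chain, lactate
dehydrogenase, and the serine/methionine branches), and the AFR filter
keeps exactly the five glycolytic ones. The branch knockouts *raise* the
sampled AFR in this network — growth falls onto a smaller, relatively more
glycolytic budget — which is a genuine property of the toy architecture,
and the fixture records both sets (`reroutable_branch`, `planted_targets`)
so tests can assert each containment.

## Statistics

All correlations are Spearman rank correlations with permutation p-values:
full enumeration of the $n!$ permutations for $n \le 9$, otherwise seeded
Monte-Carlo with $10^5$ draws and the add-one estimator (an exact
enumeration at cohort size is computationally meaningless, so the
switchover is a declared policy). Ties take mid-ranks throughout. The
partial Spearman correlation residualises the ranks of both variables on
the ranks of the covariate and permutes the ranks of the first variable.
Multiple testing uses Benjamini–Hochberg at $\alpha = 0.05$ with the
boundary counted as significant. The drug-response analysis
(`response_association()`) correlates a per-line measure (typically the
AFR) with every compound profile, reports the FDR-significant fraction and
its sign split, and derives an empirical cohort-level p-value by shuffling
the response matrix 1000 times and recomputing that fraction each time;
a Wilcoxon-based per-compound statistic (response split at the measure's
median) is available as the shuffle statistic via `statistic = "wilcoxon"`.

## Numerical choices and limitations

* LP tolerances: $10^{-9}$ optimality/feasibility in the simplex,
  $10^{-6}$ for "lactate abolished", $10^{-9}$ relative for flux fixing.
  No published tolerance exists for any of these; they are declared here.
* Sampler settings: burn-in 1000 steps, thinning 100, 1000 samples —
  the sampling depth used for every reported metric. Degenerate faces are
  detected from flux-variability ranges below $10^{-9}$ and short-circuit
  to exact answers.
* Problem sizes in the shipped tests: 20-line cancer cohorts, 10+10-line
  contrast cohorts, 100-compound response panels with 30 planted, 21
  dose-response levels at 500 samples per level. These sizes were chosen as
  the smallest at which the planted structure is decisively recoverable.
* Thermodynamic/loopless constraints and solvent-capacity constraints are
  out of scope, as is any reconstruction of real cell-line models from
  measured expression; the machinery accepts real SBML models and
  expression tables, but nothing here validates predictions against
  laboratory measurements.
* The AFR weighting by ATP stoichiometric coefficients matters only for
  lumped reactions; with unit ATP coefficients it coincides with the plain
  mean-flux ratio.
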