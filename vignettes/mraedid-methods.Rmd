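---
title: "Methods: SBM-DDF meta-frontier efficiency and staggered DID"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SBM-DDF meta-frontier efficiency and staggered DID}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

A province-year is treated as a decision-making unit that converts
four inputs — health expenditure (HE, currency), health personnel
(HP, persons), medical-institution beds (MIB) and medical
institutions (MI, counts) — into three desirable outputs — outpatient
visits (OV), discharge rate (DR, percent in (0, 100]) and bed
utilization (BU, percent) — while also generating two undesirable
outputs, observation-room mortality (MOR) and emergency mortality
(EM).  All quantities must be strictly positive: the score below
divides slacks by observed values.

The slacks-based-measure directional distance function (SBM-DDF) of
Fukuyama and Weber scores a unit $(x_0, y_0, b_0)$ against a
reference technology $(X, Y, B)$ spanned by $J$ reference units:

$$\max_{\lambda, s \ge 0}\;
\frac12\left[\frac1N\sum_{n}\frac{s^x_n}{g^x_n}
+ \frac{1}{M+I}\left(\sum_m \frac{s^y_m}{g^y_m}
+ \sum_i \frac{s^b_i}{g^b_i}\right)\right]$$

subject to $X\lambda + s^x = x_0$, $Y\lambda - s^y = y_0$,
$B\lambda + s^b = b_0$, $\lambda \ge 0$, and $\sum_j \lambda_j = 1$
under variable returns to scale.  Desirable outputs may expand while
undesirable outputs and inputs contract, each by its own amount —
the point of combining slacks with a directional formulation.
Efficiency is $1 -$ the optimum; with the direction $g$ set to the
unit's own observed quantities the optimum lies in $[0, 1]$ up to
solver round-off and the score is unit-free.

Three modelling choices here were genuinely open and are exposed as
configuration:

- **Returns to scale.** Constant returns by default, consistent with
  the free intensity weights of the cited formulation; `rts = "VRS"`
  adds the convexity constraint.  Under VRS the program can be
  infeasible for units whose undesirable outputs lie below every
  reference mix; this is raised as a typed error rather than patched.
- **Direction vector.** Own observed quantities by default, the
  standard unit-free choice; any strictly positive custom direction
  is accepted.
- **Objective weights.** The $1/(2N)$ and $1/(2(M+I))$ weights above
  are the defaults and can be overridden per slack block.

### Group frontiers, meta-frontier, TGR

Group frontiers score each unit only against its own region's
observations; the meta-frontier pools all provinces.  Since the meta
reference set contains every group set, meta efficiency can never
exceed group efficiency, and the technology gap ratio
$TGR = e_{meta}/e_{group} \in (0, 1]$ measures how far a region's
best practice sits from global best practice.  Reference observations
are pooled over all years by default (one intertemporal frontier per
scope): published provincial tables report one score per province
averaged over time, which is meaningful when the benchmark is stable;
`pooling = "per_year"` builds annual frontiers instead.  Summary
tables time-average scores per province, then take unweighted means
over provinces per region; on a balanced panel the two averaging
orders coincide, and rounding (half away from zero, 3 decimals)
happens only at the reporting layer.

### The LP solver

No linear-programming package is part of the package's dependency
set; the LPs here are small and dense (at most a few hundred
intensity variables, about ten rows), so the package carries a
two-phase primal simplex written for that shape.  Rows are normalised
by the evaluated unit's own quantities so the tableau is well scaled
regardless of measurement units.  Numerical choices: pivot and
feasibility tolerance $10^{-9}$; Dantzig pricing with a switch to
Bland's rule (which cannot cycle) after half the iteration cap;
phase-one artificials are pivoted out or their columns neutralised
before phase two.  The solver is validated in the test suite against
exhaustive vertex enumeration — every basic solution of the small
instances is enumerated independently — and efficiency clipping into
$[0,1]$ is bounded by the tests at $10^{-6}$.

## The policy evaluation model

The benchmark regression is the two-way fixed-effects DID
$$MRAE_{it} = \alpha_0 + \alpha_1\, du{\cdot}dt_{it} + \beta X_{it}
+ \mu_i + v_t + \varepsilon_{it}$$
with $du{\cdot}dt$ switching on in a pilot province's adoption
calendar year (annual data cannot resolve adoption months; the
January and May adoption dates of the two real batches both fall in
their calendar year, and this convention is what makes the treated
group contribute all 13 years, $11 \times 13 = 143$ observations).
Estimation absorbs the fixed effects by iterated two-way demeaning,
asserted in tests to equal dummy-variable least squares to $10^{-8}$.
Standard errors are conventional by default — mirroring printed
tables that do not name a clustering scheme — with cluster-by-province
(CR1, $G-1$ degrees of freedom) available; p-values use the t
distribution with residual degrees of freedom after absorption.

**Event study.**  In event time $e$ = year − adoption year, lead bins
cover $e = -2 \dots -(L+1)$ (deepest bin pooled) and lag bins
$e = 0 \dots L-1$ (last bin pooled), with $e = -1$ omitted; $L = 6$
by default, giving the six leads and six lags of the benchmark
design, every bin populated by the 2009–2021 window with 2015/2016
cohorts.  Shorter panels get the widest window they support.
Insignificant leads support parallel trends (a joint F test is
reported); the lag path traces dynamics.

**Placebo.**  The permutation test redraws *which* provinces are
treated, holding the two batch years and batch sizes fixed, and
refits the benchmark regression each time.  Timing permutation is
deliberately out of scope.  The empirical p is the share of
permutations whose $|\hat\alpha_1|$ reaches the benchmark's.

**Subgroups and VIF.**  Heterogeneity splits are by region and by
medians of time-averaged province values (ties assigned to the low
group); a subgroup without both treated and control provinces is
inestimable and raises a typed error.  $VIF_j = 1/(1-R_j^2)$ with the
conventional screening threshold of 10.

## The synthetic data generator

The generator declares — rather than estimates — a data-generating
process with the study's structure: 30 provinces × 13 years,
East/Central/West sizes 11/8/11, and 4 + 7 provinces adopting in
2015/2016 with the regional composition of the real pilot batches.

- **Inputs.** Log inputs follow province-level AR(1) processes
  (persistence 0.85) around heterogeneous unit means with
  deterministic growth, fastest for expenditure.
- **Frontier.** Desirable volume output is Cobb-Douglas in the inputs
  (exponents 0.25/0.35/0.25/0.15, constant returns), scaled by a
  regional technology factor `group_tech_gap` (defaults 1/0.8/0.92),
  which is what induces TGR below 1 for the disadvantaged regions.
  Percent outputs sit at high base levels scaled weakly by the
  technology factor.
- **Inefficiency.** $u_{it} = u_i + w_{it}$ with half-normal
  persistent and transient parts in a 3:1 split of
  `inefficiency_scale` (default 0.2).  The split reflects that
  provincial inefficiency is mostly structural — published provincial
  tables show stable rankings with several provinces at 1.000
  throughout — and the overall scale puts mean true efficiency
  $E[e^{-u}] \approx 0.86$.  True efficiency is $e^{-u_{it}}$ plus an
  additive gain `delta` (default 0.03) from each treated province's
  adoption year onward; realised outputs are frontier × efficiency ×
  log-normal noise (`noise_sd`, default 0.01), and undesirable
  outputs rise with activity and with $e^{+u}$.
- **Controls.** Drawn with unit heterogeneity, trends and a mild
  treated/control shift; by default they do *not* enter efficiency
  (`control_effects = 0`), keeping the estimand clean, but a
  coefficient vector can link them.

The hidden truth (treated set, true efficiency, frontier parameters)
travels with the panel so parameter-recovery tests are
self-documenting.

**What passing tests do and do not show.**  The generator emulates
the statistical structure the methods assume — positivity, a common
technology within groups, parallel trends by construction,
homogeneous additive effects.  It does not emulate real yearbook
data: no deflation or measurement artefacts, no anticipation, no
effect heterogeneity, no spatial spillovers, and controls that are
exogenous by construction.  Recovery of `delta` here validates the
estimator chain, not the substantive claim on any real panel.

## Known limitations and measured properties

- **Frontier censoring.**  Provinces already at score 1 cannot show
  an efficiency gain, so the DEA-scored policy effect is mildly
  attenuated relative to the truth (measured at roughly 0.15–0.25 of
  the Monte-Carlo SD of the estimate under the default DGP).  The
  test suite therefore checks the true-efficiency route for exact
  unbiasedness and bounds the DEA route's total deviation and
  censoring loss by a third of the effect size.
- **Intensive outputs under CRS.**  Percent-scale outputs (DR, BU) do
  not scale with inputs, which under constant returns lets small
  reference units be replicated; with the generator's concave
  undesirable outputs this is contained, but it is a structural
  tension of ratio outputs in CRS technologies worth knowing about.
- **Regional TGR averages** are reported as unweighted means of
  province TGRs; published tables computed from unrounded scores need
  not reproduce exactly from rounded province rows, so only province
  arithmetic is asserted.
- **Monetary inputs** are carried as given (no deflation), and
  missing values are rejected rather than imputed — the pipeline
  demands a balanced panel.

## Problem sizes used by the test suite

Simulation tests pick sizes that keep the whole suite under a couple
of minutes while preserving the regime of the full design: estimator
recovery and event-study shape run 200–500 replications at the full
30 × 13 dimensions on the true-efficiency outcome (no LPs needed);
DEA-routed closure runs 150 replications at 16 provinces × 8 years,
chosen to keep the share of frontier units near the default
configuration's; frontier monotonicity checks 50 random 8 × 3 panels;
the LP-versus-enumeration oracle uses instances of 3–6 units, where
exhaustive vertex enumeration is exact.
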