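# mraedid

Province-level health systems turn inputs (expenditure, personnel,
beds, institutions) into services (outpatient visits, discharges, bed
use) while also producing outcomes everyone wants less of (mortality
in observation rooms and emergency departments).  **mraedid** measures
how efficiently each province-year performs that transformation and
then asks whether a staggered reform — pilot provinces adopting a
policy in two batches — actually moved the needle.  It is written for
health-economics and policy-evaluation researchers who want the whole
chain, from efficiency scoring to causal inference, reproducible in
one package.

## What it computes

**Stage 1 — efficiency.**  Each province-year (a DMU) is scored with
the slacks-based-measure directional distance function (SBM-DDF) of
Fukuyama and Weber.  With inputs *x₀*, desirable outputs *y₀*,
undesirable outputs *b₀*, direction *g* (by default the unit's own
observed quantities) and reference technology (X, Y, B), the program
is

```
max  ½ [ (1/N) Σₙ sˣₙ/gˣₙ  +  1/(M+I) ( Σₘ sʸₘ/gʸₘ + Σᵢ sᵇᵢ/gᵇᵢ ) ]
s.t. Xλ + sˣ = x₀ ,  Yλ − sʸ = y₀ ,  Bλ + sᵇ = b₀ ,  λ ≥ 0
     (Σλ = 1 under VRS)
```

so desirable and undesirable outputs may adjust by different amounts.
Efficiency is 1 minus the optimum.  Scoring against a regional
*group frontier* and the pooled *meta-frontier* yields the technology
gap ratio `TGR = e_meta / e_group ≤ 1`, the distance of a region's
best practice from global best practice.  The LPs are solved by a
dense two-phase simplex written for exactly this problem shape and
validated against exhaustive vertex enumeration.

**Stage 2 — policy evaluation.**  The efficiency outcome feeds a
multi-period two-way fixed-effects DID,

```
MRAEᵢₜ = α₀ + α₁ du·dtᵢₜ + β Xᵢₜ + μᵢ + vₜ + εᵢₜ
```

with `du·dt` the staggered adoption indicator, plus an event-study
version with six lead and six lag bins in event time (omitted
category: the year before adoption), a permutation placebo test that
redraws which provinces are treated (holding the 4 + 7 batch sizes
fixed), heterogeneity subgroup fits (region, median efficiency,
median population) and VIF collinearity diagnostics.

A synthetic panel generator reproduces the study dimensions — 30
provinces × 2009–2021, East/Central/West of 11/8/11, batches of 4
(2015) and 7 (2016), a Cobb-Douglas frontier with regional technology
gaps, half-normal inefficiency and a known additive policy effect —
so every stage is testable end to end with known truth.

## Worked example

Aggregating the bundled published provincial mean scores (meta
frontier, 2009–2021):

```r
library(mraedid)
tab <- china_mrae_table()
regional_summary(data.frame(province = tab$province, efficiency = tab$meta),
                 setNames(tab$region, tab$province))
#>    region n_provinces  mean_raw  mean
#> 1 Central           8 0.7766250 0.777
#> 2    East          11 0.9370000 0.937
#> 3    West          11 0.8470000 0.847
#> 4 Overall          30 0.8612333 0.861
```

East China leads (0.937) and the overall mean efficiency is 0.861:
on average, provinces could reach the same outputs with about 14%
less resource use.  Running the whole pipeline on a synthetic panel
with a true policy effect of +0.03:

```r
b <- run_pipeline(list(synthetic = TRUE, seed = 1, n_perm = 200, quiet = TRUE))
tail(b$table2, 4)
#>    province  region  meta group   tgr
#> 31  Average    East 0.919 0.925 0.993
#> 32  Average Central 0.774 0.929 0.832
#> 33  Average    West 0.853 0.877 0.974
#> 34  Average Overall 0.856 0.909 0.943
b$did
#> Two-way FE DID: mrae ~ du_dt + 5 controls
#>   alpha1 = 0.0468 (SE 0.0088, t = 5.35, p = 1.602e-07)
#>   within R^2 = 0.082, n = 390
```

The Central region's configured technology disadvantage shows up as
the lowest TGR (0.832), and the DID stage estimates the policy effect
at 0.047 ± 0.009 against a truth of 0.03 (one draw; the estimator is
unbiased across seeds).  The event-study leads are all insignificant
(parallel trends hold by construction) while late lags are positive
and significant, and the placebo distribution puts the benchmark
coefficient in its extreme tail:

```r
cat("placebo empirical p =", b$placebo$empirical_p, "\n")
#> placebo empirical p = 0
```

## Package layout

- `R/lp.R` — dense two-phase simplex (the LP primitive)
- `R/panel.R` — panel schema, CSV I/O, validation, treatment indicators
- `R/sbm_ddf.R` — SBM-DDF program and batch scorer
- `R/metafrontier.R` — group/meta frontiers, TGR, regional summaries
- `R/did.R` — TWFE DID, event study, placebo, subgroups, VIF
- `R/synthetic.R` — synthetic panel generator with known truth
- `R/pipeline.R` — one-call pipeline and report rendering
- `vignettes/mraedid-methods.Rmd` — models, assumptions, design choices
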