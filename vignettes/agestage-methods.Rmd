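---
title: "Methods: two-sex life tables, bootstrap inference, and probit bioassays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sex life tables, bootstrap inference, and probit bioassays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agestage)
```

This vignette is the package's account of the statistical machinery it
implements, the conventions it fixes where the field's formulas leave
room, and what its synthetic-data tests do and do not demonstrate.

## The age-stage, two-sex life table

A cohort study follows `n01` eggs, one record per individual, with a
daily census: stage-entry ages, death age, sex at adult emergence, and
daily egg counts for females. The package fixes these conventions:

* **Ages are integer days; day 0 is the first day of the egg stage.**
  "At age x" means alive on day x, so an individual dying on day `d`
  has a lifespan of `d + 1` days.
* **Occupancy on a transition day belongs to the new stage.** A daily
  census cannot observe the moment of molting; attributing the
  transition day to the entered stage makes entry ages and durations
  self-consistent (durations are occupancy days and sum exactly to the
  lifespan). Because two molts can fall between consecutive
  observations, consecutive equal-looking records are permitted in the
  format (entry ages must only be strictly increasing), and the
  empirical daily transition matrix allows stage-skipping moves.
* **Adults are two stages.** Sex is revealed at emergence, so the adult
  is split into a female-adult and a male-adult stage (8 census stages
  by default: egg, L1–L4, pupa, female, male). Age-stage fecundity then
  lives in a single column of the fecundity matrix, as two-sex theory
  indexes it.
* **No censoring.** Every record ends in death, so `n01` equals the
  number of records and the survival denominators need no correction.
  Undetermined sex (`u`) is only valid for preadult deaths.

From the census counts `n_xj`, `lifetable()` computes
`s_xj = n_xj / n01`, `l_x = rowSums(s_xj)`,
`f_xj` (eggs per surviving female adult at age x),
`m_x = sum_j(s_xj f_xj) / sum_j(s_xj)`, and `lxmx = l_x * m_x`. At ages
where `l_x = 0` the defining ratio of `m_x` is 0/0; the package defines
`m_x = 0` there, which is harmless because such ages contribute nothing
to any downstream sum.

### Population parameters

`R0 = sum(lxmx)` is the net reproductive rate. The intrinsic rate of
increase `r` solves the Euler–Lotka equation

```
sum_x exp(-r (x + 1)) l_x m_x = 1,
```

with age indexed from 0 (the `x + 1` exponent is the convention under
which a cohort reproducing entirely on day x at rate R0 gives
`r = log(R0) / (x + 1)`). The left side is strictly decreasing in `r`,
so the root is unique; `solve_intrinsic_rate()` brackets it on
`[-2, 2]` per day (expanding if needed — insect cohorts never approach
that), bisects to width 1e-12, and polishes with Newton steps to a
residual below 1e-10. `lambda = exp(r)` and `T = log(R0)/r` are then
identities by construction, as is the two-sex identity
`R0 = mean fecundity per female × N_f / n01` (both sides are the total
egg count divided by `n01`).

Because the published vocabulary uses "female adult ratio" and
"male-to-female ratio" without fixing denominators, the package emits
both: `female_ratio = N_f / n01` and `male_female_ratio = N_m / N_f`.

### Life expectancy and reproductive value

Both are driven by the empirical daily transition fractions: among the
individuals observed in (age x, stage j), the fraction found the next
day in each stage, or dead. Markov-propagating these fractions forward
from an origin cell gives the conditional survival `s'`, equal to 1 at
the origin; from (0, egg) the propagation reproduces the marginal
`s_xj` exactly, because the empirical fractions are those of the same
individuals.

* `e_xj` is the double sum of `s'` over later ages and stages —
  equivalently (and as implemented) the backward recursion
  `e(x,j) = 1 + sum_y P((x,j) -> (x+1,y)) e(x+1,y)`. The current day
  counts, so `e >= 1` on occupied cells and `e(0, egg)` equals the mean
  lifespan of the cohort exactly.
* `v_xj` discounts future reproduction at rate `r`:
  `v(x,j) = exp(r(x+1)) * sum_{i>=x} exp(-r(i+1)) sum_y s'_iy f_iy`,
  with `s'` conditional on the origin. One often sees this formula
  printed with an extra `1/s_xj` factor; that version applies when `s'`
  is initialized at the marginal `s_xj` rather than at 1, and the two
  are algebraically identical. The conditional form is implemented
  because it makes the defining invariant transparent: at (0, egg) the
  inner sum telescopes to the Euler–Lotka left-hand side, which is 1 at
  the solved `r`, so `v(0, egg) = lambda`.

Cells never occupied by any individual have no empirical basis and are
reported as `NA`, not 0.

## Bootstrap inference

The resampling unit is the initial individual (egg): each replicate
draws `n01` individuals with replacement and recomputes every parameter
through the same code path as the full fit (`lt_stats()` serves both;
the suite spot-checks replicate equality against a full `lifetable()`
on the materialized resample). The default `B = 2000` is desk-scale;
studies typically publish `B = 100000`, which the same call supports.

Replicates with no reproducing female have `R0 = 0` and no Euler–Lotka
root; they contribute 0 to `R0` and `GRR` but are excluded from the
summaries of `r`, `lambda` and `T`, with the exclusion count recorded.
The reported SE is the standard deviation of the replicates.

The paired bootstrap test pairs replicates of two strains by index,
takes `d_k = a_k - b_k`, and reports the mean difference, the
percentile interval, and `p = 2 min(frac(d <= 0), frac(d >= 0))`
clamped at 1. The exact p-value rule of the legacy two-sex life-table
software is not published; this percentile construction is the
documented choice here, and a simulation in the suite confirms it holds
its nominal type-I error (rejection rate within [0.03, 0.07] at
alpha = 0.05 over 200 null pairs at `B = 1000`).

Two numerical caveats worth knowing: (i) bootstrap means converge to
the point estimates only for statistics linear in the individuals (R0,
mean fecundity, duration means); for `r`, `lambda`, `T` the bootstrap
mean carries the usual O(1/n01) resampling bias, which at `n01 = 100`
is visible against `2 SE / sqrt(B)` — that is a property of the
bootstrap, not an error. (ii) `GRR = sum(m_x)` is dominated by late
ages where few females remain alive and is therefore by far the noisiest
parameter.

Correlations with the selection generation are Pearson correlations,
reported both over the pooled (generation, replicate) pairs and over
the generation means; pooling is what published heatmaps of bootstrap
output do, but the pooled `r` shrinks as within-generation bootstrap
spread grows, so both views are emitted with explicit labels.

## Probit dose-mortality analysis

`probit_fit()` is a binomial GLM with probit link on **log10**
concentration (the convention under which published slope/LC50/LC25
triples are internally consistent, and the package's regression test
verifies this on eight published strain rows; one further published row
is internally inconsistent by ~110% — evidently a typographical error —
and is excluded). The fit refuses degenerate data: fewer than two
distinct positive concentrations, all-dead/all-alive responses, or
complete separation of dose groups.

Goodness of fit is the Pearson chi-square over dose groups with
`df = groups - 2`. Following Finney's convention (the one classic
probit software applies), when `chi2 > df` the heterogeneity factor
`h = chi2/df` inflates the variance-covariance matrix and the
confidence deviate switches from normal to t on `df` degrees of
freedom. `lc()` computes `LC_p = 10^((qnorm(p/100) - a)/b)` with limits
by Fieller's theorem on the log10 scale (exact for a ratio of normal
estimates; unbounded, with a warning, when `g >= 1`), plus a
delta-method option for comparison. Abbott's correction for control
mortality is available but **off by default**, since bioassay reports
that do not mention it should be reproduced without it.

## The synthetic generators

`cohort_spec()` emulates a laboratory cohort: per-stage durations
`1 + Poisson(mu)` (at least one census day per stage), independent
daily survival per stage, sexing at emergence, adult longevity
`1 + Poisson(mu_sex)`, APOP `1 + Poisson(mu_apop)`, and daily egg
counts Poisson-distributed around a triangular schedule of adult age.
The defaults are calibrated once to a published control colony of the
tomato leafminer: stage-duration means ~4.9/3.0/2.8/2.7/2.8/7.1 days,
~102 expected eggs per female (triangle peak 13.5 eggs/day at adult day
6, last laying day 18, net of APOP gating and adult mortality), 1:1 sex
ratio, APOP ~2.1 days, adult longevity ~18 days. The control colony's
preadult survival is not published; daily survival 0.99 per stage
(~79% egg-to-adult) is a typical laboratory figure and is the one
free choice. A treatment knob (`fecundity_mult`, `preadult_delay`)
produces selected-strain-like cohorts for comparison tests.

`expected_parameters()` computes the generator's ground truth without
simulation: per-stage defective duration pmfs `P(D = d) p^d` are
convolved into the age-at-emergence distribution; the laying schedule,
APOP gating and adult survival give expected eggs per adult day; their
convolution is the expected `lxmx` schedule, from which R0, r, lambda
and T follow through the same Euler–Lotka solver. Recovery tests
compare simulated cohorts against these values (20 cohorts of
`n01 = 500` for the population parameters; probit interval coverage
over 200 bioassays of 30 larvae/dose — sizes chosen to make the checks
sharp at interactive runtimes).

What the generator does **not** emulate — and hence what passing
recovery tests cannot show about real data: between-individual
heterogeneity beyond stage membership (frailty), density dependence,
transgenerational and maternal effects, non-Poisson overdispersion of
daily fecundity, mortality clustered on molting days, or any genetic
structure of resistance. The generators validate the pipeline's
arithmetic, not the biology.

## Multi-strain reporting

`run_strain_comparison()` derives one seed per strain from the master
seed (`seed + strain index - 1`), bootstraps each cohort, and builds
the comparison table: mean ± SE per parameter, pairwise paired tests,
compact significance letters, relative fitness against the designated
control, and generation correlations. The letter display uses the
insert-and-absorb algorithm at `alpha = 0.05`: starting from one group
holding all strains, each significant pair splits every group
containing both members and subset groups are absorbed, so two strains
share a letter exactly when no significant difference separates them.
All CSV outputs carry the seed and a configuration hash in comment
headers, and rerunning a configuration reproduces them byte for byte
(plots excepted).

## Known limitations

* No censoring or escapes: records must end in observed death.
* No temperature/degree-day scaling and no forward population
  projection (the life table summarizes the cohort; it does not project
  it).
* Percentile bootstrap intervals only — no BCa or studentized variants —
  and no multiplicity correction across parameters, matching standard
  practice in this literature.
* The probit module fits the fixed-endpoint mortality model only; no
  time-to-death analysis and no logit/complementary-log-log links as
  primary output.
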