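---
title: "Methods: a travelling-Gaussian model of the relative age effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a travelling-Gaussian model of the relative age effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttgrae)
```

## The model and its assumptions

Within an age-banded cohort, a quality $Q$ at birthtime $t \in [0,1]$
($t = 0$ = oldest possible member, $t = 1$ = youngest) is assumed
Gaussian with unit within-age variance and a mean that travels linearly
with age:

$$Q(t) \sim N(A\,t,\; 1).$$

Selection retains everyone with $Q \ge$ a fixed threshold $C$ standard
deviations above the oldest children's mean, so the selection
probability at birthtime $t$ is the upper tail

$$p(t) = 1 - \Phi(C + A\,t),$$

and the upper-tail probit of an observed proportion is *linear* in
birthtime: $z(t) = \Phi^{-1}(1 - p(t)) = C + A\,t$. Estimating $A$ (how
much one year of age is worth, in within-age standard deviations) and
$C$ (how severe the selection is) is therefore a linear regression
problem on probit-transformed grouped proportions.

Three assumptions matter and all are checkable:

* **Gaussian quality with unit variance at every birthtime.** The model
  is scale-free — $A$ is expressed in within-age standard deviations —
  so heteroscedasticity across the year is the real assumption. No
  heteroscedastic variant is offered.
* **Linear travel.** Tested by `compare_models(points, "quadratic")`:
  a significant quadratic term indicates non-constant advancement (or a
  seasonal birth process, which produces a smooth wave rather than the
  saw-tooth discontinuity of a genuine cohort effect).
* **A common slope across severity levels.** When one population is
  rated at several cumulative severities, each level gives its own
  probit line; `compare_models(points, "interaction")` tests whether
  the slopes differ.

## From tables to probit points

`rating_table` holds counts per birth interval × ordinal level.
`cumulate` forms "at or above level $k$" counts; dividing by interval
row totals gives upper-tail proportions, which `to_probit_points`
probit-transforms. The "at or above lowest" column is everyone
($p = 1$) and is never transformed; with $K$ ordinal levels a 12-month
table yields $12 \times (K-1)$ regression points. For selection data
(`selection_points`), the denominator is the interval's population
pool, and fractional selected counts (shares × total) are used as-is.

**Degenerate proportions.** A cell with $p$ of exactly 0 or 1 has no
finite probit. The default policy excludes the point and records it in
the `excluded` attribute; a continuity correction
$p^\* = (x + 0.5)/(n + 1)$ is available via `zero_cell = "correct"`.
Exclusion is the default because silently fabricating a $\pm\infty$
z-score — or an arbitrarily corrected one — can dominate a small
regression; the packaged datasets contain no such cells.

**Reverse-scored items.** Scales phrased so that *more* means *less* of
the quality (e.g. "is restless") are flipped with `reverse_code`, an
involution that reverses level order and count columns, keeping
positive $A$ aligned with positively valued qualities.

## Calendar conventions

Midpoint birthtimes are $(days\_before + days\_in/2)/year\_length$.
Two year-length conventions are supported because each reproduces one
of the packaged analyses exactly: the school-year monthly grid uses a
365-day year with February = 28 (November midpoint
$(30 + 31 + 15)/365 = 0.2082$), while the soccer tercile grid uses a
365.25-day year with 29 February weighted 0.25, giving tercile lengths
122 / 120.25 / 123 days and midpoints 0.1670 / 0.4986 / 0.8316. Custom
grids take explicit day lengths, so quarters, halves and what-if splits
need no new code. The default `year_length` is 365.

## The three estimators

* **Endpoint** (`endpoint_estimate`): per severity level, the z
  difference between the last and first interval. Midpoints of the
  extreme intervals do not span the full year, so the average
  difference is rescaled; for mid-month points the natural ratio is
  $12/11$ (eleven months separate mid-September from mid-August). The
  default rescaling, $1/(t_{last} - t_{first})$, generalises this to
  arbitrary grids and equals $365/334.5 \approx 12/11$ on the monthly
  grid; pass `span_scale = 12/11` to match the mid-month convention
  exactly.
* **Per-level** (`per_level_regression`): OLS of z on $t_B$ within each
  level; $A$ is the unweighted mean of the slopes.
* **Stacked** (`stacked_regression`): one OLS of all z on $t_B$ plus
  level dummies, reference = least severe level present. This is the
  recommended estimator: it uses all points, yields a standard error
  and $t$ statistic for $A$, and is the base model for the nested
  F tests. With a balanced design (every level observed at the same
  birthtimes) its slope equals the mean of the per-level slopes
  exactly, which the test suite asserts to $10^{-10}$.

All fits are **unweighted** OLS through `stats::lm` (QR-based, so the
residual-orthogonality contract holds to machine precision). Weighting
by binomial information would be more efficient but is deliberately not
the default: the grouped proportions here come from large, similar
denominators, and unweighted OLS is the convention this kind of
analysis reports. By-month clustered standard errors and cumulative-link
maximum likelihood are out of scope and documented as limitations.

The F statistic for adding $q$ terms is computed from residual sums of
squares, $F = (\Delta RSS/q)/(RSS_{full}/df_{full})$ — algebraically the
incremental-$R^2$ form. When the base model already fits to machine
precision ($RSS \le 10^{-12}\,TSS$) the statistic is reported as 0
rather than a 0/0 artefact.

On the packaged speaking-and-listening table the estimators give
$A = 0.6742$ (endpoint, 12/11 rescaling), $0.6426$ (per-level average)
and $0.6426$ (stacked, $t(43) = 13.08$); the quadratic and interaction
checks give $F(1,42) = 2.32$ and $F(3,40) < 1$, so the linear
common-slope model stands. Three-point scales work identically with two
usable cumulative levels (24 points on a monthly grid; $t(21)$ and
$F(1,20)$ accounting follows automatically from the design size).

## Discrimination and wastage

Metrics are evaluated at the *extrapolated* endpoints $t = 0$ and
$t = 1$ of the fitted line — the oldest- and youngest-possible child —
not at the outermost interval midpoints, which sit well inside the
year and understate the effect (the academy terciles' 4.07 selected
ratio becomes $I_D = 8.3$ at the true extremes).

The wastage baseline is the horizontal no-RAE line at $p(0)$: in a
world without relative age effects every child would face the oldest
child's selection probability. The captured fraction is

$$\mathrm{Grey} = \frac{\int_0^1 \big(1 - \Phi(C + A t)\big)\,dt}{1 - \Phi(C)},
\qquad W = 1 - \mathrm{Grey},$$

with $\mathrm{PopEx} = 1/\mathrm{Grey}$ and
$\mathrm{PopCon} = \mathrm{Grey}$ (so $\mathrm{PopEx}\cdot\mathrm{PopCon} = 1$
identically). The integral has the closed form built from
$\int \Phi(a + bt)\,dt = [(a+bt)\Phi(a+bt) + \phi(a+bt)]/b$; a
quadrature route (`stats::integrate`, relative tolerance $10^{-10}$) is
kept as an independent cross-check and the two agree to $10^{-8}$
across the tested parameter grid. An alternative baseline (e.g. the
cohort-mean probability) is not offered: the no-RAE counterfactual is
the one with policy meaning. Conventions: $A = 0$ gives $W = 0$;
$A < 0$ raises an error directing the caller to `reverse_grid`, since
the geometry presumes selection favouring the old.

The mean birthtime of the selected,
$\bar t_B = \int_0^1 t\,p(t)\,dt / \int_0^1 p(t)\,dt$, is computed by
quadrature. It decreases both in $A$ and in $C$ (verified on a 10×10
grid in the tests), which is exactly why raw mean birthtime is an
ambiguous RAE measure and the model decomposition is worth the
trouble.

## The simulator

`simulate_counts` draws from the forward model and emits data in the
same containers the fitting pipeline consumes, so simulated and real
data are interchangeable. Binomial mode draws per-interval counts; with
several criteria it enforces the nesting of cumulative levels by
sequential conditional binomials
($X_{k+1} \mid X_k \sim \mathrm{Bin}(X_k,\, p_{k+1}/p_k)$). Individual
mode draws each child's birthtime uniformly within its interval and a
single latent quality, classifying it against the ordered criteria —
nesting holds by construction. An `expected` mode returns noiseless
expectations for exact-recovery checks. All randomness flows through
one seed; the RNG state is saved and restored so callers' streams are
untouched, and identical seeds give identical output.

What the generator emulates: binomial sampling noise at realistic pool
sizes, interval midpoint grouping, nested ordinal levels, uniform
births across the year. What it does not: seasonal birthrate
fluctuation, dependence between ratings beyond the shared latent
quality, rater effects, and the survey design of real cohort studies.
Passing recovery tests therefore demonstrate statistical correctness of
the pipeline under the model's own assumptions, not robustness to those
real-data features.

Recovery studies in the test suite use 200 replicates at academy-like
settings (pools ×10 to tame degenerate cells at $p \approx 0.005$) and
1,000 replicates at classroom-like settings (12 monthly pools of 450),
sizes at which the Monte-Carlo error on the bias is comfortably below
the asserted bounds (0.03 and 0.02) while the full suite stays fast.

## Policy what-ifs

The policy engine works on parameters, in closed form:

* **Criterion relaxation**: metrics at $C$ and $C - \Delta C$.
* **Cohort splitting** into $k$ equal sub-cohorts: advancement per
  annum is assumed unchanged (linear travel — consistent with the
  quadratic test's verdict on the packaged data), so within a
  sub-cohort spanning $1/k$ year the quality travels $A/k$. The
  criterion either stays fixed (`"fixed_c"`, the default) or is
  re-solved by monotone root-finding (tolerance $10^{-8}$) so the
  expected intake matches the unsplit cohort (`"fixed_intake"`). The
  choice matters: fixed-$C$ admits more children as travel shrinks,
  fixed-intake trades some of the fairness gain back. With uniform
  births the $k$ sub-cohorts are statistically identical, so
  per-sub-cohort metrics are also the pooled metrics.
* **Advancement rescaling**: metrics at $A \cdot f$, a stylised model
  of selecting at an older age when a year matters less; $f = 0$
  removes the effect entirely ($I_D = 1$, $W = 0$).

## Numerical and editorial choices

* $\Phi$ and $\Phi^{-1}$ are `pnorm`/`qnorm` (double-precision
  throughout); no home-grown approximations.
* Proportions of exactly 0 or 1 are rejected at the probit boundary;
  policy for data cells lives in the tabulation layer (above).
* Comparisons against published worked-example values are made to one
  unit in the last printed decimal digit. Four printed values in the
  source tables are internally inconsistent and were resolved by
  recomputation: a cumulative proportion printed as .1539 where the
  underlying counts give .1532 (its printed z-score matches .1532); a
  selection probability printed as 0.005410 where the ratio gives
  0.005407 (z agrees to 3 d.p. either way); an odds-ratio numerator
  printed as 31.85% where 30.85% reproduces the printed ratio 3.18; and
  a tercile share printed once as 0.15 where 0.14 reproduces the
  printed count 44.8.
* The stacked estimate for the speaking-and-listening table computes
  to 0.64263, matching the per-level average exactly (as it must on a
  balanced design) and the published 3-d.p. value 0.643; a 4-d.p.
  rendering of 0.6428 circulating for the same analysis is not
  reproducible from the printed table.

## Known limitations

Point estimates only: no bootstrap or delta-method intervals on $I_D$
and $W$. Plain OLS standard errors (no clustering over intervals).
No seasonal birth model — the quadratic term is the linearity check.
No multi-year dynamics (self-reinforcing selection across age groups),
and no survey weighting; pools are user-supplied judgments, and the
pool-size sensitivity analysis (`epl_academy_points(pool_total = ...)`)
is the recommended way to propagate that uncertainty.
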