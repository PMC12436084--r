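---
title: "Quantifying the efficiency loss of MAMS designs under outcome delay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the efficiency loss of MAMS designs under outcome delay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mamsdelay)
```

## The problem

A group-sequential multi-arm multi-stage (MAMS) trial compares K
experimental treatments against a shared control over J stages. At each
interim analysis every undecided arm is tested: its z statistic is compared
to an efficacy bound `e_j` (cross above: reject the arm's null and stop the
arm) and a futility bound `f_j` (fall at or below: drop the arm). With
*separate* stopping rules each arm is decided on its own; the trial ends
when all arms are decided. Early stopping is where the efficiency of a MAMS
design comes from: on average it needs fewer patients than a single-stage
multi-arm trial with the same error rates.

That accounting assumes outcomes are available at recruitment. When the
primary outcome takes `m0` months to observe and recruitment continues while
interim outcomes are awaited, participants recruited in that window —
*pipeline* participants — are randomized but cannot inform the interim. If
arms (or the whole trial) stop at that interim, the pipeline participants
have been recruited anyway. This package quantifies how much of the expected
efficiency gain is destroyed by that mechanism.

## Model and notation

Outcomes are normal, `X ~ N(mu_k, sigma_k^2)` for arm `k` (0 = control), and
the one-sided hypotheses are `H_k: tau_k = mu_k - mu_0 <= 0`. With
cumulative per-arm sizes `n_jk` through stage j, the Wald statistics have

* `E[Z_jk] = tau_k * sqrt(I_jk)`, `I_jk = (sigma_k^2/n_jk + sigma_0^2/n_j0)^-1`,
* `cov(Z_jk, Z_j'k) = sqrt(I_jk / I_j'k)` for the same arm at stages `j < j'`,
* `cov(Z_jk, Z_j'k') = sqrt(I_jk * I_j'k') * sigma_0^2 / n_max(j,j'),0` across
  arms — the dependence induced by the shared control.

A trial outcome is a pair of vectors `(omega, psi)`: the stage at which each
arm was decided and whether its null was rejected. Each arm carries one of
`2J` labelled decisions, so there are `(2J)^K` outcome paths
(`enumerate_outcomes()`). The probability of a path is a box probability of
the joint normal of the active statistics — the continuation region
`(f_j, e_j)` before the arm's exit stage and the exit side at it
(`outcome_probability()`); the dimension is `sum(omega)`, at most `J*K`.
Expected sample size is the probability-weighted realized size over all
paths: `ESS = sum n(omega) P(omega, psi)`, with `n(omega)` counting each
arm's recruitment through its stopping stage and the control through
`jmax = max(omega)`.

### Calibration

Boundaries come from one-parameter shape families (`shape_boundaries()`):
O'Brien–Fleming (`c/sqrt(r_j)`), Pocock (constant), triangular-test, and the
zero-interim-futility O'Brien–Fleming variant used throughout the default
scenarios (futility at `z = 0`, i.e. drop an arm whose one-sided p-value is
at least 0.5). `f_J = e_J` always, forcing a final decision.
`calibrate_boundaries()` finds the scalar so the familywise error rate
(probability of any false rejection under the global null, with binding
futility) equals `alpha`; because the covariance depends only on allocation
ratios and spacing, the boundary does not depend on the absolute sample
size. `calibrate_group_size()` then scales the group size so *conjunctive*
power — the probability of rejecting all K nulls when every arm carries the
target effect `delta` — reaches its target; the continuous solution is kept
internally and integer sizes are a reporting decision. The efficiency
comparator `single_stage_size()` is the K-arm single-stage design calibrated
to the same two targets with the same machinery (a Dunnett-type critical
value); using familywise-error control there keeps the comparison internally
consistent, though efficiency-loss magnitudes do depend on this choice.

For the O'Brien–Fleming and Pocock families the interim futility bounds are
not pinned down by any published value we reproduce; we use the
symmetric-magnitude convention `f_j = -e_j` (j < J), which is close to
non-binding futility, and expose the zero-futility variant and fully custom
boundaries for anything else.

## Recruitment, pipelines and the delayed ESS

Two accrual laws are built in (`recruitment_model()`), both anchored so that
cumulative recruitment reaches `n_max` at `tmax`:

* **uniform**: rate `lambda = n_max/tmax`; time to recruit `n` is `n/lambda`;
* **linear**: rate grows as `Delta * t` with
  `Delta = 2 n_max / (tmax (tmax+1))` — the extreme of the ramp-up patterns
  of multi-centre trials; time to recruit `n` is the positive root of
  `Delta t (t+1)/2 = n`.

Time is real-valued, in months. Along a path, stage-j outcomes are complete
at `t_j` (inverting the accrual curve at the path's cumulative size `n_j`)
and the analysis happens at

```
t~_j = t_j + m0                 if t~_{j-1} <= t_j
       t~_{j-1} + m0            else, while t~_{j-1} + m0 < tmax
       tmax                     otherwise.
```

The pipeline count at interim j is the accrual between
`max(t_j, t~_{j-1})` and `t~_j` on the (untruncated) accrual curve, which
reproduces the closed forms `lambda * m0` and
`Delta (m0 t_j + m0 (m0+1)/2)` in the uncapped branches. It is then capped
by the maximum further recruitment `nu_j` the arms still present could need
(`min(n~_j, n_{j-1} + nu_j - n_j)`), so total recruitment can never exceed
`n_max`; pipelines are zero at the planned final stage and once the previous
analysis clock reached `tmax`. The delay-adjusted realized size is

```
n_delay(omega) = n_jmax + max(0, max_j (n_j + n~_j) - n_jmax),
```

covering both the small-delay case (pipelines inflate the total only if the
trial stops early, by `n~_jmax`) and the large-delay case (only the largest
overshoot counts — later interims are run on already-recruited
participants). `ESS_delay` replaces `n(omega)` with `n_delay(omega)` in the
ESS sum. Two corner conventions are ours: the analysis clock is kept
nondecreasing in the corner where an uncapped analysis time already exceeds
`tmax`, and the no-more-pipelines rule triggers at `t~_{j-1} >= tmax`
rather than exact equality; both only matter in regimes where the cap has
already saturated recruitment.

## Efficiency metrics

With `n_MA` the single-stage comparator size,

* `EG = (n_MA - ESS)/n_MA` — expected efficiency gain without delay,
* `EG_delay` — the same with `ESS_delay`,
* `EL = 100 (EG - EG_delay)/EG` — the percentage of the gain destroyed by
  delay; above 100 the delayed MAMS is worse than the single-stage design,
  and `EL` is undefined (reported `NA`) when `EG = 0`.

`efficiency_report()` runs the whole chain for one design cell and a vector
of delays; `scenario_grid()` crosses stages, arms, delays, accrual laws and
the three named spacing schemes (equal; first interim earlier; first interim
later), re-calibrating boundaries and sizes per cell while holding `n_MA`
fixed within a K. At a 36-month recruitment horizon and a 12-month (one
third) delay, the equally spaced 3-stage 3-arm default design loses more
than half — in fact essentially all — of its expected gain under uniform
recruitment, which is the package's headline reproduction
(`scripts/acceptance.R`).

## Numerical choices

* Box probabilities use randomized quasi-Monte-Carlo integration
  (`mvtnorm::pmvnorm`, Genz–Bretz) with absolute tolerance `1e-6` per box
  and `1e5` points (`options(mamsdelay.maxpts=)`), under a fixed internal
  RNG state, so every probability — and therefore every calibration — is
  bit-reproducible. In 16-dimensional boxes (J = K = 4) the realized error
  is nearer `5e-5`; results whose estimated error exceeds ten times the
  tolerance are flagged, never silently repaired.
* Boundary-touch events carry probability zero, so open/closed interval
  distinctions are not modelled numerically; boxes narrower than `1e-12`
  short-circuit to zero.
* Root searches are monotone bracket searches (`uniroot` with bracket
  extension): FWER is strictly decreasing in the boundary scalar,
  conjunctive power nondecreasing in the group size.
* Path probabilities are computed once per multiset of per-arm decisions
  when arms are exchangeable (equal allocation, variance and effect) — a
  pure symmetry reduction — and calibrations are memoised per design
  signature (`mams_cache_clear()` resets).
* The non-PSD covariance check is a hard failure; it should never trigger
  for valid configurations.

## The simulator and what passing tests show

`simulate_mams()` is an independent Monte Carlo oracle: it draws per-arm
per-stage cohort outcome *sums* (exact sums of individual normal responses —
deliberately not using the analytic mean/covariance code it validates),
forms the cumulative z statistics, applies the conduct rules verbatim, and
advances the recruitment clock to attach `n(omega)` and `n_delay(omega)` to
each replicate. A single integer seed fixes the whole replicate stream. The
test suite checks integration against simulation within three Monte Carlo
standard errors at `1e5` replicates on a fixed battery of designs.

The generator emulates exactly the model's assumptions: normal outcomes with
known variance, deterministic accrual, a fixed delay identical for all
participants, and immediate analyses. Real trials violate all four in
degree — over-dispersed or non-normal endpoints, stochastic and seasonal
recruitment, variable delay, administrative analysis lag. Passing tests
therefore certify the arithmetic of the model, not the behaviour of any
particular trial; in particular, time-to-event outcomes with
exposure-dependent delay are out of scope.

## Problem sizes and known limitations

Enumeration grows as `(2J)^K` paths with integrals of dimension up to `J*K`;
designs up to J = K = 4 (4096 paths, 330 distinct integrals under
exchangeability) take seconds to a few tens of seconds per cell, which is
why the shipped scenario grid stops there. The default scenario grid in the
tests uses that full range; simulator cross-checks use `1e5` replicates.

One behaviour of the published pipeline rules deserves emphasis. For
designs with three or more stages, once interim analyses chain — the
previous analysis time `t~_{j-1}` passes the next recruitment-completion
time `t_j` — the pipeline window at the later interim is
`(t~_{j-1}, tmax]`, which *shrinks* as `m0` grows. The per-interim counts
therefore stop tracking cumulative recruitment, and `EL` as a function of
`m0` dips between roughly `tmax/3` and `2*tmax/3` before the recruitment
caps saturate everything at `n_max` (for the equally spaced 3-stage 3-arm
default under uniform accrual: EL = 0, 39.2, 107.7, 49.9, 130.9, 130.9,
130.9 at m0 = 0, 6, ..., 36). A cumulative-accrual accounting would be
monotone, but it is not what the per-interim formulas define, and no
published worked number involves a chained interim, so we keep the formulas
as defined and flag the regime. For the same reason the uniform-vs-linear
EL ordering can invert in that regime for deeper designs; with a single
interim (J = 2) both monotonicity and the ordering provably hold, and the
tests assert them there.

Known limitations, deliberate:

* recruitment never pauses at interims, and futility is binding;
* no treatment selection, sample-size re-estimation, platform-style arm
  addition, or simultaneous stopping;
* mixed (ramp-then-plateau) accrual is not modelled — uniform and linear
  bracket it from below and above in pipeline counts;
* the delay `m0` is a known constant, not a distribution.

A note on one published illustration: for the 2-stage dose-ranging
reproduction (`run_tailor()`), the per-shape maximum sample sizes implied by
the published pipeline counts sit 4–10% below what our conjunctive-power
calibration produces, consistent with a different (unpublished) power
configuration in the original; the fixed-size pipeline columns, which do not
depend on that choice, reproduce exactly, and the per-shape efficiency
columns are reported as computed by this package's own calibration.
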