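---
title: "Models and methods behind grtsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind grtsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grtsim)
```

## The problem

Multiple-period parallel group-randomized trials (GRTs) randomize intact
groups — schools, clinics, communities — to conditions and measure members
of those groups over several time periods.  Outcomes within a group are
positively correlated, and repeated measurement adds correlation over time
at the group level (and, in cohort designs, at the member level).  An
analysis that mis-models this correlation structure can reject a true null
hypothesis of no intervention effect far more often than its nominal
level.

`grtsim` provides the three pieces needed to study this by simulation:

1. a **generator** for balanced two-condition multiple-period GRT data
   under two mechanisms — repeated measures ANOVA (RM, categorical time)
   and random coefficients (RC, continuous time), each in cross-sectional
   and cohort form;
2. an **estimation engine** that fits the standard grid of linear mixed
   analytic models by unconstrained restricted maximum likelihood and
   tests the time-by-condition interaction with Kenward-Roger (KR) or
   between-within (BW) small-sample F tests; and
3. a **Monte Carlo harness** that turns rejection indicators into type I
   error estimates with Wilson intervals over a scenario grid.

## Generating mechanisms

With members $i$, periods $j$ (time values $t_j$), groups $k$ and
conditions $l$, the cohort RM mechanism is

$$Y_{ijkl} = \mu + C_l + T_j + TC_{jl}
  + G_{kl} + TG_{jkl} + M_{ikl} + \epsilon_{ijkl},$$

with independent normal random effects: group intercepts
$G_{kl}\sim N(0,\sigma^2_g)$, time-by-group intercepts
$TG_{jkl}\sim N(0,\sigma^2_{tg})$, member intercepts
$M_{ikl}\sim N(0,\sigma^2_m)$ and residual error
$\epsilon\sim N(0,\sigma^2_e)$.  With one observation per member per
occasion a time-by-member intercept cannot be separated from residual
error, so its variance is fixed at zero.  The cross-sectional form drops
the member terms and draws a fresh set of members each period.

The cohort RC mechanism replaces the categorical time structure with
group- and member-level lines,

$$Y_{ijkl} = \mu + C_l + T_{(lin)} t_j + T_{(lin)}C_l\, t_j
  + G_{kl} + T_{(lin)}G_{kl}\, t_j + M_{ikl} + T_{(lin)}M_{ikl}\, t_j
  + \epsilon_{ijkl},$$

with slope variances $\sigma^2_{t(lin)g}$ and $\sigma^2_{t(lin)m}$.
Intercepts and slopes are drawn independently by default; an
intercept-slope correlation is available (`rho_g`, `rho_m`) but is not
part of the canonical study conditions.

All fixed effects default to zero, so simulated data are generated under
the null hypothesis of no time-by-condition interaction and rejection
rates estimate type I error.  Nonzero effects turn the same machinery
into a power calculation.

## Correlation summaries and the inverse problem

The within-period ICC, between-period ICC, cluster autocorrelation and
individual autocorrelation are, under the RM definitions,

$$\mathrm{WPICC} = \frac{\sigma^2_g+\sigma^2_{tg}}
      {\sigma^2_g+\sigma^2_{tg}+\sigma^2_m+\sigma^2_{tm}+\sigma^2_e},
  \qquad
  \mathrm{BPICC} = \frac{\sigma^2_g}
      {\sigma^2_g+\sigma^2_{tg}+\sigma^2_m+\sigma^2_{tm}+\sigma^2_e},$$
$$\mathrm{CAC} = \frac{\mathrm{BPICC}}{\mathrm{WPICC}}
             = \frac{\sigma^2_g}{\sigma^2_g+\sigma^2_{tg}},
  \qquad
  \mathrm{IAC} = \frac{\sigma^2_m}{\sigma^2_m+\sigma^2_{tm}+\sigma^2_e}.$$

RC-mechanism components are summarized through the same mapping (slope
variances in the time-varying slots); the genuinely time-varying
between-period correlation of RC data is out of scope here.

`solve_components()` inverts these formulas: given a target WPICC (and,
for cohort data, a target IAC) with the group-level variances anchored,
it returns the member and residual variances exactly.  The canonical
grid anchors $\sigma^2_g=\sigma^2_{tg}=1$ (CAC $=0.50$; the low
time-by-group variant uses $\sigma^2_{tg}=0.10$, CAC $\approx 0.91$) and
targets WPICC $\in\{0.10, 0.01, 0.001\}$ with IAC $=0.70$ for cohort
settings, giving for example cross-sectional residual variances 18, 198
and 1998, and cohort RM member/residual variances $(12.6,\,5.4)$ at
WPICC 0.10:

```{r}
solve_components(0.10, target_iac = 0.70, structure = "cohort")
```

An IAC of 0.70 is used because member-level correlation only matters to
the analysis when it is large.  Cohort solutions at the lower WPICC
values are recomputed from the algebra rather than transcribed (at
WPICC 0.01 the member variance is 138.6, not the 12.6 of the
highest-ICC row: keeping the member variance fixed would change the IAC
by an order of magnitude).

## The analytic model zoo

Eight analytic models are registered (`list_models()`): four families —
RM-ANOVA with VC covariance, RM-ANOVA with UN covariance, RC, and
Saturated — each with ("time x group") and, except the Saturated model,
without ("intercept only") the time-varying group random effect.  G
denotes the random-effects covariance and R the residual covariance, as
in the usual mixed-model formulation $Y_i = X_i\beta + Z_i\gamma_i +
\epsilon_i$, $\gamma_i \sim N(0, G)$, $\epsilon_i \sim N(0, R)$.

| model | cross-sectional | parameters | cohort | parameters |
|---|---|---|---|---|
| RM-ANOVA, VC | G = VC | 3, 2 | G = VC, R = CS | 4, 3 |
| RM-ANOVA, UN | G = UN | 16 (15), 2 | G = VC, R = UN | 17, 16 |
| RC | G = UN(2) | 4, 2 | G, member = UN(2) | 7, 4 |
| Saturated | G = UN, R = UN(1) | 20 (15), — | G = UN, R = UN | 30 (15), — |

Counts left of the comma are for the time-by-group variant, right for
intercept only; parenthesized counts are the group-mean formulation.

Two bookkeeping decisions deserve a note, since the underlying software
configurations cannot be reconstructed from parameter counts alone:

* **Cross-sectional RM-ANOVA/UN at individual level.**  A time-invariant
  group variance is aliased with an unstructured matrix over the five
  time-varying group effects, so the model is fitted as UN(5) plus a
  residual variance — 16 parameters, 15 in the group-mean formulation.
* **Intercept-only cohort RC (4 parameters).**  Dropping only the group
  slope from the full cohort RC model would leave five parameters; the
  registered model drops the group slope *and* the member intercept-slope
  covariance, i.e. a group intercept, independent member intercept and
  slope, and residual error.  This is the only nearby parameterization
  consistent with the published count.

The intercept-only cohort RM-ANOVA/UN model (group intercept, UN member
covariance) is the familiar mixed model for repeated measures of
individually randomized longitudinal trials.

## REML estimation on balanced designs

Every registered model's marginal covariance for one group block of $m$
members by $t$ periods can be written

$$V \;=\; J_m \otimes A \;+\; I_m \otimes B,$$

where $A$ ($t\times t$) collects group-level random effects shared by
all members and $B$ collects member-level effects and residual error —
and $V$ is *linear* in the covariance parameters for every structure in
scope (VC, CS, UN, UN(1), intercept+slope).  The spectral decomposition
of $J_m$ splits each group block into two strata: the member-mean
direction with covariance $S_1 = mA + B$ (multiplicity 1) and member
deviations with covariance $B$ (multiplicity $m-1$).  All REML
quantities therefore reduce to $t\times t$ algebra over two sufficient
statistics per dataset — the $t$-vector of period means per group and
the pooled within-group scatter matrix — regardless of $m$.  A fit at
the canonical scale (4000 observations) takes milliseconds, which is
what makes the Monte Carlo studies cheap.

Numerical choices:

* **Optimizer.**  Fisher scoring on the REML criterion with step
  halving.  For covariance structures linear in their parameters the
  expected information is available in closed form and scoring is the
  classic REML algorithm; on balanced data it typically converges in a
  handful of iterations.  Starting values are a method-of-moments
  projection of the stratum estimates ($m\,\bar e \bar e^\top$ pooled,
  and the within-group scatter) onto the covariance basis by least
  squares; one deterministic perturbed restart is attempted before a fit
  is declared non-convergent.  Non-convergence is a flagged result, not
  an error, so a Monte Carlo run never dies mid-stream.
* **Unconstrained ("nobound") estimation.**  Covariance parameters are
  not sign-constrained; the only requirement on an accepted iterate is
  that both strata $S_1$ and $B$ be positive definite, which is exactly
  positive definiteness of the assembled marginal covariance.
  Unstructured matrices are parameterized elementwise (not by Cholesky
  factors) precisely so that non-positive-definite *G* components remain
  reachable; negative variance estimates are reported with a flag.  This
  matters for type I error: constraining a null variance to zero halves
  its sampling distribution and distorts the test.
* **Convergence.**  Relative log-likelihood change below $10^{-10}$ and
  a gradient-norm check, with at most 200 iterations.
* **Fitting level.**  The cross-sectional RM-ANOVA/UN and both Saturated
  models are fitted on group-period means by default.  In the
  mean-parameterization the joint REML criterion separates into a
  means-model part and a within-group part, so the fixed-effect
  estimates, their adjusted covariance and the interaction p-value are
  identical to the individual-level fit on balanced data (the test suite
  verifies equality to $10^{-8}$), at a fraction of the cost.  A flag
  forces individual-level fitting.  Group-mean reduction refuses unequal
  group sizes, where the equivalence is not guaranteed.

## Small-sample tests

The null hypothesis is no time-by-condition interaction: $(t-1)(c-1)$
numerator df under categorical time coding, $c-1$ under linear coding.

**Kenward-Roger.**  The adjusted covariance of $\hat\beta$ and a scaled
F statistic with possibly fractional denominator df are obtained by
moment matching of the Wald statistic, with the inverse expected REML
information as the covariance of the covariance-parameter estimates.
For structures linear in their parameters the second-derivative term of
the adjustment vanishes, so the original and "improved" constructions
coincide; both method labels (`kr1`, `kr2`) are accepted and agree
identically here.  The implementation reproduces the classical exact
cases, which the test suite asserts: ordinary least squares
(adjustment vanishes, ddf $= n - \mathrm{rank}\,X$), the balanced
one-period nested ANOVA (ddf $= cg-2$), and Hotelling's $T^2$ for the
saturated group-mean model (ddf $= G - c - q + 1$).  Fractional ddf are
never rounded.

**Between-within.**  The residual df are partitioned at the group level:
contrasts of effects constant within a group (condition) receive
$G - \mathrm{rank}\,X_{between}$ df; contrasts of effects varying within
a group (time, time-by-condition) receive the remaining residual df.
Deterministic integer df, provided for comparison with the
design-based tradition.

## The Monte Carlo harness

`mc_scenario()` fixes a design, a generating mechanism and a model list;
`run_scenario()` simulates, fits, tests and aggregates.  Conventions:

* Rejection rates are computed over converged fits only, with the
  failure count reported alongside (the convergent-only denominator is
  the transparent choice; failures are rare to absent on this grid).
* The 95% Monte Carlo interval is the Wilson score interval.
* Every replication's seed derives deterministically from the scenario
  base seed (`replication_seed()`), so a flagged replication can be
  replayed in isolation and parallel execution cannot change results.
* The canonical study conditions are two conditions, five periods at
  times 0-4 (used raw, no centering), 40 members per group, 10/20/40
  groups per condition, WPICC $\in\{0.10, 0.01, 0.001\}$, CAC 0.50 (or
  0.91), IAC 0.70, nominal level 0.05.  The reference replication count
  is 1000; the package's tests and acceptance checks use 300
  replications and a subset of the grid (one cohort-RC and one
  cross-sectional scenario at $g=10$, WPICC 0.10, plus reduced-rep
  directional checks), chosen so the whole suite runs on a desk machine
  in well under an hour while keeping the binomial Monte Carlo error
  (about 0.013 at 300 replications) small relative to the effects being
  demonstrated.

What the checks do and do not show: the generator emulates exactly the
normal, balanced, complete-data world of the design above.  Passing
tests demonstrate correctness of the algebra and the qualitative
conclusions — correctly specified RC and Saturated models with KR df
hold the nominal level; variance-components RM-ANOVA applied to RC data
inflates; omitting a real time-by-group effect inflates severely unless
the ICC is tiny — they do not speak to unbalanced designs, attrition,
non-normal outcomes, or decaying autocorrelation structures, none of
which the generator produces.

## Known limitations

* Exponentially decaying cluster/individual autocorrelations and the
  time-varying between-period ICC of the RC mechanism are not
  summarized or fitted.
* Unbalanced designs are rejected rather than approximated (the blocked
  stratum algebra and the group-mean equivalence both rely on balance).
* Information-criterion model selection is deliberately absent.
* More than two conditions are supported by the schema and design
  matrices, but the canonical grid and all validation use two.
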