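---
title: "Time-specific AUC for an interval-censored disease marker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-specific AUC for an interval-censored disease marker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idmAUC)
```

## The model

A subject starts disease-free (state 0), may develop an irreversible
disease (state 1) and may die (state 2, absorbing), with a direct
0 &rarr; 2 path. The process is Markov with transition intensities
$\lambda_{01}(t)$, $\lambda_{02}(t)$, $\lambda_{12}(t)$ on the
time-since-origin clock; time is measured in **months** throughout, and
the reporting layer converts to years (1 year = 12 months).

Disease status is a binary time-dependent marker $X(t)$ observed only at
scheduled visits, so onset is interval-censored: it is only known to lie
in $(L, R]$ between the last negative and first positive screen, and we
use the half-open convention (onset strictly after $L$, at or before
$R$). Death and censoring times are observed exactly. When the last
screen before death or censoring is negative, the terminal disease
status is unknown, and all interval-censored likelihoods in this package
sum it out.

The generating model used for all study conditions has Weibull
intensities $\lambda_{hl}(t) = \alpha_{hl} k t^{k-1}$ with common shape
$k = 0.5$ and rates $\alpha_{01} = \alpha_{02} = 0.05$,
$\alpha_{12} = 0.56$ per month$^{k}$, so the death hazard ratio for
diseased vs disease-free subjects is constant,
$\gamma(t) = \lambda_{12}(t)/\lambda_{02}(t) = 11.2$.

## Two time-specific AUCs

Both definitions reduce, for a binary marker, to
$0.5 + 0.5\,(p - \pi_1)$ with two prevalences:

* **Incident/dynamic**, at time $t$: cases die exactly at $t$, controls
  survive beyond $t$. $\pi_1(t)$ is the disease prevalence among
  survivors, $P_{01}(0,t)/[P_{00}(0,t)+P_{01}(0,t)]$, and $p(t)$ the
  prevalence among the dying, which the hazard ratio tilts:
  $P_{01}\gamma(t)/[P_{00}+P_{01}\gamma(t)]$. Hence $\gamma \equiv 1$
  forces AUC $\equiv 0.5$, $\gamma > 1$ pushes it above, $\gamma < 1$
  below — a property the test suite checks on whole grids.
* **Cumulative/dynamic**, marker frozen at $s$, window end $t$: cases
  die in $(s,t]$, controls survive past $t$. Both prevalences are pure
  transition-probability functionals, so this AUC is insensitive to how
  the within-window hazard is parametrised.

The package evaluates the cumulative/dynamic curve with a 5-year
(60-month) window by default, at start times $s$ such that $s + 60$
stays within the 120-month horizon; the tabled evaluation points are
$(12, 72)$, $(36, 96)$ and $(60, 120)$ months. Under the generating
model these give 0.59, 0.62, 0.64 (and the incident/dynamic values at
1/3/5 years are 0.71, 0.72, 0.72), which `scripts/acceptance.R`
recomputes from scratch.

## Estimation routes

All fitted objects honour one small contract (`idm_transprob`,
`idm_cumhaz`, `death_hazard_ratio`, `idm_jump_times`), and the plug-in
estimators `auc_id()` / `auc_cd()` are written against that contract
only.

**Cox with time-dependent marker** (`fit_cox_idm`): the naive route that
treats the first positive visit $R$ as an exact onset time. Counting
process rows $(0,R]$ with $x=0$ and $(R,T^*]$ with $x=1$, Breslow ties,
baseline identified with $\lambda_{02}$,
$\lambda_{12} = e^{\beta}\lambda_{02}$, Nelson–Aalen for the 0&rarr;1
hazard, Aalen–Johansen product integrals for $P(s,t)$. A second,
ROC-based incident estimator (`riskset_auc_id`) uses model-based
risk-set weights for the case distribution and the empirical risk-set
marker distribution for controls; taking the control distribution over
the whole at-risk set (the single incident case has negligible mass for
continuous death times) makes the null case $\beta = 0 \Rightarrow$
AUC $= 0.5$ exact.

**Piecewise-constant panel likelihood** (`fit_pwc_idm`): intensities
constant between changepoints (default 6, 30, 60, 90 months). Interval
transition matrices use the closed form for the triangular generator,
with the removable-singularity limit $q_{01} d\, e^{-q_{12} d}$ when
$q_{01} + q_{02} = q_{12}$. Likelihood factors: $P_{00}/P_{01}/P_{11}$
per consecutive visit pair; for death at $T^*$ from last-seen state $h$,
$\sum_{l} P_{hl}(v^*, T^*)\lambda_{l2}(T^*{-})$ (hidden terminal status
summed out; the left-limit piece avoids ambiguity when death falls on a
changepoint); for censoring alive, $\sum_{l} P_{hl}(v^*, T^*)$.
Optimisation is quasi-Newton on log-rates (box constraints enforce
positivity), initialised from per-piece occurrence/exposure rates that
treat $R$ as exact. The proportional constraint
$\lambda_{12,j} = \lambda_{02,j} e^{\beta}$ is available for hazard-ratio
reporting; **AUC estimation defaults to the unconstrained fit** — the
constraint changes the AUC only mildly in our checks, and the
unconstrained fit is the more flexible model of the two, so it is the
better default when the estimand is a transition-probability functional.

**Weibull interval-censored likelihood** (`fit_weibull_ic`): six free
parameters (per-transition shapes and rates — the shapes are *not*
constrained equal, matching the flexibility the parametrisation allows,
even though the simulator uses a common shape). Contributions for the
four observation patterns (never/ever positive × died/censored) share
one onset integral
$\int P_{00}(L,u)\lambda_{01}(u) P_{11}(u, T^*)\,du$. Multi-start
quasi-Newton (crude rates with exponential shapes, fixed agnostic
defaults, a perturbed start), standard errors from the numerical Hessian
of the log-parameterised likelihood.

## Numerical choices

* **Quadrature.** The onset integrand contains
  $\lambda_{01}(u) \propto u^{k_{01}-1}$, singular at 0 for shapes below
  one. Substituting $z = u^{k_{01}}$ absorbs the singular factor exactly
  (for $k = 0.5$ this is the classical $u = v^2$ substitution), leaving
  a smooth integrand handled by fixed Gauss–Legendre rules: 41 nodes for
  the true-model transition probabilities (checked against adaptive
  quadrature to $10^{-8}$ absolute), 21 nodes inside the Weibull
  likelihood where speed matters.
* **Left limits.** Models with step-function transition probabilities
  (the Cox fit) evaluate the incident/dynamic plug-in at $P(0, t-)$ for
  *both* components. The marker enters the partial likelihood as a
  predictable process, so its value at an event time is the value just
  before; the practical consequence is that the curve equals 0.5 before
  the first observed diagnosis, and at an evaluation time that coincides
  with a visit the diagnoses made at that visit do not yet count. The
  cumulative/dynamic estimator, by contrast, freezes the marker at the
  measurement made at $s$ (right-continuous there): a diagnosis at the
  visit at $s$ is part of the marker value being evaluated. Smooth
  models are unaffected by either convention.
* **Ties and degenerate records.** Breslow tie handling (adequate for
  the modest tie multiplicity of visit-grid data; Efron is deliberately
  out of scope); diagnosis coinciding with the end of follow-up keeps
  the terminal row diseased by default (`diag_at_end = "diseased"`,
  matching the generating rule $X(T^*) = X(v^*)$), with the
  disease-free convention available behind the flag — on simulated data
  at $N = 2000$ the two conventions move $\hat\beta$ by well under 0.01.
  `coxph` is run with `timefix = FALSE` because the $k < 1$ hazard
  legitimately produces death times of order $10^{-7}$ months that the
  tie-rounding heuristic would collapse into zero-length intervals.
* **Caching.** The piecewise-constant likelihood reduces the visit pairs
  to counts per unique (from, to) time pair — regular grids make this
  set small — and precomputes the parameter-independent piece-overlap
  geometry once per dataset, so each likelihood evaluation is a handful
  of matrix products.
* **Optimiser tolerances.** L-BFGS-B with `factr = 1e7`
  ($\approx 10^{-9}$ relative); rates bounded in $[10^{-8}, 5]$
  (piecewise) and $[10^{-7}, 20]$ with shapes in $[0.05, 8]$ (Weibull),
  and estimates at a bound are flagged as boundary solutions rather than
  silently returned.

## The simulator

`simulate_idm()` reproduces the study conditions: latent paths by
inversion (common shape required by the inversion formulas), exit-state
choice with probability $\alpha_{01}/(\alpha_{01}+\alpha_{02})$,
conditional death times for diseased subjects, administrative censoring
at 120 months or uniform censoring on 60–120 months, and
interval-censoring of onset on the regular grid $\{0, \tau, 2\tau,
\dots\}$ with $\tau \in \{3, 6, 12\}$. Onset falling exactly on a visit
day is detected at that visit (inclusive rule); a visit exactly at the
death/censoring time is kept. The 18 scenario configurations are exposed
by `scenario_catalogue()`.

The generator emulates a screening cohort with a *state-independent*
visit process and visit times common to all subjects. It does not
emulate irregular or informative visiting, marker misclassification,
covariate heterogeneity, or recurrent/reversible disease — so passing
tests show correct behaviour under ideal screening logistics, not
robustness to the messier attendance patterns of real cohorts.

Randomness: each dataset is drawn from one seeded base-R stream with
fully vectorised draws (deterministic given seed and $N$); the
simulation harness draws all replicate seeds once from the master seed,
so aggregated results do not depend on evaluation order.

## Problem sizes

The shipped tests run the harness at the sizes a desk check needs:
100 replicates for the Cox and piecewise-constant bias tables, 50 for
the Weibull fits (Monte Carlo error on a bias of order 0.01 is then
about 0.002–0.004), with the full 1000-replicate design available by
raising `nsim`. Distributional properties use $2\times 10^5$ latent
paths.

## Known limitations

* The M-spline (penalised-likelihood) route and its smoothing-parameter
  selection are out of scope, as are covariates, confidence bands for
  the AUC curves, and the alternative incident/dynamic definition with
  the marker evaluated at an earlier time.
* The piecewise-constant model's early pieces are weakly identified
  when the visit spacing is coarse relative to the first changepoints
  (e.g. yearly visits against a changepoint at 6 months): the fitted
  early-piece hazards, and hence the incident/dynamic AUC before the
  first visit, then carry substantial replicate-to-replicate
  variability.
* `death_hazard_ratio` for the Cox route is the single constant
  $e^{\hat\beta}$; a time-varying ratio is only available from the
  Weibull or piecewise-constant fits.
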