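# idmAUC

Discrimination performance of a binary, interval-censored disease marker
on survival, in the illness-death (healthy → diseased → dead, with a
direct healthy → dead path) multi-state model.

In screening cohorts — post-operative surveillance for metastases,
dementia studies, and similar designs — disease can only be detected at
scheduled visits, so onset is *interval-censored*: it happened somewhere
between the last negative and first positive screen, and a patient whose
last screen was negative may still have developed disease before dying.
`idmAUC` quantifies how well such a marker separates dying from surviving
patients over time, using two time-specific AUC definitions expressed in
terms of the model's transition probabilities \(P_{hl}(s,t)\) and
death-hazard ratio \(\gamma(t) = \lambda_{12}(t)/\lambda_{02}(t)\):

- **incident/dynamic**:
  \(AUC^{I/D}(t) = 0.5 + 0.5\,(p(t) - \pi_1(t))\), contrasting deaths at
  `t` with survivors beyond `t`, where \(\pi_1(t)\) is disease prevalence
  among survivors and \(p(t)\) prevalence among the dying;
- **cumulative/dynamic**:
  \(AUC^{C/D}(s,t)\), with the marker frozen at `s`, contrasting deaths
  in `(s,t]` with survivors beyond `t`.

The package provides the generating Weibull illness-death model with its
exact AUC curves, three estimation routes (a naive Cox model with
time-dependent marker that ignores interval censoring; a
piecewise-constant panel likelihood; a Weibull likelihood for
interval-censored onset and exact death times), a simulator for
visit-grid screening data, and a simulation harness that reports bias,
empirical SE and RMSE of each estimator's AUC.

## Worked example

```r
library(idmAUC)

truth <- weibull_idm()          # k = 0.5, rates 0.05/0.05/0.56 per month^k
round(true_auc_id(truth, c(12, 36, 60)), 2)
#> [1] 0.71 0.72 0.72
round(true_auc_cd(truth, c(12, 36, 60), c(72, 96, 120)), 2)
#> [1] 0.59 0.62 0.64
death_hazard_ratio(truth, 12)
#> [1] 11.2

# a screening cohort: 1000 subjects, 3-monthly visits, uniform censoring
pd <- simulate_idm(1000, tau = 3, censoring = "uniform", seed = 1)
pd
#> Illness-death panel: 1000 subjects, 18386 visit records, 561 deaths

fit <- fit_cox_idm(pd)          # naive: first positive visit = onset
exp(fit$beta)
#> [1] 10.49058
auc_id(fit, 12)$value           # incident/dynamic AUC at 1 year
#> [1] 0.6758918

wfit <- fit_weibull_ic(pd)      # accounts for interval censoring
auc_id(wfit, 12)$value
#> [1] 0.7024146
```

The Cox route under-reads both the hazard ratio (10.5 vs the generating
11.2) and the year-1 AUC (0.676 vs the true 0.706) because it pretends
disease started at the first positive visit; the interval-censored
Weibull fit recovers the truth closely. The gap widens with coarser
visit schedules — `run_scenario()` reproduces those bias tables, e.g.

```r
rows <- run_scenario("C", nsim = 100, models = "cox", seed = 7)  # yearly visits
subset(rows, metric_kind == "ID", c(eval_time, truth, bias, se))
# year-1 bias is -0.21 with SE 0.00: before the first visit at 12 months
# no disease has been observed, so every replicate's AUC is exactly 0.5
```

A thin CLI over the same functions lives at `inst/cli/idmauc.R`
(`truth`, `simulate`, `fit`, `auc`, `run-scenario` subcommands).

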