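# cllcea

Lifetime cost-effectiveness modelling of first-line therapy for older
chronic lymphocytic leukemia (CLL) patients, from a Chinese payer
perspective.

## The problem

Chinese guidelines allow either continuous oral ibrutinib (IB) or six
cycles of intravenous bendamustine plus rituximab (BE+RI, with
lenalidomide maintenance) as first-line therapy for previously untreated
CLL patients aged 65+ without del(17p)/TP53 aberration. The two
strategies differ sharply in drug cost profile (ongoing oral BTK-inhibitor
vs front-loaded chemo-immunotherapy plus years of maintenance), toxicity
and progression risk, so the economically preferred option is not obvious.
`cllcea` implements a decision-analytic model that answers this with
quality-adjusted life-years (QALYs), discounted lifetime costs in 2022
USD, and an incremental cost-effectiveness ratio (ICER)

> ICER = ΔCost / ΔQALY,

judged against a willingness-to-pay threshold of $38,223.34/QALY
(3 × Chinese per-capita GDP). A strategy that is both cheaper and more
effective is *dominant*.

## What is inside

* **Markov cohort engine** (`run_cohort`): states EFS → TF (transient) →
  post-failure treatment lines (2L, 3L, allo-HSCT, BSC) → death; monthly
  cycles for 4 years then yearly to 10 years; per-line survival clocks
  via tunnel compartments; background mortality floor from a life table;
  cycle-start discounting at 5%/year.
* **Parametric survival toolkit** (`surv_dist`, `fit_parametric`,
  `select_best`): six families (exponential, Weibull, Gompertz, gamma,
  lognormal, log-logistic), right-censored MLE via `flexsurv`, AIC/BIC
  selection.
* **Pseudo-IPD reconstruction** (`reconstruct_ipd`, `km_estimate`):
  Guyot-style interval algorithm recovering patient-level data from
  digitized Kaplan–Meier coordinates plus number-at-risk tables.
* **Costing and utilities** (`cycle_cost`, `cycle_utility`): drug
  regimens, administration/supportive/hospitalization fees, severe
  adverse events, follow-up schedule, BSC, transplant and end-of-life
  costs; route-specific EFS utilities and SAE disutilities.
* **Economics and uncertainty** (`compute_icer`, `one_way_dsa`,
  `run_psa`, `ceac`): dominance classification, tornado analysis over
  published ranges, 1000-draw probabilistic sensitivity analysis with
  moment-matched gamma/beta/normal distributions, acceptability curves.
* **Synthetic data** (`simulate_cohort`, `digitize`, `make_life_table`):
  everything the tests need, generated in code.

See `vignette("model-methods", package = "cllcea")` for the model's
assumptions, parameter anomalies handled as-published, and known
reproduction gaps.

## Worked example

```r
library(cllcea)
model <- default_model()     # full packaged model definition
bc <- run_base_case(model)
bc
#> <ce_result> BE_RI vs IB (WTP $38,223.34/QALY)
#>   BE_RI    cost $286,307.54, QALYs 3.7652
#>   IB       cost $185,275.64, QALYs 4.4607
#>   delta cost $101,031.90, delta QALYs -0.6955
#>   ICER: $-145,261.96, BE_RI: dominated
```

Reading: over ten years a first-line IB patient accrues 4.46 discounted
QALYs at $185,276 while a BE+RI patient accrues 3.77 QALYs at $286,308 —
BE+RI is *dominated* (costs $101,032 more, yields 0.70 fewer QALYs), so
the ICER is negative and first-line IB is the economically preferred
strategy at any willingness-to-pay. `ce_table(bc)` gives the cost
breakdown (first-line drugs, subsequent drugs, adverse events, other);
`run_analysis()` writes the base case, tornado, PSA scatter and CEAC as
CSV plus a run manifest.

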