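# psmcure

Partitioned survival cost-effectiveness modelling with mixture cure
extrapolation, for trial-based economic evaluation in oncology.

The package targets the question of whether adding a PD-L1 inhibitor
(atezolizumab) to first-line carboplatin–etoposide chemotherapy for
extensive-stage small-cell lung cancer is cost-effective from a US payer
perspective. Immunotherapy survival curves often end in a plateau that
standard parametric extrapolation cannot represent, so the package fits
both the five standard families and a mixture cure model

S_pop(t) = S_gen(t) · { p_cured + (1 − p_cured) · S_uncured(t) },

where S_gen is general-population survival from a life table (cured
patients die at background rates) and S_uncured a standard parametric
kernel, and feeds either extrapolation into a three-state partitioned
survival model (progression-free, post-progression, dead; 21-day
cycles, 2.5-year horizon, 3% annual discounting):

pf_k = min(S_PFS(t_k), S_OS(t_k)),  pp_k = S_OS(t_k) − pf_k,
dead_k = 1 − S_OS(t_k).

Around that core it provides:

* **Synthetic trial generation** calibrated to the published trial
  summaries (median OS 12.3/10.3 months, 12-month OS 51.7%/38.2%,
  OS HR ≈ 0.70, median PFS 5.2/4.3 months, PFS HR ≈ 0.77, intervention
  arm survival plateau) — patient-level trial data were never published.
* **Kaplan–Meier utilities**: product-limit estimation with Greenwood
  errors, curve digitization emulation, and Guyot-style pseudo-IPD
  reconstruction from digitized coordinates plus numbers at risk.
* **Survival fitting**: censored MLE for exponential, Weibull, Gompertz,
  log-logistic and log-normal families; AIC model selection; additive
  background mortality; mixture cure fitting with the background inside
  the likelihood; a Schoenfeld-residual proportional-hazards diagnostic.
* **Economics**: discounted costs by category (drugs dosed by the
  Calvert formula and body surface area, administration, supportive
  care, second-line chemotherapy, terminal care, adverse-event
  management), QALYs and life-years, incremental cost-utility/
  cost-effectiveness ratios, one-way DSA tornado tables, a 1,000-draw
  probabilistic sensitivity analysis with cost-effectiveness
  acceptability curves, and utility scenario analyses.

## Worked example

```r
library(psmcure)
rep <- run_pipeline(seed = 1, psa_draws = 1000)
rep
#> Partitioned-survival cost-effectiveness report (seed 1 )
#>
#>                model        group   cost  qaly   lyg    icur    icer
#>         mixture_cure intervention 120538 0.669 0.986      NA      NA
#>         mixture_cure      control  29724 0.606 0.914      NA      NA
#>         mixture_cure  incremental  90814 0.063 0.071 1439833 1273004
#>  standard_parametric intervention 120053 0.660 0.968      NA      NA
#>  standard_parametric      control  29724 0.606 0.914      NA      NA
#>  standard_parametric  incremental  90328 0.054 0.054 1680764 1667655
#>
#> P(cost-effective at US$100,000/QALY):  mixture_cure 0 %; standard_parametric 0 %
```

Reading the output: the pipeline simulated a 403-patient trial from the
calibrated generator, reconstructed pseudo-IPD from its digitized
Kaplan–Meier curves, fitted the survival models, and ran the economic
model under both intervention-arm extrapolations ("model 1" = mixture
cure, "model 2" = standard parametric; the control arm is always
standard parametric). The combination costs about US$91,000 more per
patient over the horizon and gains 0.05–0.06 QALYs, so the incremental
cost-utility ratio is above US$1.4M/QALY at this trial-size replicate —
an order of magnitude above the US$100,000/QALY willingness-to-pay
threshold — and none of the 1,000 probabilistic draws is
cost-effective. The cure variant keeps more tail survival, hence more
life-years and a lower ICUR than the parametric variant.

Individual stages are exposed as ordinary fitting functions with the
usual methods:

```r
cal <- default_calibration()
ipd <- generate_ipd(cal$arms, cal$lifetable, seed = 1)
bg  <- lifetable_survival(cal$lifetable, start_age = 64)
d   <- subset(ipd, arm == "A+C")

fit <- fit_mixture_cure(d$os_time, d$os_event, family = "gompertz",
                        background = bg, restricted = TRUE)
fit
#> Mixture cure fit (uncured kernel: gompertz restricted )
#>   cure fraction: 0.02445
#>   uncured: shape = 0.12186, rate = 0.029279
#> logLik: -530.15   AIC: 1066.3

round(predict(fit, times = c(12, 24, 60)), 4)  # population survival
#> [1] 0.4592 0.0377 0.0229
plot(fit)                             # KM overlay with plateau line
```

`fit_parametric()`, `kaplan_meier()`, `reconstruct_ipd()`,
`ps_model()`, `one_way_dsa()`, `psa()`, `ceac()` and
`scenario_analysis()` follow the same pattern; `write_report()` emits
the full report pack (results, fit rankings, survival grids, tornado,
PSA draws, CEAC) as plain CSV.

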