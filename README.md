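# odorddm

Drift-diffusion analysis of olfactory figure–background segregation: how do
background odorants interfere with the detection of a target odorant? This
package is for psychophysicists and computational neuroscientists analysing
two-alternative odor-detection behaviour (choices and reaction times) with
the drift-diffusion model (DDM), and for anyone who wants a fully synthetic,
end-to-end testable version of that analysis.

## The model

A decision variable accumulates evidence, `dx/dt = A + ξ` with
`E[ξ(t)ξ(t′)] = c²δ(t−t′)`, from a starting point `mθ` until it first hits
`+θ` ("report target present") or `−θ` ("report target absent"). With
`r = 2Aθ/c²`:

- choice probability `p = (e^r − e^{−rm}) / (2 sinh r)`,
- mean decision time `E[DT] = θ[cosh r − m sinh r − e^{−rm}] / (A sinh r)`,
- and the derivative signs `∂p/∂A > 0`, `sign(∂p/∂c²) = −sign(A)`,
  `∂E[DT]/∂c² < 0` — extra diffusion noise always makes decisions *faster*.

Three interference mechanisms map background count to parameters: **false
signal** (drift increases), **signal reduction** (drift decreases), **noise
boost** (diffusion variance increases). Only the noise boost predicts the
paradoxical signature of faster-but-less-accurate responses on harder
trials; the fitted models quantify how much of the interference loads on
signal vs noise.

The fitting stage is the chi-square quantile method: per condition, correct
and error reaction times are summarized by 5 quantiles into 6 bins each
(12 statistics × 18 conditions = 216), expected bin counts come from the
defective first-passage-time CDF mixed with a 5% uniform contaminant, and
`Σ(O−E)²/E` is minimized over 38 parameters per mouse (per-condition
threshold and drift in unit-diffusion coordinates, shared start fraction
and non-decision time), then rescaled exactly to drift/diffusion units with
the threshold fixed at 1/2.

## Worked example

```r
library(odorddm)
set.seed(1)

# closed-form prediction curves for the noise-boost mechanism
spec <- hypothesis_spec("noise_boost",
                        baseline_on  = ddm_params(2,   3, 1),
                        baseline_off = ddm_params(-2.5, 3, 1))
head(prediction_table(spec, 0:3), 4)
#>     mechanism n_background trial_type         p   mean_dt
#> 1 noise_boost            0  target_on 0.7913915 0.2913915
#> 2 noise_boost            1  target_on 0.7310586 0.2310586
#> 3 noise_boost            2  target_on 0.6899745 0.1899745
#> 4 noise_boost            3  target_on 0.6607564 0.1607564

# synthetic mouse -> preprocessing -> 38-parameter chi-square fit
cfg    <- task_config(n_sessions = 20)
trials <- generate_mouse_dataset(cfg)
kept   <- normalize_reaction_times(filter_sessions(trials)$trials)
res    <- fit_mouse(kept, seed = 1)
res$fit
#> DDM chi-square fit, mouse m1: 18 conditions, m = 0.094, Ter = 0.250 s, objective = 210.09

parameter_recovery_report(default_ground_truth(), res$fit)$metrics
#>           class        bias       rmse correlation
#> 1         drift -0.02093131 0.20108818   0.9850911
#> 2 diffusion_var  0.02351641 0.08190336   0.9447287
```

The prediction table shows the report-present probability contracting
toward `(1+m)/2 = 0.5` and the mean decision time falling as backgrounds
are added. The recovery metrics say the fit reads back the generating
per-condition drifts (truth-estimate correlation 0.985) and diffusion
variances (0.945) from a 20-session (~5,000-trial) mouse; at the full
70-session scale the correlations reach ~0.997 and ~0.977.

A thin CLI over the same functions is installed as `exec/odorddm`
(subcommands `generate`, `preprocess`, `fit`, `predict`, `evaluate`,
`recover`).

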