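# tvmvar

Recursive estimation of **time-varying multivariate autoregressive (tvMVAR)
models** from multi-trial electrophysiological recordings (EEG, MEG, LFP),
and time–frequency **directed connectivity** derived from them.

Directed interactions between brain areas evolve within tens of
milliseconds. A tvMVAR model

y(n) = Σ_{r=1..p} A_r(n) y(n−r) + e(n)

captures those dynamics through time-dependent lag-coefficient matrices
A_r(n), estimated recursively sample by sample. The package implements the
four standard recursive estimators —

| algorithm | call | trial strategies | adaptation parameter |
|---|---|---|---|
| Recursive least squares | `fitRls()` | single- and multi-trial | forgetting factor λ |
| General linear Kalman filter | `fitGlkf()` | single- and multi-trial | constants c1, c2 |
| Multivariate adaptive AR estimator | `fitMvaar()` | single-trial | constant c2 (squared process noise) |
| Dual extended Kalman filter | `fitDekf()` | single-trial | update coefficient |

— and converts coefficient trajectories into the squared,
inflow-normalized **partial directed coherence**

PDC_ij(f,t) = |Ā_ij(f,t)|² / Σ_m |Ā_im(f,t)|²,  Ā(f,t) = I − Σ_r A_r(t) e^(−i2πfr/fs),

whose receiver rows sum to one at every time–frequency point
(`pdcSquared()`, `bandAverage()`, `totalDriving()`).

Around the estimators sit the tools needed to evaluate them systematically:
simulated benchmark networks with time-varying couplings
(`twoNodeNetwork()`, `fiveNodeNetwork()`, `buildNetwork()`,
`simulateTvMvar()`, `addMeasurementNoise()`, `antialiasDownsample()`),
model-quality metrics (`goodnessOfFit()`, `percentConsistency()`),
connectivity-accuracy metrics against the ground truth
(`missesFalseAlarms()`, `peakDelay()`), AIC/BIC order selection
(`informationCriteria()`), BCa bootstrap intervals and benchmark driver
criteria (`bootstrapBcaCi()`, `cohensDPooled()`, `evaluateCriteria()`),
and a sweep driver (`runSweep()`) that crosses algorithms with grids of
adaptation coefficients, model orders, sampling rates or trial counts.

## Worked example

```r
library(tvmvar)

model  <- twoNodeNetwork()                    # 1 -> 2 coupling, 8 ms lag, 1000 Hz
trials <- simulateTvMvar(model, nTrials = 20, seed = 1)
trials <- addMeasurementNoise(trials, snrDb = 20, seed = 2)
trials
#> TrialSet: 20 trial(s) x 2 channel(s) x 1000 sample(s) at 1000 Hz

cfg <- estimatorConfig("glkf", "multi_trial", orderP = 8, adaptation = 0.02)
fit <- fitGlkf(trials, cfg)

g <- goodnessOfFit(trials, fit)
sprintf("GOF: %.1f%% (pooled %.1f%%)", g$gof, g$pooled)
#> "GOF: 89.9% (pooled 94.5%)"

conn <- pdcSquared(fit, freqs = seq(0, 500, by = 5))
tru  <- pdcSquared(model, freqs = seq(0, 500, by = 5))
round(missesFalseAlarms(conn, tru, edgePartition(model)), 3)
#>      misses falseAlarms
#>       0.116       0.005

informationCriteria(trials, 2:20)[c("bicOrder", "aicOrder")]
#> $bicOrder [1] 10    $aicOrder [1] 10
```

The GOF line says the fitted trajectories one-step-predict ~90% of the
signal variance. The miss error (0.116) is the normalized mean squared PDC
error on the one coupled edge 1→2; the false-alarm error (0.005) is the
same quantity on the null edge 2→1 — estimates on the absent connection are
essentially flat zero. BIC selects order 10 for the 8 ms (8-sample) lag,
slightly above the lag as expected in the presence of measurement noise.

A thin command-line wrapper ships in `inst/cli/tvmvar.R`
(`simulate`, `fit`, `connectivity`, `sweep` subcommands; every output gets
a JSON metadata sidecar with the seed and config echo).

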