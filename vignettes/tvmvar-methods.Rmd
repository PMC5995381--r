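---
title: "Recursive time-varying MVAR estimation: models, algorithms and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recursive time-varying MVAR estimation: models, algorithms and evaluation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvmvar)
```

## The model

A d-channel recording y(n) is modeled as a time-varying multivariate
autoregression (tvMVAR) of order p,

$$ y(n) = \sum_{r=1}^{p} A_r(n)\, y(n-r) + e(n), $$

where the coefficient matrices $A_r(n)$ change over time and $e(n)$ is
zero-mean uncorrelated Gaussian innovation noise. Off-diagonal entries
$A_r(n)[i, j]$ quantify the lagged directed influence of channel j on
channel i; the frequency-domain summary of those influences is the squared,
inflow-normalized partial directed coherence (PDC)

$$ \mathrm{PDC}_{ij}(f, t) =
   \frac{|\bar A_{ij}(f,t)|^2}{\sum_m |\bar A_{im}(f,t)|^2},
   \qquad
   \bar A(f,t) = I - \sum_{r=1}^{p} A_r(t)\, e^{-2\pi i f r / f_s}, $$

so that for every receiver i, frequency and time the incoming values sum to
one. `pdcSquared()` enforces this normalization to $10^{-10}$, and a
ground-truth ("simulated") PDC computed from the generating coefficient
stack is exactly zero on every edge that was never given a coupling.

## The four estimators and the two trial strategies

All four estimators update a coefficient estimate recursively in time; all
run on data standardized to unit pooled variance internally (MVAR
coefficients are invariant under a uniform rescaling of all channels, so
this changes nothing about the estimates in exact arithmetic, but it gives
the covariance initializations and adaptation constants a fixed, data-free
meaning).

**RLS** (`fitRls`) discounts the lagged-observation Gram matrix by
$(1-\lambda)$ at every step before adding the current contribution, and
updates the coefficients through the innovation-weighted gain. The Gram
matrix starts at zero; we realize the required regularization as an initial
$\delta I$ with trace-scaled $\delta = 10^{-8}$ and then maintain the
*inverse* Gram matrix exactly by rank-one (Sherman–Morrison) updates, which
is algebraically the same recursion at $O((dp)^2)$ per step instead of
$O((dp)^3)$. The forgetting factor $\lambda \in (0,1)$ sets the effective
memory to roughly $1/\lambda$ samples.

**GLKF** (`fitGlkf`) runs a linear Kalman filter on the stacked state
$Q = [A_1^\top; \dots; A_p^\top]$ with a random-walk transition. The
observation-noise covariance $W$ (d × d) starts at the identity and is
updated recursively from the one-step prediction error with constant $c_1$;
in multi-trial mode the update uses the across-trial error covariance
(divided by $k-1$), and the observation stage stacks all k trials at every
time step. Two implementation choices deserve emphasis:

* the gain treats the k-trial innovation covariance as
  $H P H^\top + (\mathrm{tr}\, W / d)\, I_k$ — the matrix-variate filter
  with a spherical column approximation, which is what makes a single
  shared (dp × dp) state covariance exact across channels;
* the process noise is injected *relative to the current state-covariance
  scale*, $V_n = c_2\, (\mathrm{tr}\,P/dp)\, I$. With an absolute $c_2 I$
  the filter's behavior depends on the raw data scale: at usable signal
  amplitudes it is saturated by weight noise for $c_2 \gtrsim 0.1$ and
  over-adaptive at $c_2 = 0.001$, which inverts the known
  adaptation-speed phenomenology of these estimators. The relative form is
  the update-coefficient convention of adaptive-AR Kalman implementations
  and makes the per-step fractional adaptation approximately equal to
  $c_2$ itself, independent of trial count; multiple trials then reduce
  the *variance* of the trajectory by roughly the trial count rather than
  changing its speed.

**MVAAR** (`fitMvaar`) is the same single-trial recursion with two
variants: the process-noise constant enters squared ($c_2^2$), and the
measurement-noise covariance is updated from the prediction error of the
*previous* step.

**DEKF** (`fitDekf`) interleaves two filters per time step: a signal-state
filter on the companion-form state built from the current coefficient
estimates, and a weight filter on the stacked coefficients whose process
noise is the update coefficient times the identity. The recursion is a
reconstruction from the dual-estimation framework (the customary reference
implementation publishes code, not equations); it is gated here by
parameter-recovery tests against a least-squares oracle, not by
output-matching. Divergence (non-finite covariances) is reported with the
failing time index rather than masked — instability on larger networks is a
documented property of this estimator worth surfacing.

**Single-trial vs multi-trial.** RLS and GLKF can fit one shared model
across all trials simultaneously (multi-trial, MT); all four can fit each
trial separately (single-trial, ST) and combine afterwards, either by
averaging coefficient stacks (default — PDC normalization is then exact on
the averaged model) or by averaging per-trial PDC arrays. Model-quality
metrics score single-trial fits per trial against that trial's own model
and average the percentages; scoring every trial against the averaged
coefficients conflates combination error with model fit and collapses at
high model orders.

## Model quality and connectivity accuracy

* **GOF** = (1 − REV)·100, REV being the one-step squared prediction error
  normalized by signal variance; computed per channel and averaged, with a
  pooled (variance-weighted) variant reported alongside since the
  normalization convention is a genuine choice.
* **Percent consistency** simulates surrogates from the fitted model with
  residual-matched innovations and compares the full cross-correlation
  structure (all channel pairs, lags 0..p, Euclidean norm on the stacked
  vector).
* **Misses / false alarms**: normalized mean squared PDC error on edges
  with / without a simulated coupling, both normalized by the mean squared
  ground-truth PDC on the coupled edges.
* **Peak delay**: signed difference of the latency of the maximum of the
  frequency-averaged PDC time course, averaged over coupled edges; flat
  courses tie-break to the earliest index and are flagged.
* **AIC/BIC** are computed on pooled stationary least-squares fits with
  effective sample count $N_e = k(N-p)$; an argmin at the top of the grid
  is flagged as non-converged.

## The simulated networks

`twoNodeNetwork()` and `fiveNodeNetwork()` generate the two benchmark
layouts: a 2-node network with a single influence 1 → 2 (boxcar with
raised-cosine ramps, 250 ms active around mid-trial, 1000 Hz, 1 s trials)
at a configurable lag, and a 5-node acyclic network with four couplings at
lags of 1, 1, 2 and 3 samples (Gaussian pulses of 50 ms standard deviation
at distinct latencies, 500 Hz, 2 s trials). Trials are simulated
independently, started from a discarded burn-in of 10·p samples whose first
p values are pure innovations, and white measurement noise is added per
channel at a configurable SNR (variance ratio; 20 dB in the replication
protocols). An explosion bound of $10^6 \times$ the innovation SD aborts
unstable coefficient paths with the offending trial and time index.

Design choices that were genuinely open, and how they were fixed:

* **Diagonal self-regression.** Each node carries a damped-oscillator AR(2)
  baseline (`dampedOscillator()`, default 60 Hz at pole radius 0.75 for
  1000 Hz data). Two constraints drive this. A first-order diagonal with a
  moderate coefficient cannot produce realistic goodness-of-fit: an AR(1)
  with a = 0.5 caps GOF at ~25%, far below what band-limited
  electrophysiological signals show. A strong AR(1) (a ≈ 0.95) fixes GOF
  but makes the sender's recent past an excellent proxy for its lagged
  past, so order-selection criteria can absorb a lag-p coupling into order
  p−1 terms and the imposed lag becomes unidentifiable. A resonant AR(2)
  gives both: high one-step predictability (GOF ceiling ≈ 90–95%) with
  autocorrelation that decays within a few samples at horizons beyond the
  oscillation period.
* **Coupling amplitude.** The 2-node coupling peaks at 2.0. The influence
  is active only a quarter of the trial, and a pooled stationary fit can
  only capture its time-average; the unmodeled time variation acts as extra
  residual noise. Below an amplitude of ~1 the information criteria cannot
  see the imposed lag at all, which would make the order-selection study
  vacuous.
* **Pulse time scale (5-node).** 50 ms standard deviation: the adaptation
  study needs influences faster than the memory of a slow estimator
  (1/0.001 samples ≈ the whole trial) and slower than the ~10-sample
  memory at coefficient 0.1, i.e. the evoked-response time scale the
  method targets.
* **Innovation covariance** is the identity by default, configurable
  through `innovationSd`.

What the generator does *not* emulate: volume conduction / field spread,
non-Gaussian or correlated innovations, nonstationary noise floors,
artifacts, and inter-subject variability. Passing the simulation suite
therefore demonstrates correct recovery of linear lagged influences under
the model's own assumptions, not robustness to the full complexity of real
recordings — that is what the benchmark-criteria machinery
(`evaluateCriteria()`, BCa bootstrap over subjects) is for, given real
band-averaged connectivity per subject.

## Evaluation protocols and problem sizes

The replication protocols used by the test suite and the acceptance script
fix: 20 trials per dataset, adaptation coefficient 0.02 for every
algorithm (the a-priori value recommended for this family of estimators),
and the frequency grid at 5–10 Hz spacing up to Nyquist for PDC-error
metrics. Repetition counts are 20 for the fit-quality and pattern checks
and 10 for the order-selection ranges; these sizes keep each protocol in
the minutes range on one CPU while leaving the qualitative outcomes stable
across seeds (verified over several disjoint seed sets during
development). The bootstrap coverage check uses 2,000 Monte-Carlo
replications with 2,000 resamples each.

One caveat is reported openly: with this generator the AIC argmin for a
16 ms lag sits on a nearly flat tail of the criterion curve and its
minimum across repetitions lands at 18–21 rather than ≥ 22; the BIC
ranges, in contrast, are stable ([9,10] for 8 ms, [18,19] for 16 ms).
The tail location depends on spectral details of the generating process
that admit many plausible choices; we fixed the generator by the BIC
behavior and GOF realism and report AIC as computed.

## Numerical choices

* Kalman covariances are symmetrized (P ← (P+Pᵀ)/2) after every update.
* Innovation covariances receive a $10^{-12}$ trace-scaled ridge before
  inversion.
* RLS maintains the inverse Gram matrix by rank-one updates from a
  trace-scaled $\delta I$ start (see above).
* The antialiasing filter is an order-8 Chebyshev type-I (0.05 dB ripple)
  at 0.8 × the new Nyquist, applied forward-backward (zero phase), with
  integer decimation; stopband suppression after the double pass exceeds
  40 dB just above the new Nyquist, and a pulse peak maps to the nearest
  decimated index.
* Coefficients before time index p+1 are reported as zeros (the
  recursions' initialization), and time is 0-based internally with
  user-facing quantities in Hz, ms and seconds.

## Limitations

DEKF cost grows as $d^4 p^2$ per step and the estimator is prone to
divergence on high-dimensional networks; RLS shares the instability in
high dimensions. Sliding-window MVAR, nonparametric spectral-factorization
estimators, and PDC variants (generalized, orthogonalized, conditional)
are out of scope. The multi-trial W update requires at least two trials.
Rate sweeps compare estimates against a sample-and-hold decimation of the
generating coefficients, which is itself an approximation of "ground truth
at the lower rate" — the null-edge structure is preserved exactly, which
is what the false-alarm metric relies on.
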