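#' Create an estimator configuration
#'
#' @param algorithm "rls", "glkf", "mvaar" or "dekf".
#' @param strategy "single_trial" (fit per trial, then combine) or
#'   "multi_trial" (one shared model across trials; RLS and GLKF only).
#' @param orderP model order (number of lags).
#' @param adaptation one or two adaptation coefficients in (0, 1): the RLS
#'   forgetting factor, the Kalman constants c1 and c2 (a single value is
#'   used for both), or the DEKF update coefficient.
#' @param combineMode how single-trial fits are combined:
#'   "average_coefficients" (default) or "average_pdc".
#' @return an [EstimatorConfig-class] object.
#' @export
estimatorConfig <- function(algorithm, strategy = c("single_trial",
                                                    "multi_trial"),
                            orderP, adaptation,
                            combineMode = c("average_coefficients",
                                            "average_pdc")) {
  new("EstimatorConfig", algorithm = match.arg(tolower(algorithm),
                                               c("rls", "glkf", "mvaar",
                                                 "dekf")),
      strategy = match.arg(strategy), orderP = as.integer(orderP),
      adaptation = as.numeric(adaptation),
      combineMode = match.arg(combineMode))
}

# trials (k x d x N) -> cube (d, N, k) for the C++ cores
.as_cube <- function(trials) aperm(trialArray(trials), c(2, 3, 1))

# core output (d, dp, N) -> coefficient array (N, p, d, d)
.core_to_coeffs <- function(out, d, p) {
  N <- dim(out)[3L]
  tmp <- aperm(out, c(3, 2, 1))          # (N, dp, d=receiver)
  dim(tmp) <- c(N, d, p, d)              # (N, sender, lag, receiver)
  aperm(tmp, c(1, 3, 4, 2))              # (N, lag, receiver, sender)
}

.check_fit_inputs <- function(trials, config) {
  stopifnot(is(trials, "TrialSet"), is(config, "EstimatorConfig"))
  validObject(config)
  if (nSamples(trials) <= config@orderP)
    stop("trial length must exceed the model order")
  if (config@strategy == "multi_trial" && config@algorithm == "glkf" &&
      nTrials(trials) < 2L)
    stop("multi-trial GLKF requires at least 2 trials (the W update divides by k - 1)")
}

.wrap_fit <- function(trials, config, perTrial, fit1, multiFit = NULL) {
  fs <- samplingRate(trials)
  d <- nChannels(trials); p <- config@orderP
  mk <- function(out) new("TVMVARCoefficients",
                          coeffs = .core_to_coeffs(out, d, p),
                          samplingRate = fs)
  # the recursions run on globally standardized data: the covariance
  # initializations (P0 = I, W0 = I_d) and the absolute process-noise scale
  # of the adaptation coefficients presume unit-variance signals, and AR
  # coefficients are invariant under a uniform rescaling of all channels
  Y <- .as_cube(trials)
  s <- sqrt(mean(Y^2))
  if (s > 0) Y <- Y / s
  if (config@strategy == "multi_trial") {
    fit <- mk(multiFit(Y))
    return(if (perTrial) list(fit) else fit)
  }
  fits <- lapply(seq_len(nTrials(trials)),
                 function(t) mk(fit1(Y[, , t, drop = FALSE])))
  if (perTrial) fits else combineSingleTrial(fits, "average_coefficients")
}

#' Recursive least squares tvMVAR fit
#'
#' Recursive least-squares estimation with forgetting factor lambda: at each
#' step the lagged-observation Gram matrix is discounted by (1 - lambda) and
#' refreshed with the current observation, and the coefficient matrix is
#' updated through the innovation-weighted gain. Multi-trial fitting
#' accumulates the Gram and innovation updates over all trials at each time
#' step, yielding one shared model.
#'
#' @param trials a [TrialSet-class].
#' @param config an [EstimatorConfig-class] with algorithm "rls";
#'   `adaptation[1]` is the forgetting factor.
#' @param perTrial if TRUE and single-trial, return the list of per-trial
#'   fits instead of their combination.
#' @return a [TVMVARCoefficients-class] (or a list of them).
#' @export
fitRls <- function(trials, config, perTrial = FALSE) {
  .check_fit_inputs(trials, config)
  stopifnot(config@algorithm == "rls")
  lam <- config@adaptation[1L]; p <- config@orderP
  .wrap_fit(trials, config, perTrial,
            fit1 = function(Y) .rls_core(Y, p, lam),
            multiFit = function(Y) .rls_core(Y, p, lam))
}

#' General linear Kalman filter tvMVAR fit
#'
#' Linear Kalman recursion on the stacked coefficient state with random-walk
#' transition: process noise c2 * I, and an observation-noise covariance
#' updated recursively from the one-step prediction error with constant c1.
#' Multi-trial fitting stacks all trials in the observation stage at each
#' time step and updates the noise covariance from the across-trial
#' prediction-error covariance.
#'
#' @inheritParams fitRls
#' @param config an [EstimatorConfig-class] with algorithm "glkf";
#'   `adaptation` supplies c1 and c2 (one value is used for both).
#' @return a [TVMVARCoefficients-class] (or a list of them).
#' @export
fitGlkf <- function(trials, config, perTrial = FALSE) {
  .check_fit_inputs(trials, config)
  stopifnot(config@algorithm == "glkf")
  c1 <- config@adaptation[1L]
  c2 <- config@adaptation[min(2L, length(config@adaptation))]
  p <- config@orderP
  .wrap_fit(trials, config, perTrial,
            fit1 = function(Y) .glkf_core(Y, p, c1, c2, FALSE),
            multiFit = function(Y) .glkf_core(Y, p, c1, c2, FALSE))
}

#' Multivariate adaptive autoregressive (MVAAR) tvMVAR fit
#'
#' Same Kalman recursion as [fitGlkf()] restricted to single-trial modeling,
#' with two variants: the state process noise uses the squared constant
#' (c2^2 * I), and the measurement-noise covariance is updated from the
#' prediction error of the previous step.
#'
#' @inheritParams fitRls
#' @param config an [EstimatorConfig-class] with algorithm "mvaar";
#'   `adaptation` supplies c2 (and optionally c1, defaulting to c2).
#' @return a [TVMVARCoefficients-class] (or a list of them).
#' @export
fitMvaar <- function(trials, config, perTrial = FALSE) {
  .check_fit_inputs(trials, config)
  stopifnot(config@algorithm == "mvaar")
  if (config@strategy != "single_trial")
    stop("MVAAR only supports single-trial modeling")
  c2 <- config@adaptation[min(2L, length(config@adaptation))]
  c1 <- config@adaptation[1L]
  p <- config@orderP
  .wrap_fit(trials, config, perTrial,
            fit1 = function(Y) .glkf_core(Y, p, c1, c2, TRUE))
}

#' Dual extended Kalman filter tvMVAR fit
#'
#' Dual estimation: at each time step one Kalman filter tracks the signal
#' state (companion form built from the current coefficient estimates) and a
#' second filter tracks the stacked coefficients as a random walk whose
#' process noise is scaled by the update coefficient. Single-trial only. The
#' recursion is a reconstruction from the dual-estimation framework (state
#' filter + weight filter); divergence is reported, not masked.
#'
#' @inheritParams fitRls
#' @param config an [EstimatorConfig-class] with algorithm "dekf";
#'   `adaptation[1]` is the update coefficient.
#' @param stateNoise process-noise variance of the signal-state filter.
#' @param obsNoise observation-noise variance of the signal-state filter.
#' @return a [TVMVARCoefficients-class] (or a list of them).
#' @export
fitDekf <- function(trials, config, perTrial = FALSE, stateNoise = 1,
                    obsNoise = 0.01) {
  .check_fit_inputs(trials, config)
  stopifnot(config@algorithm == "dekf")
  if (config@strategy != "single_trial")
    stop("DEKF only supports single-trial modeling")
  uc <- config@adaptation[1L]; p <- config@orderP
  .wrap_fit(trials, config, perTrial,
            fit1 = function(Y) .dekf_core(Y[, , 1L], p, uc, stateNoise,
                                          obsNoise))
}

#' Fit a tvMVAR model with any configured algorithm
#'
#' Dispatcher over [fitRls()], [fitGlkf()], [fitMvaar()] and [fitDekf()].
#'
#' @inheritParams fitRls
#' @return a [TVMVARCoefficients-class] (or a list of per-trial fits).
#' @export
fitTvMvar <- function(trials, config, perTrial = FALSE) {
  switch(config@algorithm,
         rls = fitRls(trials, config, perTrial),
         glkf = fitGlkf(trials, config, perTrial),
         mvaar = fitMvaar(trials, config, perTrial),
         dekf = fitDekf(trials, config, perTrial))
}

#' Combine single-trial fits
#'
#' Either averages the coefficient stacks element-wise
#' (`"average_coefficients"`, returning one model) or computes squared PDC
#' per trial and averages the connectivity (`"average_pdc"`, returning a
#' [TFConnectivity-class]; averaging row-normalized arrays preserves the
#' unit row sums).
#'
#' @param fits list of [TVMVARCoefficients-class] with identical dimensions.
#' @param mode "average_coefficients" or "average_pdc".
#' @param freqs frequency grid for mode "average_pdc" (default: 1 Hz steps
#'   from 0 to Nyquist).
#' @return a [TVMVARCoefficients-class] or [TFConnectivity-class].
#' @export
combineSingleTrial <- function(fits, mode = c("average_coefficients",
                                              "average_pdc"), freqs = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, is, TRUE, "TVMVARCoefficients")))
  dims <- lapply(fits, function(f) dim(coefArray(f)))
  if (!all(vapply(dims, identical, TRUE, dims[[1L]])))
    stop("per-trial fits have mixed dimensions")
  if (mode == "average_coefficients") {
    avg <- Reduce(`+`, lapply(fits, coefArray)) / length(fits)
    return(new("TVMVARCoefficients", coeffs = avg,
               samplingRate = samplingRate(fits[[1L]])))
  }
  conns <- lapply(fits, pdcSquared, freqs = freqs)
  pdc <- Reduce(`+`, lapply(conns, pdcArray)) / length(conns)
  spec <- Reduce(`+`, lapply(conns, spectralArray)) / length(conns)
  new("TFConnectivity", pdc = pdc, spectralMatrix = spec,
      freqs = frequencies(conns[[1L]]), times = timePoints(conns[[1L]]))
}
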