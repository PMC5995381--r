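#' Assemble a time-varying MVAR coefficient stack from coupling specs
#'
#' Builds the ground-truth coefficient array of a simulated network: each
#' [waveformSpec()] places its time course on one (receiver, sender, lag)
#' entry, every node carries a stable self-regression on the diagonal, and
#' every undeclared off-diagonal edge is exactly zero at all times and lags.
#'
#' @param specs list of [waveformSpec()] objects (may be empty).
#' @param d number of channels/nodes.
#' @param p model order (maximum lag).
#' @param N number of time points.
#' @param fs sampling rate in Hz.
#' @param selfCoef numeric vector of self-regression coefficients applied at
#'   lags 1..length(selfCoef) on every node's diagonal. The default,
#'   [dampedOscillator()] at 60 Hz with pole radius 0.75, gives each node a
#'   stationary rhythmic baseline that is highly one-step predictable yet
#'   decorrelates within a few samples, as in band-limited
#'   electrophysiological signals.
#'
#' @return a [TVMVARCoefficients-class] object.
#' @export
buildNetwork <- function(specs, d, p, N, fs, selfCoef = NULL) {
  d <- as.integer(d); p <- as.integer(p); N <- as.integer(N)
  if (is.null(selfCoef)) selfCoef <- dampedOscillator(fs)
  if (length(selfCoef) > p)
    stop("self-regression lags exceed the model order p")
  coeffs <- array(0, dim = c(N, p, d, d))
  for (i in seq_len(d)) for (r in seq_along(selfCoef))
    coeffs[, r, i, i] <- selfCoef[r]
  seen <- character(0)
  for (spec in specs) {
    if (!inherits(spec, "waveformSpec"))
      stop("specs must be a list of waveformSpec objects")
    if (spec$from < 1L || spec$from > d || spec$to < 1L || spec$to > d)
      stop(sprintf("edge %d->%d lies outside 1..%d", spec$from, spec$to, d))
    if (spec$lagSamples > p)
      stop(sprintf("lag %d samples of edge %d->%d exceeds model order %d",
                   spec$lagSamples, spec$from, spec$to, p))
    key <- paste(spec$to, spec$from, spec$lagSamples)
    if (key %in% seen)
      stop(sprintf("duplicate spec for edge %d->%d at lag %d",
                   spec$from, spec$to, spec$lagSamples))
    seen <- c(seen, key)
    coeffs[, spec$lagSamples, spec$to, spec$from] <- evalWaveform(spec, N, fs)
  }
  new("TVMVARCoefficients", coeffs = coeffs, samplingRate = fs)
}

#' Five-node benchmark network
#'
#' A 5-node acyclic network with four time-varying directed couplings at
#' lags of 1, 1, 2 and 3 samples, each following a Gaussian pulse at a
#' distinct latency, on top of stable self-regressions. With the defaults
#' (500 Hz, 1000 samples) the trial lasts 2 s. This is the network used by
#' the adaptation-coefficient sweeps.
#'
#' @param fs sampling rate in Hz.
#' @param N samples per trial.
#' @param p model order of the generating process (>= 3).
#' @param amplitude peak strength of each coupling.
#' @param selfCoef diagonal self-regression coefficient.
#' @return a [TVMVARCoefficients-class] object.
#' @export
fiveNodeNetwork <- function(fs = 500, N = 1000, p = 3L, amplitude = 0.4,
                            selfCoef = dampedOscillator(fs)) {
  dur <- N / fs
  specs <- list(
    waveformSpec(1, 2, 1L, "gaussian", amplitude = amplitude,
                 center = 0.25 * dur, width = 0.025 * dur),
    waveformSpec(1, 3, 1L, "gaussian", amplitude = amplitude,
                 center = 0.40 * dur, width = 0.025 * dur),
    waveformSpec(3, 4, 2L, "gaussian", amplitude = amplitude,
                 center = 0.55 * dur, width = 0.025 * dur),
    waveformSpec(4, 5, 3L, "gaussian", amplitude = amplitude,
                 center = 0.70 * dur, width = 0.025 * dur))
  buildNetwork(specs, d = 5L, p = p, N = N, fs = fs, selfCoef = selfCoef)
}

#' Two-node benchmark network
#'
#' A 2-node network with one directed coupling from node 1 to node 2, active
#' for `durationMs` around mid-trial (boxcar with raised-cosine ramps), at a
#' configurable lag. The generating order equals the coupling lag in samples.
#' With the defaults (1000 Hz, 1000 samples, 8 ms lag) this is the
#' order-selection test bed.
#'
#' @param fs sampling rate in Hz.
#' @param N samples per trial.
#' @param lagMs lag of the causal influence, milliseconds.
#' @param durationMs total active duration of the influence, milliseconds.
#' @param amplitude peak coupling strength.
#' @param selfCoef diagonal self-regression coefficient.
#' @return a [TVMVARCoefficients-class] object.
#' @export
twoNodeNetwork <- function(fs = 1000, N = 1000, lagMs = 8, durationMs = 250,
                           amplitude = 1, selfCoef = dampedOscillator(fs)) {
  lag <- as.integer(round(lagMs * fs / 1000))
  if (lag < 1L) stop("lagMs is below one sample at this sampling rate")
  dur <- durationMs / 1000
  onset <- (N / fs - dur) / 2
  spec <- waveformSpec(1, 2, lag, "boxcar", amplitude = amplitude,
                       onset = onset, duration = dur,
                       ramp = min(0.025, dur / 4))
  buildNetwork(list(spec), d = 2L, p = max(lag, length(selfCoef)), N = N,
               fs = fs, selfCoef = selfCoef)
}

#' Damped-oscillator self-regression coefficients
#'
#' AR(2) coefficients with complex poles at radius `radius` and frequency
#' `freqHz`, the standard rhythmic baseline of simulated neural nodes:
#' a1 = 2 r cos(2 pi f / fs), a2 = -r^2.
#'
#' @param fs sampling rate in Hz.
#' @param freqHz oscillation frequency in Hz.
#' @param radius pole radius in (0, 1); closer to 1 means a sharper, more
#'   predictable rhythm.
#' @return numeric vector c(a1, a2).
#' @export
dampedOscillator <- function(fs, freqHz = min(60, fs / 4), radius = 0.75) {
  stopifnot(radius > 0, radius < 1, freqHz >= 0, freqHz <= fs / 2)
  c(2 * radius * cos(2 * pi * freqHz / fs), -radius^2)
}

#' Edge partition of a generating network
#'
#' Derives the connected (any nonzero coefficient at any time/lag) and null
#' off-diagonal edge sets of a ground-truth coefficient stack, as used by the
#' miss / false-alarm metrics.
#'
#' @param model a [TVMVARCoefficients-class] generating model.
#' @return an [EdgePartition-class] object.
#' @export
edgePartition <- function(model) {
  d <- nChannels(model)
  cf <- coefArray(model)
  conn <- NULL; null <- NULL
  for (i in seq_len(d)) for (j in seq_len(d)) {
    if (i == j) next
    if (any(cf[, , i, j] != 0)) conn <- rbind(conn, c(i, j))
    else null <- rbind(null, c(i, j))
  }
  empty <- matrix(integer(0), 0, 2)
  new("EdgePartition",
      connectedEdges = if (is.null(conn)) empty else conn,
      nullEdges = if (is.null(null)) empty else null)
}
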