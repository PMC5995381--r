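#' Simulate trials from a time-varying MVAR model
#'
#' Iterates y(n) = sum_r A_r(n) y(n - r) + e(n) independently per trial with
#' zero-mean uncorrelated Gaussian innovations (identity covariance scaled by
#' `innovationSd`). Each trial starts from a burn-in segment generated under
#' the first coefficient matrix, whose first p samples are pure innovations;
#' the burn-in is discarded so trials begin near their stationary regime.
#'
#' @param model a [TVMVARCoefficients-class] generating model.
#' @param nTrials number of independent trials.
#' @param innovationSd innovation standard deviation (> 0).
#' @param seed optional integer seed; identical seeds give bit-identical
#'   output.
#' @param burnIn number of discarded warm-up samples (default 10 * p).
#'
#' @return a [TrialSet-class] of dimension nTrials x d x N.
#' @export
simulateTvMvar <- function(model, nTrials, innovationSd = 1, seed = NULL,
                           burnIn = NULL) {
  stopifnot(innovationSd > 0, nTrials >= 1)
  cf <- coefArray(model)
  N <- dim(cf)[1L]; p <- dim(cf)[2L]; d <- dim(cf)[3L]
  if (is.null(burnIn)) burnIn <- 10L * p
  burnIn <- max(as.integer(burnIn), p)
  if (!is.null(seed)) set.seed(seed)
  bound <- 1e6 * innovationSd

  # per-time-step d x dp matrices [A_1(n) A_2(n) ... A_p(n)], lag-major
  Alist <- vector("list", N)
  for (n in seq_len(N))
    Alist[[n]] <- matrix(aperm(cf[n, , , , drop = FALSE], c(3, 4, 2, 1)), d, d * p)
  A0 <- Alist[[1L]]

  Ntot <- burnIn + N
  out <- array(0, dim = c(nTrials, d, N))
  for (k in seq_len(nTrials)) {
    e <- matrix(stats::rnorm(d * Ntot, sd = innovationSd), d, Ntot)
    x <- matrix(0, d, Ntot)
    x[, seq_len(p)] <- e[, seq_len(p)]          # first p samples: innovations
    xlag <- as.vector(x[, p:1, drop = FALSE])   # (y(m-1); ...; y(m-p))
    for (m in (p + 1):Ntot) {
      A <- if (m > burnIn) Alist[[m - burnIn]] else A0
      xn <- drop(A %*% xlag) + e[, m]
      if (any(!is.finite(xn)) || any(abs(xn) > bound))
        stop(sprintf(
          "unstable coefficient path: sample exceeded the explosion bound at trial %d, time index %d",
          k, m - burnIn))
      x[, m] <- xn
      xlag <- c(xn, xlag[seq_len(d * (p - 1))])
    }
    out[k, , ] <- x[, (burnIn + 1):Ntot]
  }
  new("TrialSet", data = out, samplingRate = samplingRate(model),
      channelLabels = character(0))
}

#' Add white measurement noise at a fixed signal-to-noise ratio
#'
#' Adds uncorrelated Gaussian noise per channel with variance equal to the
#' channel's signal variance (computed across trials and samples) divided by
#' 10^(snrDb / 10) -- i.e. SNR is the ratio of signal variance to noise
#' variance. `snrDb = Inf` returns the input unchanged.
#'
#' @param trials a [TrialSet-class].
#' @param snrDb signal-to-noise ratio in dB.
#' @param seed optional integer seed.
#' @return a [TrialSet-class] with noise added.
#' @export
addMeasurementNoise <- function(trials, snrDb, seed = NULL) {
  stopifnot(is(trials, "TrialSet"))
  if (is.infinite(snrDb) && snrDb > 0) return(trials)
  stopifnot(is.finite(snrDb))
  if (!is.null(seed)) set.seed(seed)
  x <- trialArray(trials)
  d <- dim(x)[2L]
  for (ch in seq_len(d)) {
    v <- stats::var(as.vector(x[, ch, ]))
    if (v == 0)
      stop(sprintf("channel %d has zero variance; SNR is undefined", ch))
    x[, ch, ] <- x[, ch, ] +
      stats::rnorm(length(x[, ch, ]), sd = sqrt(v / 10^(snrDb / 10)))
  }
  initialize(trials, data = x)
}

#' Zero-phase antialiasing filter and decimation
#'
#' Low-pass filters each channel below the new Nyquist frequency with an
#' order-8 Chebyshev type-I filter (0.05 dB ripple, cutoff at 0.8 times the
#' new Nyquist) applied forward and backward (zero phase), then keeps every
#' q-th sample, where q = fs / targetFs must be an integer. A pulse's peak
#' therefore maps to the nearest decimated index. `targetFs` equal to the
#' current rate returns the input unchanged.
#'
#' @param trials a [TrialSet-class].
#' @param targetFs target sampling rate in Hz.
#' @return a decimated [TrialSet-class].
#' @export
antialiasDownsample <- function(trials, targetFs) {
  stopifnot(is(trials, "TrialSet"))
  fs <- samplingRate(trials)
  if (targetFs > fs)
    stop("upsampling is not supported: targetFs exceeds the sampling rate")
  if (targetFs == fs) return(trials)
  q <- fs / targetFs
  if (abs(q - round(q)) > 1e-9)
    stop("targetFs must divide the sampling rate (integer decimation only)")
  q <- as.integer(round(q))
  flt <- signal::cheby1(8, 0.05, 0.8 / q)   # cutoff relative to Nyquist
  x <- trialArray(trials)
  k <- dim(x)[1L]; d <- dim(x)[2L]; N <- dim(x)[3L]
  keep <- seq(1L, by = q, length.out = N %/% q)
  out <- array(0, dim = c(k, d, length(keep)))
  for (tr in seq_len(k)) for (ch in seq_len(d)) {
    y <- signal::filtfilt(flt, x[tr, ch, ])
    out[tr, ch, ] <- y[keep]
  }
  new("TrialSet", data = out, samplingRate = targetFs,
      channelLabels = channelLabels(trials))
}
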