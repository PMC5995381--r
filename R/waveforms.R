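#' Time course of a directed coupling
#'
#' Describes one time-varying off-diagonal coefficient of a simulated tvMVAR
#' network: which edge it sits on, at which lag, and how its strength evolves
#' over the trial. Three parametric families are available: a boxcar with
#' raised-cosine on/off ramps, a Gaussian pulse, and a piecewise-linear
#' breakpoint curve.
#'
#' @param from sender node index.
#' @param to receiver node index.
#' @param lagSamples autoregressive lag of the influence, in samples (>= 1).
#' @param shape "boxcar", "gaussian" or "piecewise".
#' @param amplitude peak coupling strength (boxcar/gaussian).
#' @param onset boxcar: start of the active period, seconds.
#' @param duration boxcar: total active duration including ramps, seconds.
#' @param ramp boxcar: raised-cosine ramp length at each end, seconds.
#' @param center gaussian: pulse center, seconds.
#' @param width gaussian: pulse standard deviation, seconds.
#' @param breakpoints piecewise: data.frame with columns time (s) and value;
#'   linearly interpolated, zero outside the breakpoint range.
#'
#' @return a `"waveformSpec"` object.
#' @export
waveformSpec <- function(from, to, lagSamples, shape = c("boxcar", "gaussian",
                                                         "piecewise"),
                         amplitude = 0.5, onset = 0, duration = 0.25,
                         ramp = 0.025, center = 0.5, width = 0.1,
                         breakpoints = NULL) {
  shape <- match.arg(shape)
  if (from == to)
    stop("waveformSpec describes off-diagonal couplings; from must differ from to")
  if (lagSamples < 1L)
    stop("lagSamples must be >= 1")
  if (shape == "piecewise") {
    if (is.null(breakpoints) || !all(c("time", "value") %in% names(breakpoints)))
      stop("piecewise shape needs breakpoints with columns time and value")
  }
  structure(list(from = as.integer(from), to = as.integer(to),
                 lagSamples = as.integer(lagSamples), shape = shape,
                 amplitude = amplitude, onset = onset, duration = duration,
                 ramp = ramp, center = center, width = width,
                 breakpoints = breakpoints),
            class = "waveformSpec")
}

#' Evaluate a coupling time course on a sample grid
#'
#' @param spec a [waveformSpec()].
#' @param N number of samples.
#' @param fs sampling rate in Hz.
#' @return numeric vector of length N.
#' @export
evalWaveform <- function(spec, N, fs) {
  tt <- (seq_len(N) - 1) / fs
  switch(spec$shape,
    boxcar = {
      on <- spec$onset; dur <- spec$duration
      rp <- min(spec$ramp, dur / 2)
      w <- numeric(N)
      act <- tt >= on & tt <= on + dur
      w[act] <- spec$amplitude
      if (rp > 0) {
        up <- tt >= on & tt < on + rp
        w[up] <- spec$amplitude * 0.5 * (1 - cos(pi * (tt[up] - on) / rp))
        dn <- tt > on + dur - rp & tt <= on + dur
        w[dn] <- spec$amplitude * 0.5 * (1 - cos(pi * (on + dur - tt[dn]) / rp))
      }
      w
    },
    gaussian = spec$amplitude * exp(-0.5 * ((tt - spec$center) / spec$width)^2),
    piecewise = {
      bp <- spec$breakpoints
      stats::approx(bp$time, bp$value, xout = tt, yleft = 0, yright = 0,
                    rule = 1, ties = "ordered")$y -> v
      v[is.na(v)] <- 0
      v
    })
}
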