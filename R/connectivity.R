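#' Time-resolved spectral coefficient matrix
#'
#' Evaluates the MVAR spectral representation
#' Abar(f, t) = I - sum_r A_r(t) exp(-i 2 pi f r / fs)
#' on a frequency grid for every time step of a coefficient trajectory.
#'
#' @param coeffs a [TVMVARCoefficients-class].
#' @param freqs frequencies in Hz within [0, Nyquist]; default: 1 Hz steps
#'   from 0 to Nyquist inclusive.
#' @return complex array (receiver, sender, frequency, time).
#' @export
spectralMatrix <- function(coeffs, freqs = NULL) {
  stopifnot(is(coeffs, "TVMVARCoefficients"))
  fs <- samplingRate(coeffs)
  if (is.null(freqs)) freqs <- seq(0, fs / 2, by = 1)
  if (!length(freqs)) stop("empty frequency grid")
  if (any(freqs < 0) || any(freqs > fs / 2))
    stop("frequencies must lie in [0, Nyquist]")
  cf <- coefArray(coeffs)
  N <- dim(cf)[1L]; p <- dim(cf)[2L]; d <- dim(cf)[3L]
  nf <- length(freqs)
  # phase factors exp(-i 2 pi f r / fs), lags x freqs
  ph <- exp(-2i * pi * outer(seq_len(p), freqs) / fs)
  # (N*d*d, p) %*% (p, F) in one multiply
  M <- matrix(aperm(cf, c(1, 3, 4, 2)), N * d * d, p)
  S <- -(M %*% ph)                               # (N*d*d, F)
  A <- array(S, dim = c(N, d, d, nf))
  for (i in seq_len(d)) A[, i, i, ] <- A[, i, i, ] + 1
  aperm(A, c(2, 3, 4, 1))                        # (d, d, F, N)
}

#' Squared inflow-normalized partial directed coherence
#'
#' Element-wise squared PDC:
#' PDC_ij(f, t) = |Abar_ij(f, t)|^2 / sum_m |Abar_im(f, t)|^2,
#' i.e. the information flow from sender j to receiver i normalized by the
#' total inflow to i, so every receiver row sums to one.
#'
#' @inheritParams spectralMatrix
#' @return a [TFConnectivity-class].
#' @export
pdcSquared <- function(coeffs, freqs = NULL) {
  fs <- samplingRate(coeffs)
  if (is.null(freqs)) freqs <- seq(0, fs / 2, by = 1)
  A <- spectralMatrix(coeffs, freqs)
  mag <- Mod(A)^2
  denom <- apply(mag, c(1, 3, 4), sum)           # (receiver, F, N)
  if (any(denom == 0)) {
    idx <- which(denom == 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "PDC undefined: zero total inflow for receiver %d at frequency %g Hz, time index %d",
      idx[1L], freqs[idx[2L]], idx[3L]))
  }
  d <- dim(mag)[1L]
  pdc <- mag / aperm(array(denom, dim = dim(mag)[c(1, 3, 4, 2)]),
                     c(1, 4, 2, 3))
  N <- dim(mag)[4L]
  new("TFConnectivity", pdc = pdc, spectralMatrix = A, freqs = freqs,
      times = (seq_len(N) - 1) / fs)
}

#' Band-averaged connectivity
#'
#' Mean of the squared PDC over all frequency bins inside the closed band
#' [fLo, fHi], per edge and time point.
#'
#' @param conn a [TFConnectivity-class].
#' @param fLo,fHi band edges in Hz (inclusive).
#' @return numeric array (receiver, sender, time).
#' @export
bandAverage <- function(conn, fLo, fHi) {
  stopifnot(is(conn, "TFConnectivity"))
  sel <- which(frequencies(conn) >= fLo & frequencies(conn) <= fHi)
  if (!length(sel))
    stop(sprintf("band [%g, %g] Hz contains no frequency bins", fLo, fHi))
  apply(pdcArray(conn)[, , sel, , drop = FALSE], c(1, 2, 4), mean)
}

#' Total driving (outflow) of a node
#'
#' Sum of all outgoing PDC values from `node` to every other node, per time
#' point (and per frequency unless a band-averaged array is supplied).
#' Diagonal (self) terms are excluded.
#'
#' @param x a [TFConnectivity-class] or a band-averaged array
#'   (receiver, sender, time) from [bandAverage()].
#' @param node sender node index.
#' @return numeric vector over time (band-averaged input) or a matrix
#'   frequency x time.
#' @export
totalDriving <- function(x, node) {
  if (is(x, "TFConnectivity")) x <- pdcArray(x)
  nd <- length(dim(x))
  stopifnot(nd %in% c(3L, 4L), node >= 1, node <= dim(x)[1L])
  recv <- setdiff(seq_len(dim(x)[1L]), node)
  if (nd == 3L) {
    out <- x[recv, node, , drop = FALSE]
    colSums(matrix(out, length(recv), dim(x)[3L]))
  } else {
    out <- x[recv, node, , , drop = FALSE]
    apply(array(out, dim = c(length(recv), dim(x)[3L], dim(x)[4L])),
          c(2, 3), sum)
  }
}
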