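#' @useDynLib tvmvar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Multi-trial multichannel time series
#'
#' Container for repeated realizations (trials) of a multichannel recording,
#' the raw material of every estimator in the package. The data array is
#' indexed (trial, channel, sample).
#'
#' @slot data numeric array of dimension trials x channels x samples.
#' @slot samplingRate sampling rate in Hz.
#' @slot channelLabels character vector of channel names (may be empty).
#'
#' @export
setClass("TrialSet",
  representation(data = "array", samplingRate = "numeric",
                 channelLabels = "character"))

setValidity("TrialSet", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L)
    return("data must be a 3-D array (trial x channel x sample)")
  if (d[1L] < 1L || d[2L] < 1L || d[3L] < 1L)
    return("all dimensions must be >= 1")
  if (!all(is.finite(object@data)))
    return("data contains non-finite values")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    return("samplingRate must be a single positive number")
  if (length(object@channelLabels) &&
      length(object@channelLabels) != d[2L])
    return("channelLabels length must match the number of channels")
  TRUE
})

#' Time-varying MVAR coefficient trajectories
#'
#' Stack of lag-coefficient matrices A_r(n) describing a time-varying
#' multivariate autoregression of order p over d channels:
#' y(n) = sum_r A_r(n) y(n - r) + e(n). The array is indexed
#' (time, lag, receiver, sender).
#'
#' @slot coeffs numeric array of dimension N x p x d x d.
#' @slot samplingRate sampling rate in Hz.
#'
#' @export
setClass("TVMVARCoefficients",
  representation(coeffs = "array", samplingRate = "numeric"))

setValidity("TVMVARCoefficients", function(object) {
  dm <- dim(object@coeffs)
  if (length(dm) != 4L)
    return("coeffs must be a 4-D array (time x lag x receiver x sender)")
  if (dm[3L] != dm[4L])
    return("receiver and sender dimensions must agree")
  if (dm[2L] < 1L) return("model order must be >= 1")
  if (dm[1L] < dm[2L] + 1L)
    return("need at least p + 1 time points")
  if (!all(is.finite(object@coeffs)))
    return("coeffs contains non-finite values")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    return("samplingRate must be a single positive number")
  TRUE
})

#' Estimator configuration
#'
#' Algorithm, trial strategy, model order and adaptation coefficient(s) for
#' a recursive tvMVAR fit. Adaptation coefficients must lie strictly between
#' 0 and 1; multi-trial modeling is only defined for RLS and GLKF.
#'
#' @slot algorithm one of "rls", "glkf", "mvaar", "dekf".
#' @slot strategy "single_trial" or "multi_trial".
#' @slot orderP integer model order (number of lags).
#' @slot adaptation one or two scalars in (0, 1): forgetting factor (RLS),
#'   c1 and c2 (GLKF/MVAAR), update coefficient (DEKF).
#' @slot combineMode single-trial combination: "average_coefficients" or
#'   "average_pdc".
#'
#' @export
setClass("EstimatorConfig",
  representation(algorithm = "character", strategy = "character",
                 orderP = "integer", adaptation = "numeric",
                 combineMode = "character"))

setValidity("EstimatorConfig", function(object) {
  if (!object@algorithm %in% c("rls", "glkf", "mvaar", "dekf"))
    return("algorithm must be one of rls, glkf, mvaar, dekf")
  if (!object@strategy %in% c("single_trial", "multi_trial"))
    return("strategy must be single_trial or multi_trial")
  if (object@strategy == "multi_trial" &&
      !object@algorithm %in% c("rls", "glkf"))
    return("multi-trial modeling is only available for RLS and GLKF")
  if (object@orderP < 1L) return("orderP must be >= 1")
  if (!length(object@adaptation) %in% 1:2)
    return("adaptation must contain one or two coefficients")
  if (any(!is.finite(object@adaptation)) ||
      any(object@adaptation <= 0) || any(object@adaptation >= 1))
    return("adaptation coefficients must lie strictly between 0 and 1")
  if (!object@combineMode %in% c("average_coefficients", "average_pdc"))
    return("combineMode must be average_coefficients or average_pdc")
  TRUE
})

#' Time-frequency directed connectivity
#'
#' Squared inflow-normalized partial directed coherence on a time-frequency
#' grid, together with the complex spectral coefficient matrix it derives
#' from. The pdc array is indexed (receiver, sender, frequency, time) and
#' every receiver row sums to one over senders.
#'
#' @slot pdc numeric array d x d x F x N in [0, 1].
#' @slot spectralMatrix complex array d x d x F x N.
#' @slot freqs frequency grid in Hz.
#' @slot times time axis in seconds.
#'
#' @export
setClass("TFConnectivity",
  representation(pdc = "array", spectralMatrix = "array",
                 freqs = "numeric", times = "numeric"))

setValidity("TFConnectivity", function(object) {
  dm <- dim(object@pdc)
  if (length(dm) != 4L || dm[1L] != dm[2L])
    return("pdc must be a 4-D array (receiver x sender x frequency x time)")
  if (!identical(dim(object@spectralMatrix), dm))
    return("spectralMatrix dimensions must match pdc")
  if (length(object@freqs) != dm[3L])
    return("freqs length must match the frequency dimension")
  if (length(object@times) != dm[4L])
    return("times length must match the time dimension")
  if (any(object@pdc < -1e-12) || any(object@pdc > 1 + 1e-12))
    return("pdc values must lie in [0, 1]")
  rs <- apply(object@pdc, c(1L, 3L, 4L), sum)
  if (max(abs(rs - 1)) > 1e-10)
    return("pdc receiver rows must sum to 1 (within 1e-10)")
  TRUE
})

#' Connected / null edge partition
#'
#' Off-diagonal edges with and without a simulated connection, used by the
#' miss and false-alarm accuracy metrics. Edges are (receiver, sender) pairs.
#'
#' @slot connectedEdges integer matrix, one (receiver, sender) row per edge.
#' @slot nullEdges integer matrix, one (receiver, sender) row per edge.
#'
#' @export
setClass("EdgePartition",
  representation(connectedEdges = "matrix", nullEdges = "matrix"))

setValidity("EdgePartition", function(object) {
  for (nm in c("connectedEdges", "nullEdges")) {
    m <- slot(object, nm)
    if (ncol(m) != 2L) return(sprintf("%s must have two columns", nm))
    if (nrow(m) && any(m[, 1L] == m[, 2L]))
      return(sprintf("%s must not contain diagonal entries", nm))
  }
  key <- function(m) paste(m[, 1L], m[, 2L])
  if (length(intersect(key(object@connectedEdges), key(object@nullEdges))))
    return("connected and null edge sets must be disjoint")
  TRUE
})
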