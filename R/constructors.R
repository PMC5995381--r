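#' Construct a TrialSet
#'
#' @param data numeric array trials x channels x samples.
#' @param samplingRate sampling rate in Hz.
#' @param channelLabels optional channel names.
#' @return a [TrialSet-class].
#' @export
trialSet <- function(data, samplingRate, channelLabels = character(0)) {
  new("TrialSet", data = data, samplingRate = samplingRate,
      channelLabels = as.character(channelLabels))
}

#' Construct a TVMVARCoefficients object
#'
#' @param coeffs numeric array time x lag x receiver x sender.
#' @param samplingRate sampling rate in Hz.
#' @return a [TVMVARCoefficients-class].
#' @export
tvmvarCoefficients <- function(coeffs, samplingRate) {
  new("TVMVARCoefficients", coeffs = coeffs, samplingRate = samplingRate)
}
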