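#' Accessor generics
#'
#' Small accessor family shared by the package classes: sampling rate,
#' dimensions, and the underlying arrays.
#'
#' @param object a package object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setGeneric("modelOrder", function(object) standardGeneric("modelOrder"))
#' @rdname accessors
#' @export
setGeneric("trialArray", function(object) standardGeneric("trialArray"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("coefArray", function(object) standardGeneric("coefArray"))
#' @rdname accessors
#' @export
setGeneric("pdcArray", function(object) standardGeneric("pdcArray"))
#' @rdname accessors
#' @export
setGeneric("spectralArray", function(object) standardGeneric("spectralArray"))
#' @rdname accessors
#' @export
setGeneric("frequencies", function(object) standardGeneric("frequencies"))
#' @rdname accessors
#' @export
setGeneric("timePoints", function(object) standardGeneric("timePoints"))

## ---- TrialSet ----

#' @rdname accessors
setMethod("samplingRate", "TrialSet", function(object) object@samplingRate)
#' @rdname accessors
setMethod("nTrials", "TrialSet", function(object) dim(object@data)[1L])
#' @rdname accessors
setMethod("nChannels", "TrialSet", function(object) dim(object@data)[2L])
#' @rdname accessors
setMethod("nSamples", "TrialSet", function(object) dim(object@data)[3L])
#' @rdname accessors
setMethod("trialArray", "TrialSet", function(object) object@data)
#' @rdname accessors
setMethod("channelLabels", "TrialSet", function(object) object@channelLabels)

setMethod("show", "TrialSet", function(object) {
  cat(sprintf("TrialSet: %d trial(s) x %d channel(s) x %d sample(s) at %g Hz\n",
              nTrials(object), nChannels(object), nSamples(object),
              samplingRate(object)))
  if (length(object@channelLabels))
    cat("  channels:", paste(object@channelLabels, collapse = ", "), "\n")
})

## ---- TVMVARCoefficients ----

#' @rdname accessors
setMethod("samplingRate", "TVMVARCoefficients",
          function(object) object@samplingRate)
#' @rdname accessors
setMethod("nChannels", "TVMVARCoefficients",
          function(object) dim(object@coeffs)[3L])
#' @rdname accessors
setMethod("nSamples", "TVMVARCoefficients",
          function(object) dim(object@coeffs)[1L])
#' @rdname accessors
setMethod("modelOrder", "TVMVARCoefficients",
          function(object) dim(object@coeffs)[2L])
#' @rdname accessors
setMethod("coefArray", "TVMVARCoefficients", function(object) object@coeffs)

setMethod("show", "TVMVARCoefficients", function(object) {
  cat(sprintf(
    "TVMVARCoefficients: %d channel(s), order %d, %d time point(s) at %g Hz\n",
    nChannels(object), modelOrder(object), nSamples(object),
    samplingRate(object)))
})

## ---- TFConnectivity ----

#' @rdname accessors
setMethod("nChannels", "TFConnectivity", function(object) dim(object@pdc)[1L])
#' @rdname accessors
setMethod("pdcArray", "TFConnectivity", function(object) object@pdc)
#' @rdname accessors
setMethod("spectralArray", "TFConnectivity",
          function(object) object@spectralMatrix)
#' @rdname accessors
setMethod("frequencies", "TFConnectivity", function(object) object@freqs)
#' @rdname accessors
setMethod("timePoints", "TFConnectivity", function(object) object@times)

setMethod("show", "TFConnectivity", function(object) {
  f <- object@freqs; tt <- object@times
  cat(sprintf(
    "TFConnectivity: %d x %d edges, %d frequencies (%g-%g Hz), %d time points\n",
    nChannels(object), nChannels(object), length(f), min(f), max(f),
    length(tt)))
})

## ---- EstimatorConfig ----

#' @rdname accessors
setMethod("modelOrder", "EstimatorConfig", function(object) object@orderP)

setMethod("show", "EstimatorConfig", function(object) {
  cat(sprintf("EstimatorConfig: %s (%s), order %d, adaptation %s\n",
              toupper(object@algorithm),
              if (object@strategy == "multi_trial") "MT" else "ST",
              object@orderP,
              paste(signif(object@adaptation, 4), collapse = "/")))
})

setMethod("show", "EdgePartition", function(object) {
  cat(sprintf("EdgePartition: %d connected, %d null edge(s)\n",
              nrow(object@connectedEdges), nrow(object@nullEdges)))
})
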