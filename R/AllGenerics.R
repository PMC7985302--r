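## Generic accessors shared by the containers.

#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @export
setGeneric("recordingData", function(x) standardGeneric("recordingData"))
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))
#' @export
setGeneric("freqResolution", function(x) standardGeneric("freqResolution"))
#' @export
setGeneric("incrementSamples",
           function(x, channel, frequency) standardGeneric("incrementSamples"))
#' @export
setGeneric("couplingValue", function(x) standardGeneric("couplingValue"))
#' @export
setGeneric("bootstrapTrace", function(x) standardGeneric("bootstrapTrace"))
#' @export
setGeneric("estimatorName", function(x) standardGeneric("estimatorName"))
#' @export
setGeneric("miTerms", function(x) standardGeneric("miTerms"))
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @export
setGeneric("graphPairs", function(x) standardGeneric("graphPairs"))
#' @export
setGeneric("graphThreshold", function(x) standardGeneric("graphThreshold"))

#' Sample spectral increments from windows of a recording
#'
#' @param x a [MultiChannelRecording-class] or [TrialSet-class].
#' @param windowLength window length in seconds (for a TrialSet the trial
#'   duration is used and this argument must agree with it if supplied).
#' @param frequencies frequencies in Hz; each must be an exact DFT bin.
#' @param demean remove each window's mean before the FFT (affects the 0 Hz
#'   bin only); default FALSE.
#' @return A [SpectralSampleSet-class].
#' @export
setGeneric("sampleIncrements",
           function(x, windowLength, frequencies, demean = FALSE)
             standardGeneric("sampleIncrements"))

## -- accessors ---------------------------------------------------------------

setMethod("nChannels", "MultiChannelRecording", function(x) nrow(x@data))
setMethod("channelNames", "MultiChannelRecording", function(x) x@channelNames)
setMethod("samplingRate", "MultiChannelRecording", function(x) x@fs)
setMethod("nSamples", "MultiChannelRecording", function(x) ncol(x@data))
setMethod("recordingData", "MultiChannelRecording", function(x) x@data)

setMethod("nChannels", "TrialSet", function(x) dim(x@data)[2L])
setMethod("channelNames", "TrialSet", function(x) x@channelNames)
setMethod("samplingRate", "TrialSet", function(x) x@fs)
setMethod("nSamples", "TrialSet", function(x) dim(x@data)[3L])
setMethod("nTrials", "TrialSet", function(x) dim(x@data)[1L])
setMethod("recordingData", "TrialSet", function(x) x@data)

setMethod("nWindows", "SpectralSampleSet", function(x) x@nWindows)
setMethod("freqResolution", "SpectralSampleSet", function(x) x@freqResolution)
setMethod("channelNames", "SpectralSampleSet", function(x) x@channels)
setMethod("incrementSamples", "SpectralSampleSet", function(x, channel, frequency) {
  key <- .incKey(channel, frequency)
  if (!key %in% names(x@samples))
    stop("no stored samples for ", key, call. = FALSE)
  x@samples[[key]]
})

setMethod("couplingValue", "CouplingEstimate", function(x) x@value)
setMethod("bootstrapTrace", "CouplingEstimate", function(x) x@iterations)
setMethod("estimatorName", "CouplingEstimate", function(x) x@estimator)
setMethod("miTerms", "CouplingEstimate", function(x) x@terms)

setMethod("graphPairs", "PGCGraph", function(x) x@pairs)
setMethod("graphThreshold", "PGCGraph", function(x) x@tau)
setMethod("graphEdges", "PGCGraph", function(x) {
  p <- x@pairs
  p[p$ok & p$pgc > p$tau, c("from", "to", "pgc", "mif", "tau"), drop = FALSE]
})

## -- show methods ------------------------------------------------------------

setMethod("show", "MultiChannelRecording", function(object) {
  cat(sprintf("MultiChannelRecording: %d channel(s) x %d samples @ %g Hz (%.4g s)\n",
              nChannels(object), nSamples(object), object@fs,
              nSamples(object) / object@fs))
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
})

setMethod("show", "TrialSet", function(object) {
  cat(sprintf("TrialSet: %d trial(s) x %d channel(s) x %d samples @ %g Hz\n",
              nTrials(object), nChannels(object), nSamples(object), object@fs))
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
})

setMethod("show", "SpectralSampleSet", function(object) {
  cat(sprintf("SpectralSampleSet: %d window(s) of %g s (resolution %g Hz)\n",
              object@nWindows, object@windowLength, object@freqResolution))
  for (ch in object@channels)
    cat(sprintf("  %s: %s Hz\n", ch,
                paste(object@frequencies[[ch]], collapse = ", ")))
})

setMethod("show", "CouplingEstimate", function(object) {
  cat(sprintf("CouplingEstimate [%s]: %.4f nats", object@estimator,
              object@value))
  if (length(object@iterations) > 1L)
    cat(sprintf(" (%d bootstrap iterations, sd %.4f)",
                length(object@iterations), sd(object@iterations)))
  cat("\n")
  if (length(object@terms))
    cat("  terms:", paste(sprintf("%s = %.4f", names(object@terms),
                                  object@terms), collapse = ", "), "\n")
})

setMethod("show", "PGCGraph", function(object) {
  e <- graphEdges(object)
  cat(sprintf("PGCGraph: %d vertices, %d edge(s) (tau = %.4g nats)\n",
              length(object@vertices), nrow(e), object@tau))
  if (nrow(e))
    for (i in seq_len(nrow(e)))
      cat(sprintf("  %s -- %s  (PGC %.4f, MIF %.4f)\n", e$from[i], e$to[i],
                  e$pgc[i], e$mif[i]))
})
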