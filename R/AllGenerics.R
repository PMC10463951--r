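#' @include AllClasses.R
NULL

#' @export
setGeneric("voltages", function(x) standardGeneric("voltages"))

#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @export
setGeneric("channelIds", function(x) standardGeneric("channelIds"))

#' @export
setGeneric("recordingDuration", function(x) standardGeneric("recordingDuration"))

#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))

#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))

#' @export
setGeneric("traceRatios", function(x) standardGeneric("traceRatios"))

#' @export
setGeneric("neuronInfo", function(x) standardGeneric("neuronInfo"))

#' @export
setGeneric("visits", function(x) standardGeneric("visits"))

#' @export
setGeneric("schedule", function(x) standardGeneric("schedule"))

#' @export
setGeneric("cornerAssignments", function(x) standardGeneric("cornerAssignments"))

#' @export
setGeneric("lightsOn", function(x) standardGeneric("lightsOn"))

#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @export
setGeneric("normalizeToBaseline",
           function(x, ...) standardGeneric("normalizeToBaseline"))

#' @export
setGeneric("summarizeSlice", function(x, ...) standardGeneric("summarizeSlice"))

#' @export
setGeneric("callPeaks", function(x, ...) standardGeneric("callPeaks"))
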