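#' @describeIn MEARecording-class channels x samples voltage matrix.
#' @param x object.
#' @export
setMethod("voltages", "MEARecording", function(x) x@voltages)

#' @describeIn MEARecording-class sampling rate in Hz.
#' @export
setMethod("samplingRate", "MEARecording", function(x) x@samplingRate)

#' @describeIn MEARecording-class channel labels.
#' @export
setMethod("channelIds", "MEARecording", function(x) x@channelIds)

#' @describeIn MEARecording-class trace duration in seconds.
#' @export
setMethod("recordingDuration", "MEARecording",
          function(x) ncol(x@voltages) / x@samplingRate)

#' @describeIn SpikeTrain-class event times in seconds.
#' @param x object.
#' @export
setMethod("spikeTimes", "SpikeTrain", function(x) x@spikeTimes)

#' @describeIn CalciumTraceSet-class time grid (seconds).
#' @param x object.
#' @export
setMethod("traceTimes", "CalciumTraceSet", function(x) x@times)

#' @describeIn CalciumTraceSet-class time x neuron ratio matrix.
#' @export
setMethod("traceRatios", "CalciumTraceSet", function(x) x@ratios)

#' @describeIn CalciumTraceSet-class per-neuron metadata.
#' @export
setMethod("neuronInfo", "CalciumTraceSet", function(x) x@neuronInfo)

#' @describeIn IntelliCageExperiment-class visit table.
#' @param x object.
#' @export
setMethod("visits", "IntelliCageExperiment", function(x) x@visits)

#' @describeIn IntelliCageExperiment-class task schedule.
#' @export
setMethod("schedule", "IntelliCageExperiment", function(x) x@schedule)

#' @describeIn IntelliCageExperiment-class per-animal corner assignments.
#' @export
setMethod("cornerAssignments", "IntelliCageExperiment",
          function(x) x@assignments)

#' @describeIn IntelliCageExperiment-class lights-on offset (seconds).
#' @export
setMethod("lightsOn", "IntelliCageExperiment", function(x) x@lightsOn)

#' @describeIn LipidTable-class samples x species intensity matrix.
#' @param x object.
#' @export
setMethod("intensities", "LipidTable",
          function(x) t(SummarizedExperiment::assay(x, "intensity")))

#' @describeIn LipidTable-class group label per sample.
#' @export
setMethod("sampleGroups", "LipidTable",
          function(x) SummarizedExperiment::colData(x)$group)

setMethod("show", "MEARecording", function(object) {
  cat(sprintf(
    "MEARecording: %d channels x %d samples (%.1f s at %g kHz), slice '%s', group '%s'\n",
    nrow(object@voltages), ncol(object@voltages),
    ncol(object@voltages) / object@samplingRate,
    object@samplingRate / 1000, object@sliceId, object@group))
})

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf(
    "SpikeTrain '%s': %d events in %.1f s (%.3f Hz), threshold %.3g (noise SD %.3g)\n",
    object@channelId, length(object@spikeTimes), object@duration,
    length(object@spikeTimes) / object@duration,
    object@thresholdUsed, object@noiseSd))
})

setMethod("show", "CalciumTraceSet", function(object) {
  cat(sprintf(
    "CalciumTraceSet: %d neurons x %d time points (%.0f-%.0f s, step %.3g s)\n",
    ncol(object@ratios), length(object@times),
    min(object@times), max(object@times),
    if (length(object@times) > 1L) object@times[2L] - object@times[1L] else NA))
  grp <- table(object@neuronInfo$group)
  cat("  groups:", paste(sprintf("%s (%d)", names(grp), grp), collapse = ", "),
      "\n")
})

setMethod("show", "IntelliCageExperiment", function(object) {
  v <- object@visits
  cat(sprintf(
    "IntelliCageExperiment: %d visits, %d animals, %d task segments (%s)\n",
    nrow(v), length(unique(v$animal_id)), nrow(object@schedule),
    paste(object@schedule$task, collapse = " -> ")))
})

setMethod("show", "LipidTable", function(object) {
  g <- table(sampleGroups(object))
  cat(sprintf("LipidTable: %d species x %d samples; groups: %s\n",
              nrow(object), ncol(object),
              paste(sprintf("%s (%d)", names(g), g), collapse = ", ")))
})
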