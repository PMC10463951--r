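#' Multi-electrode-array recording
#'
#' Container for a multichannel extracellular voltage recording: a channels x
#' samples matrix plus the sampling rate and channel labels. This is the raw
#' substrate of threshold-based multi-unit-activity (MUA) detection; the
#' emulated acquisition regime is a 60-electrode chip sampled at 50 kHz for
#' 5-minute traces.
#'
#' @slot voltages numeric matrix, channels x samples (volt-equivalent units).
#' @slot samplingRate sampling rate in Hz.
#' @slot channelIds character vector of channel labels, one per row.
#' @slot sliceId identifier of the recorded slice (metadata).
#' @slot group experimental group label (metadata).
#'
#' @seealso [MEARecording()] for the constructor, [summarizeSlice()] for the
#'   per-slice analysis entry point.
#' @export
setClass("MEARecording",
  slots = c(
    voltages = "matrix",
    samplingRate = "numeric",
    channelIds = "character",
    sliceId = "character",
    group = "character"
  )
)

setValidity("MEARecording", function(object) {
  v <- object@voltages
  if (!is.numeric(v) || nrow(v) < 1L || ncol(v) < 1L)
    return("voltages must be a non-empty numeric matrix (channels x samples)")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    return("samplingRate must be a single positive number")
  if (length(object@channelIds) != nrow(v))
    return("channelIds must have one label per voltage row")
  TRUE
})

#' Construct an MEARecording
#'
#' @param voltages channels x samples numeric matrix.
#' @param samplingRate sampling rate in Hz.
#' @param channelIds channel labels; defaults to `ch01, ch02, ...`.
#' @param sliceId,group optional metadata labels.
#' @return an [MEARecording-class] object.
#' @export
MEARecording <- function(voltages, samplingRate,
                         channelIds = sprintf("ch%02d", seq_len(nrow(voltages))),
                         sliceId = "slice1", group = "unknown") {
  if (is.null(dim(voltages))) voltages <- matrix(voltages, nrow = 1L)
  methods::new("MEARecording", voltages = voltages,
               samplingRate = as.numeric(samplingRate),
               channelIds = as.character(channelIds),
               sliceId = as.character(sliceId), group = as.character(group))
}

#' Detected spike train for one channel
#'
#' Times of threshold-crossing events (|x| > k * noise SD) on one electrode,
#' together with the threshold actually applied and the robust noise estimate
#' it was derived from.
#'
#' @slot channelId channel label.
#' @slot spikeTimes event times in seconds, strictly increasing.
#' @slot thresholdUsed absolute detection threshold (volt-equivalent).
#' @slot noiseSd robust noise SD estimate the threshold was based on.
#' @slot duration trace duration in seconds.
#' @export
setClass("SpikeTrain",
  slots = c(
    channelId = "character",
    spikeTimes = "numeric",
    thresholdUsed = "numeric",
    noiseSd = "numeric",
    duration = "numeric"
  )
)

setValidity("SpikeTrain", function(object) {
  st <- object@spikeTimes
  if (length(st) && (any(st < 0) || any(st > object@duration)))
    return("spikeTimes must lie within [0, duration]")
  if (length(st) > 1L && any(diff(st) <= 0))
    return("spikeTimes must be strictly increasing")
  if (object@duration <= 0) return("duration must be positive")
  TRUE
})

#' Collection of ratiometric calcium traces
#'
#' F340/380 ratio time series for a set of neurons on a shared uniform time
#' grid (default 2 s steps), with per-neuron metadata. The standard protocol
#' window layout is: baseline 0-200 s, capsaicin 200-220 s, KCl 780-825 s.
#'
#' @slot times time grid in seconds, strictly increasing.
#' @slot ratios numeric matrix, time points x neurons, all values > 0.
#' @slot neuronInfo data.frame with one row per neuron (columns `neuron_id`,
#'   `animal_id`, `group`).
#' @export
setClass("CalciumTraceSet",
  slots = c(
    times = "numeric",
    ratios = "matrix",
    neuronInfo = "data.frame"
  )
)

setValidity("CalciumTraceSet", function(object) {
  if (length(object@times) != nrow(object@ratios))
    return("length(times) must equal nrow(ratios)")
  if (any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (any(object@ratios <= 0))
    return("ratios must be positive (F340/380 is a ratio of fluorescences)")
  if (nrow(object@neuronInfo) != ncol(object@ratios))
    return("neuronInfo must have one row per trace column")
  TRUE
})

#' Construct a CalciumTraceSet
#'
#' @param times time grid (seconds).
#' @param ratios time x neuron matrix of F340/380 ratios.
#' @param neuronInfo data.frame with columns `neuron_id`, `animal_id`, `group`;
#'   defaults are generated.
#' @return a [CalciumTraceSet-class] object.
#' @export
CalciumTraceSet <- function(times, ratios, neuronInfo = NULL) {
  if (is.null(dim(ratios))) ratios <- matrix(ratios, ncol = 1L)
  if (is.null(neuronInfo)) {
    neuronInfo <- data.frame(
      neuron_id = sprintf("n%03d", seq_len(ncol(ratios))),
      animal_id = "a1", group = "unknown", stringsAsFactors = FALSE)
  }
  methods::new("CalciumTraceSet", times = as.numeric(times), ratios = ratios,
               neuronInfo = neuronInfo)
}

#' IntelliCage experiment: visit stream plus task schedule
#'
#' Ordered corner-visit events for a cohort of animals together with the task
#' schedule (free adaptation FA, nosepoke adaptation NP3c, place preference
#' learning PPL and its reversal PPLrev) and per-animal corner assignments.
#' Times are seconds from the lights-on anchor at the start of observation;
#' the light cycle is 12 h day / 12 h night.
#'
#' The visit table has one row per corner visit with columns `animal_id`,
#' `group`, `corner` (1-4), `start`, `end` (seconds), `np_count`,
#' `np_correct_count`, `first_np_s` (latency from visit start to first
#' nosepoke, NA if none), `door_opened`, `lick_count`, `lick_duration_s`,
#' `task`, `day` (1-based observation day).
#'
#' @slot visits data.frame of visit records, sorted by animal then start time.
#' @slot schedule data.frame with columns `task`, `start`, `end` (seconds),
#'   contiguous and non-overlapping.
#' @slot assignments data.frame with columns `animal_id`, `group`,
#'   `ppl_corner` (the rewarded corner in PPL; the PPLrev corner is the
#'   opposite-side corner).
#' @slot lightsOn offset of lights-on within the day, seconds (default 0:
#'   t = 0 is lights-on).
#' @export
setClass("IntelliCageExperiment",
  slots = c(
    visits = "data.frame",
    schedule = "data.frame",
    assignments = "data.frame",
    lightsOn = "numeric"
  )
)

setValidity("IntelliCageExperiment", function(object) {
  v <- object@visits
  need <- c("animal_id", "corner", "start", "end")
  if (!all(need %in% names(v)))
    return(paste("visits must contain columns:", paste(need, collapse = ", ")))
  if (nrow(v)) {
    if (any(v$end <= v$start)) return("every visit must have end > start")
    if (!all(v$corner %in% 1:4)) return("corner must be in 1..4")
    for (a in unique(v$animal_id)) {
      va <- v[v$animal_id == a, , drop = FALSE]
      va <- va[order(va$start), , drop = FALSE]
      if (nrow(va) > 1L && any(va$start[-1L] < va$end[-nrow(va)]))
        return(sprintf("overlapping visits for animal %s", a))
    }
  }
  s <- object@schedule
  if (!nrow(s)) return("schedule must contain at least one task segment")
  if (any(s$end <= s$start)) return("schedule segments must have end > start")
  TRUE
})

#' Construct an IntelliCageExperiment
#'
#' @param visits visit data.frame (see [IntelliCageExperiment-class]).
#' @param schedule task schedule data.frame (`task`, `start`, `end` seconds).
#' @param assignments per-animal corner assignment data.frame; if NULL a
#'   round-robin assignment over corners 1-4 is generated.
#' @param lightsOn lights-on offset within the day, seconds.
#' @return an [IntelliCageExperiment-class] object.
#' @export
IntelliCageExperiment <- function(visits, schedule, assignments = NULL,
                                  lightsOn = 0) {
  visits <- visits[order(visits$animal_id, visits$start), , drop = FALSE]
  rownames(visits) <- NULL
  if (is.null(assignments)) {
    ids <- unique(visits$animal_id)
    grp <- if ("group" %in% names(visits))
      visits$group[match(ids, visits$animal_id)] else rep("unknown", length(ids))
    assignments <- data.frame(animal_id = ids, group = grp,
                              ppl_corner = rep_len(1:4, length(ids)),
                              stringsAsFactors = FALSE)
  }
  methods::new("IntelliCageExperiment", visits = visits, schedule = schedule,
               assignments = assignments, lightsOn = as.numeric(lightsOn))
}

#' Lipid feature table
#'
#' Samples x lipid-species intensity table (area ratios to class internal
#' standards, AUC/IS) with a two-level group factor, stored as a
#' SummarizedExperiment (species as rows, samples as columns, group in
#' `colData`). Feeds the volcano screening stage.
#'
#' @export
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
setClass("LipidTable", contains = "SummarizedExperiment")

setValidity("LipidTable", function(object) {
  m <- SummarizedExperiment::assay(object, "intensity")
  if (any(m <= 0)) return("intensities must be strictly positive")
  if (!"group" %in% names(SummarizedExperiment::colData(object)))
    return("colData must contain a 'group' column")
  g <- SummarizedExperiment::colData(object)$group
  if (length(unique(g)) != 2L)
    return("group labels must cover exactly 2 groups")
  TRUE
})

#' Construct a LipidTable
#'
#' @param intensities samples x species numeric matrix of AUC/IS area ratios
#'   (rows are samples; transposed internally to the species x sample layout).
#' @param groups group label per sample (exactly two distinct levels).
#' @param species species names; defaults to the matrix column names.
#' @return a [LipidTable-class] object.
#' @export
LipidTable <- function(intensities, groups, species = colnames(intensities)) {
  if (is.null(species))
    species <- sprintf("L%03d", seq_len(ncol(intensities)))
  m <- t(intensities)
  rownames(m) <- species
  if (is.null(colnames(m)))
    colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = m),
    colData = S4Vectors::DataFrame(group = as.character(groups)))
  methods::new("LipidTable", se)
}
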