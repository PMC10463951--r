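#' Causal Butterworth highpass filter
#'
#' Second-order Butterworth highpass (default 200 Hz cutoff), applied as a
#' causal single pass to mimic online acquisition-software preprocessing. A
#' zero-phase variant (forward-backward) is available behind `zeroPhase`.
#'
#' @param trace numeric sample vector.
#' @param samplingRate sampling rate in Hz.
#' @param cutoff highpass cutoff in Hz (must be below Nyquist).
#' @param order filter order.
#' @param zeroPhase if TRUE use forward-backward filtering (no phase lag).
#' @return filtered numeric vector, same length as the input.
#' @export
highpassFilter <- function(trace, samplingRate, cutoff = 200, order = 2,
                           zeroPhase = FALSE) {
  .stopIf(cutoff >= samplingRate / 2,
          "cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
          cutoff, samplingRate / 2)
  .stopIf(cutoff <= 0 || order < 1, "cutoff and order must be positive")
  bf <- signal::butter(order, cutoff / (samplingRate / 2), type = "high")
  out <- if (zeroPhase) signal::filtfilt(bf, trace)
         else signal::filter(bf, trace)
  as.numeric(out)
}

#' Robust noise SD estimate
#'
#' Median-absolute-deviation estimator `median(|x|) / 0.6745`, consistent for
#' the SD of zero-mean Gaussian noise and robust to the large-amplitude spikes
#' whose detection threshold it calibrates (a plain SD would be inflated by
#' the very events being detected).
#'
#' @param filtered highpass-filtered sample vector (zero-mean).
#' @return noise SD estimate (0 for an all-zero trace).
#' @export
estimateNoiseSd <- function(filtered) {
  .stopIf(length(filtered) < 1000,
          "need at least 1000 samples for a stable noise estimate")
  stats::median(abs(filtered)) / 0.6745
}

#' Threshold-crossing spike detection
#'
#' Events are excursions where `|x|` exceeds `thresholdMultiple` times the
#' robust noise SD (default the fivefold-SD rule). Crossings separated by
#' less than `deadTime` are merged into one event; the event time is the
#' sample of largest absolute deflection within the excursion. Both
#' polarities are detected.
#'
#' @param filtered highpass-filtered sample vector.
#' @param samplingRate sampling rate in Hz.
#' @param thresholdMultiple threshold in noise-SD units.
#' @param deadTime minimum separation between events, seconds.
#' @param noiseSd noise SD; estimated with [estimateNoiseSd()] when NULL.
#' @param channelId label carried into the returned [SpikeTrain-class].
#' @return a [SpikeTrain-class].
#' @export
detectSpikes <- function(filtered, samplingRate, thresholdMultiple = 5,
                         deadTime = 0.001, noiseSd = NULL, channelId = "ch") {
  .stopIf(thresholdMultiple <= 0, "thresholdMultiple must be positive")
  if (is.null(noiseSd)) noiseSd <- estimateNoiseSd(filtered)
  .stopIf(noiseSd <= 0,
          "degenerate threshold: noise SD is %g (flat or all-zero trace)",
          noiseSd)
  thr <- thresholdMultiple * noiseSd
  duration <- length(filtered) / samplingRate
  idx <- which(abs(filtered) > thr)
  if (!length(idx)) {
    return(methods::new("SpikeTrain", channelId = channelId,
                        spikeTimes = numeric(0), thresholdUsed = thr,
                        noiseSd = noiseSd, duration = duration))
  }
  deadSamples <- deadTime * samplingRate
  grp <- cumsum(c(1L, as.integer(diff(idx) > deadSamples)))
  peaks <- vapply(split(idx, grp),
                  function(ii) ii[which.max(abs(filtered[ii]))], integer(1))
  times <- (unname(peaks) - 1L) / samplingRate
  # enforce the dead time between merged-event extrema as well
  if (length(times) > 1L) {
    keep <- logical(length(times))
    last <- -Inf
    for (i in seq_along(times)) {
      if (times[i] - last >= deadTime) {
        keep[i] <- TRUE
        last <- times[i]
      }
    }
    times <- times[keep]
  }
  methods::new("SpikeTrain", channelId = channelId, spikeTimes = times,
               thresholdUsed = thr, noiseSd = noiseSd, duration = duration)
}

#' Active-channel classification
#'
#' A channel is inactive if fewer than `minSpikes` events were detected over
#' the reference recording period (100 spikes in 5 min); exactly `minSpikes`
#' is active. For other durations the count threshold scales linearly.
#'
#' @param spikeCount detected event count (non-negative).
#' @param duration trace duration, seconds.
#' @param minSpikes count threshold at the reference duration.
#' @param referenceDuration reference duration, seconds.
#' @return logical: TRUE if the channel is active.
#' @export
classifyChannelActivity <- function(spikeCount, duration, minSpikes = 100,
                                    referenceDuration = 300) {
  .stopIf(any(spikeCount < 0), "spike counts must be non-negative")
  .stopIf(duration <= 0, "duration must be positive")
  spikeCount >= minSpikes * (duration / referenceDuration)
}

#' Multi-unit-activity frequency
#'
#' @param x a [SpikeTrain-class] or a numeric spike count.
#' @param duration trace duration in seconds (taken from the SpikeTrain when
#'   omitted).
#' @return event frequency in Hz (count / duration).
#' @export
muaFrequency <- function(x, duration = NULL) {
  if (methods::is(x, "SpikeTrain")) {
    n <- length(x@spikeTimes)
    if (is.null(duration)) duration <- x@duration
  } else n <- x
  .stopIf(is.null(duration) || duration <= 0, "duration must be positive")
  n / duration
}

#' Channel indices for electrode rows of a rectangular MEA layout
#'
#' Channels are assumed numbered row-wise on an `nRows` x `nCols` grid
#' (default the 6 x 10 view of a 60-electrode chip). Analyses restricted to
#' particular cortical layers select the corresponding electrode rows, e.g.
#' rows 2 and 3 for layer 2/3.
#'
#' @param rows electrode row numbers to select.
#' @param nRows,nCols grid dimensions.
#' @return integer channel indices.
#' @export
meaRowChannels <- function(rows, nRows = 6, nCols = 10) {
  .stopIf(!all(rows %in% seq_len(nRows)), "rows must be in 1..%d", nRows)
  as.integer(outer(seq_len(nCols), (rows - 1) * nCols, `+`))
}

#' Per-slice MUA summary
#'
#' Runs the full detection chain per channel (highpass filter, robust noise
#' estimate, threshold detection, active-channel classification) and reports
#' the two slice-level readouts: the number of active channels and the MUA
#' frequency of every analyzed channel.
#'
#' @param x an [MEARecording-class].
#' @param channels optional subset of channel indices or ids to analyze
#'   (e.g. `meaRowChannels(2:3)`); default all channels.
#' @param cutoff,filterOrder,zeroPhase highpass settings, see
#'   [highpassFilter()].
#' @param thresholdMultiple,deadTime detection settings, see [detectSpikes()].
#' @param minSpikes,referenceDuration classification settings, see
#'   [classifyChannelActivity()].
#' @param ... ignored.
#' @return data.frame with one row per analyzed channel (`channel_id`,
#'   `noise_sd`, `spike_count`, `mua_hz`, `active`) and attributes
#'   `nActive` and `duration`.
#' @export
setMethod("summarizeSlice", "MEARecording",
  function(x, channels = NULL, cutoff = 200, filterOrder = 2,
           zeroPhase = FALSE, thresholdMultiple = 5, deadTime = 0.001,
           minSpikes = 100, referenceDuration = 300, ...) {
    ids <- channelIds(x)
    sel <- if (is.null(channels)) seq_along(ids)
           else if (is.character(channels)) match(channels, ids)
           else as.integer(channels)
    .stopIf(anyNA(sel) || any(sel < 1L) || any(sel > length(ids)),
            "unknown channel selection")
    dur <- recordingDuration(x)
    rows <- lapply(sel, function(i) {
      f <- highpassFilter(voltages(x)[i, ], samplingRate(x), cutoff,
                          filterOrder, zeroPhase)
      sd_i <- estimateNoiseSd(f)
      if (sd_i <= 0) {
        return(data.frame(channel_id = ids[i], noise_sd = sd_i,
                          spike_count = 0L, mua_hz = 0, active = FALSE))
      }
      st <- detectSpikes(f, samplingRate(x), thresholdMultiple, deadTime,
                         noiseSd = sd_i, channelId = ids[i])
      n <- length(spikeTimes(st))
      data.frame(channel_id = ids[i], noise_sd = sd_i, spike_count = n,
                 mua_hz = muaFrequency(n, dur),
                 active = classifyChannelActivity(n, dur, minSpikes,
                                                  referenceDuration))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "nActive") <- sum(out$active)
    attr(out, "duration") <- dur
    out
  })
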