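#' Score spike detection against generator ground truth, channel by channel
#'
#' Simulates the full acquisition regime one channel at a time (a 60-channel
#' 5-minute 50 kHz recording does not need to be held in memory at once),
#' runs the detection chain on each channel and scores the detected event
#' times against the inserted ground truth.
#'
#' @param nChannels number of channels.
#' @param duration trace duration, seconds.
#' @param samplingRate sampling rate, Hz.
#' @param spikeRate true spike rate per channel, Hz.
#' @param spikeAmplitude spike amplitude in noise-SD multiples.
#' @param seed master seed (per-channel seeds are derived).
#' @param tol event-matching tolerance, seconds.
#' @param ... further arguments to [detectSpikes()].
#' @return list: `recall`, `precision` (pooled over channels), and
#'   `channels`, a data.frame with per-channel `n_true`, `n_detected`,
#'   `tp`, `fp`, `fn`, `true_rate_hz`, `mua_hz`.
#' @export
validateSpikeDetection <- function(nChannels = 60, duration = 300,
                                   samplingRate = 50000, spikeRate = 1,
                                   spikeAmplitude = 8, seed = 1,
                                   tol = 0.002, ...) {
  rows <- lapply(seq_len(nChannels), function(i) {
    cfg <- meaSimConfig(nChannels = 1, duration = duration,
                        samplingRate = samplingRate, spikeRates = spikeRate,
                        spikeAmplitude = spikeAmplitude,
                        seed = childSeed(seed, i))
    sim <- simulateMEARecording(cfg)
    f <- highpassFilter(voltages(sim$recording)[1, ], samplingRate)
    st <- detectSpikes(f, samplingRate, channelId = sprintf("ch%02d", i), ...)
    m <- matchEventTimes(spikeTimes(st), sim$spikeTimes[[1]], tol = tol)
    data.frame(channel = i, n_true = length(sim$spikeTimes[[1]]),
               n_detected = length(spikeTimes(st)), tp = m$tp, fp = m$fp,
               fn = m$fn,
               true_rate_hz = length(sim$spikeTimes[[1]]) / duration,
               mua_hz = muaFrequency(st))
  })
  ch <- do.call(rbind, rows)
  list(recall = sum(ch$tp) / sum(ch$n_true),
       precision = sum(ch$tp) / sum(ch$n_detected),
       channels = ch)
}
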