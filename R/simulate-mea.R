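#' MEA simulation configuration
#'
#' Emulated acquisition regime: 60-electrode chip, 50 kHz sampling, 5-minute
#' traces. Spikes are biphasic (negative-then-positive) 1 ms waveforms
#' inserted at per-channel Poisson rates into Gaussian noise, scaled in
#' multiples of the noise SD.
#'
#' @param nChannels number of channels.
#' @param duration trace duration, seconds.
#' @param samplingRate sampling rate, Hz.
#' @param noiseSd Gaussian noise SD per channel (volt-equivalent units).
#' @param spikeRates per-channel Poisson spike rate, Hz (recycled).
#' @param spikeAmplitude peak spike amplitude in multiples of `noiseSd`.
#' @param spikeWaveformWidth waveform support, seconds (default 1 ms).
#' @param seed integer seed.
#' @return a validated config list of class `MEASimConfig`.
#' @export
meaSimConfig <- function(nChannels = 60, duration = 300, samplingRate = 50000,
                         noiseSd = 1, spikeRates = 1, spikeAmplitude = 8,
                         spikeWaveformWidth = 0.001, seed = 1) {
  .stopIf(duration <= 0, "duration must be positive")
  .stopIf(samplingRate <= 0, "samplingRate must be positive")
  .stopIf(nChannels < 1, "need at least one channel")
  .stopIf(any(spikeRates < 0), "spike rates must be non-negative")
  .stopIf(noiseSd < 0, "noiseSd must be non-negative")
  # waveform must be resolvable: >= 10 samples across its support
  .stopIf(samplingRate * spikeWaveformWidth < 10,
          "samplingRate too low for the spike waveform width")
  structure(list(nChannels = as.integer(nChannels), duration = duration,
                 samplingRate = samplingRate, noiseSd = noiseSd,
                 spikeRates = rep_len(spikeRates, nChannels),
                 spikeAmplitude = spikeAmplitude,
                 spikeWaveformWidth = spikeWaveformWidth,
                 seed = as.integer(seed)),
            class = "MEASimConfig")
}

# biphasic extracellular waveform: dominant negative phase followed by a
# smaller positive rebound (40%), peak |amplitude| = 1, trough at width/4
.spikeWaveform <- function(width, samplingRate) {
  n <- round(width * samplingRate)
  h <- floor(n / 2)
  c(-sin(pi * seq_len(h) / h), 0.4 * sin(pi * seq_len(n - h) / (n - h)))
}

#' Ground-truth spike times only (no voltage synthesis)
#'
#' Draws the same Poisson event times that [simulateMEARecording()] inserts,
#' without allocating the voltage matrix. Useful for checking event-count
#' statistics at full scale cheaply; shares the code path (and seed stream)
#' of the full simulator.
#'
#' @param config an [meaSimConfig()].
#' @return list of per-channel sorted spike-time vectors (trough times,
#'   seconds).
#' @export
simulateMEASpikeTimes <- function(config) {
  stopifnot(inherits(config, "MEASimConfig"))
  set.seed(config$seed)
  width <- config$spikeWaveformWidth
  lapply(seq_len(config$nChannels), function(i) {
    n <- stats::rpois(1, config$spikeRates[i] * config$duration)
    if (!n) return(numeric(0))
    starts <- sort(stats::runif(n, 0, config$duration - width))
    starts + width / 4  # trough of the biphasic waveform
  })
}

#' Simulate a multichannel MEA recording with known spike times
#'
#' Gaussian noise plus biphasic spike waveforms at Poisson ground-truth times,
#' bit-identical for a fixed seed. The returned truth times are the waveform
#' trough times, matching the extremum-based event times that
#' [detectSpikes()] reports.
#'
#' @param config an [meaSimConfig()].
#' @return list with `recording` (an [MEARecording-class]) and `spikeTimes`
#'   (per-channel ground-truth event times).
#' @export
simulateMEARecording <- function(config) {
  stopifnot(inherits(config, "MEASimConfig"))
  truth <- simulateMEASpikeTimes(config)  # seeds the RNG, draws event times
  nS <- round(config$duration * config$samplingRate)
  w <- .spikeWaveform(config$spikeWaveformWidth, config$samplingRate) *
    config$spikeAmplitude * config$noiseSd
  nw <- length(w)
  v <- matrix(0, nrow = config$nChannels, ncol = nS)
  for (i in seq_len(config$nChannels)) {
    x <- stats::rnorm(nS, 0, config$noiseSd)
    troughs <- truth[[i]]
    if (length(troughs)) {
      starts <- round((troughs - config$spikeWaveformWidth / 4) *
                        config$samplingRate) + 1L
      for (s in starts) {
        j <- s:(s + nw - 1L)
        x[j] <- x[j] + w
      }
    }
    v[i, ] <- x
  }
  rec <- MEARecording(v, config$samplingRate, sliceId = "sim",
                      group = "synthetic")
  list(recording = rec, spikeTimes = truth)
}
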