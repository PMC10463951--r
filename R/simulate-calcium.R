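#' Calcium-trace simulation configuration
#'
#' Emulates the ratiometric imaging protocol: baseline-level F340/380 traces
#' sampled every 2 s, a capsaicin transient for responders starting at 200 s
#' (20 s perfusion) and a KCl transient starting at 780 s (45 s perfusion).
#' Transients are smooth rise-decay (alpha-function) kernels whose peak fold
#' over baseline is the configured amplitude; the kernel peaks `peakDelay`
#' seconds after stimulus onset, placed on the sample grid so noise-free
#' maxima are exact.
#'
#' @param nNeurons number of neurons.
#' @param duration trace length, seconds.
#' @param sampleInterval sampling step, seconds (default 2).
#' @param baselineLevel baseline F340/380 ratio.
#' @param noiseSd additive Gaussian noise SD (ratio units).
#' @param capsOnset,capsWindow capsaicin onset and perfusion window, seconds.
#' @param capsAmplitude capsaicin peak fold over baseline for responders.
#' @param kclOnset,kclWindow KCl onset and perfusion window, seconds.
#' @param kclAmplitude KCl peak fold over baseline for responders.
#' @param responderFraction probability that a neuron responds to capsaicin.
#' @param kclResponderFraction probability that a neuron responds to KCl
#'   (viability; near 1 in healthy preparations).
#' @param peakDelay kernel time-to-peak after onset, seconds.
#' @param group group label attached to all neurons.
#' @param seed integer seed.
#' @return a validated config list of class `CaSimConfig`.
#' @export
caSimConfig <- function(nNeurons = 100, duration = 900, sampleInterval = 2,
                        baselineLevel = 0.8, noiseSd = 0.01,
                        capsOnset = 200, capsWindow = 20, capsAmplitude = 1.8,
                        kclOnset = 780, kclWindow = 45, kclAmplitude = 2.5,
                        responderFraction = 0.7, kclResponderFraction = 0.95,
                        peakDelay = 10, group = "synthetic", seed = 1) {
  .stopIf(nNeurons < 1 || duration <= 0 || sampleInterval <= 0,
          "nNeurons, duration and sampleInterval must be positive")
  .stopIf(capsOnset >= kclOnset, "capsaicin onset must precede KCl onset")
  .stopIf(capsOnset + capsWindow > kclOnset,
          "overlapping stimulus windows (capsaicin window reaches into KCl)")
  .stopIf(responderFraction < 0 || responderFraction > 1 ||
            kclResponderFraction < 0 || kclResponderFraction > 1,
          "responder fractions must be in [0, 1]")
  .stopIf(baselineLevel <= 0, "baselineLevel must be positive")
  .stopIf(capsAmplitude < 1 || kclAmplitude < 1,
          "amplitudes are folds over baseline and must be >= 1")
  structure(list(nNeurons = as.integer(nNeurons), duration = duration,
                 sampleInterval = sampleInterval,
                 baselineLevel = baselineLevel, noiseSd = noiseSd,
                 capsOnset = capsOnset, capsWindow = capsWindow,
                 capsAmplitude = capsAmplitude, kclOnset = kclOnset,
                 kclWindow = kclWindow, kclAmplitude = kclAmplitude,
                 responderFraction = responderFraction,
                 kclResponderFraction = kclResponderFraction,
                 peakDelay = peakDelay, group = group,
                 seed = as.integer(seed)),
            class = "CaSimConfig")
}

# alpha kernel, peak exactly 1 at t = peakDelay, 0 for t < 0
.alphaKernel <- function(t, peakDelay) {
  k <- (t / peakDelay) * exp(1 - t / peakDelay)
  k[t < 0] <- 0
  k
}

#' Simulate calcium traces with known responder ground truth
#'
#' @param config a [caSimConfig()].
#' @return list with `traces` (a [CalciumTraceSet-class]) and `truth`
#'   (data.frame: `neuron_id`, `caps_responder`, `caps_amplitude`,
#'   `kcl_responder`, `kcl_amplitude`).
#' @export
simulateCalciumTraces <- function(config) {
  stopifnot(inherits(config, "CaSimConfig"))
  set.seed(config$seed)
  times <- seq(0, config$duration, by = config$sampleInterval)
  base <- config$baselineLevel
  capsResp <- stats::runif(config$nNeurons) < config$responderFraction
  kclResp <- stats::runif(config$nNeurons) < config$kclResponderFraction
  capsK <- .alphaKernel(times - config$capsOnset, config$peakDelay)
  kclK <- .alphaKernel(times - config$kclOnset, config$peakDelay)
  ratios <- vapply(seq_len(config$nNeurons), function(i) {
    x <- base + stats::rnorm(length(times), 0, config$noiseSd)
    if (capsResp[i]) x <- x + (config$capsAmplitude - 1) * base * capsK
    if (kclResp[i]) x <- x + (config$kclAmplitude - 1) * base * kclK
    x
  }, numeric(length(times)))
  info <- data.frame(neuron_id = sprintf("n%03d", seq_len(config$nNeurons)),
                     animal_id = "sim", group = config$group,
                     stringsAsFactors = FALSE)
  truth <- data.frame(neuron_id = info$neuron_id,
                      caps_responder = capsResp,
                      caps_amplitude = ifelse(capsResp, config$capsAmplitude, 1),
                      kcl_responder = kclResp,
                      kcl_amplitude = ifelse(kclResp, config$kclAmplitude, 1),
                      stringsAsFactors = FALSE)
  list(traces = CalciumTraceSet(times, ratios, info), truth = truth)
}
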