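#' Default stimulus windows of the calcium-imaging protocol
#'
#' Baseline 0-200 s, capsaicin perfusion 200-220 s, KCl 780-825 s. The
#' capsaicin response is searched in `[200, 780)` s (so late depolarization
#' responses are never mis-attributed) and the KCl response strictly after
#' 780 s.
#'
#' @return named list of window vectors (seconds).
#' @export
stimulusWindows <- function() {
  list(baseline = c(0, 200), capsaicin = c(200, 220),
       caps_search = c(200, 780), kcl = c(780, 825),
       kcl_search = c(780, Inf))
}

#' Normalize a ratio trace to its baseline mean
#'
#' Fold change `ratio(t) / mean(ratio over the baseline window)`. The
#' baseline window is half-open `[t0, t1)` and must contain at least 10
#' samples.
#'
#' @param x numeric ratio vector, or a [CalciumTraceSet-class].
#' @param times sample times (seconds); taken from the object for a trace set.
#' @param baselineWindow two-element window, seconds.
#' @param ... passed between methods.
#' @return fold-change vector (or time x neuron matrix for a trace set).
#' @rdname normalizeToBaseline
#' @export
setMethod("normalizeToBaseline", "numeric",
  function(x, times, baselineWindow = c(0, 200), ...) {
    inBase <- times >= baselineWindow[1] & times < baselineWindow[2]
    .stopIf(sum(inBase) < 10,
            "need at least 10 samples in the baseline window")
    m <- mean(x[inBase])
    .stopIf(!is.finite(m) || m <= 0, "non-positive baseline mean")
    x / m
  })

#' @rdname normalizeToBaseline
#' @export
setMethod("normalizeToBaseline", "CalciumTraceSet",
  function(x, baselineWindow = c(0, 200), ...) {
    apply(traceRatios(x), 2, normalizeToBaseline, times = traceTimes(x),
          baselineWindow = baselineWindow)
  })

#' Earliest qualifying supra-threshold run
#'
#' Finds the earliest maximal run of at least `minRun` consecutive samples
#' with fold strictly above `threshold`, whose first sample lies in the
#' search window. The run-start window check is `start >= window[1]` (or
#' `>` when `leftOpen`) and `start < window[2]`.
#'
#' @param fold normalized fold-change vector.
#' @param times sample times, seconds.
#' @param threshold fold threshold (strict inequality).
#' @param minRun minimum run length in samples.
#' @param window search window for the run start, seconds.
#' @param leftOpen if TRUE the left window bound is exclusive (the KCl rule's
#'   "time to peak > 780 s").
#' @return list with `start` (index) and `length`, or NULL if no run
#'   qualifies.
#' @export
findThresholdRun <- function(fold, times, threshold, minRun = 5,
                             window = c(-Inf, Inf), leftOpen = FALSE) {
  .stopIf(minRun < 1, "minRun must be at least 1")
  .stopIf(length(window) != 2 || window[2] <= window[1],
          "empty search window")
  r <- rle(fold > threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] < minRun) next
    t0 <- times[starts[k]]
    okLeft <- if (leftOpen) t0 > window[1] else t0 >= window[1]
    if (okLeft && t0 < window[2])
      return(list(start = starts[k], length = r$lengths[k]))
  }
  NULL
}

# peak/AUC of the above-baseline excursion containing a qualifying run.
# Excursion = maximal run of fold > 1 containing runStart, extended by one
# flanking sample on each side; AUC integrates max(fold - 1, 0) over it by
# the trapezoidal rule, so a piecewise-linear transient that touches baseline
# at the flanks is integrated exactly.
.excursionPeak <- function(fold, times, runStart) {
  above <- fold > 1
  lo <- runStart
  while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- runStart
  n <- length(fold)
  while (hi < n && above[hi + 1L]) hi <- hi + 1L
  core <- lo:hi
  ext <- max(1L, lo - 1L):min(n, hi + 1L)
  iPeak <- core[which.max(fold[core])]
  list(peak_fold = fold[iPeak], time_to_peak = times[iPeak],
       auc = .trapz(times[ext], pmax(fold[ext] - 1, 0)))
}

.noCall <- function(rule) {
  data.frame(detected = FALSE, peak_fold = NA_real_, time_to_peak = NA_real_,
             auc = NA_real_, rule = rule)
}

#' Call the capsaicin response of a normalized trace
#'
#' The response is the first run of at least `minRun` consecutive samples
#' more than 10% above baseline whose start lies in the capsaicin search
#' window; the peak is the maximum fold within the above-baseline excursion
#' containing that run, and the AUC the trapezoidal integral of (fold - 1)
#' over the excursion.
#'
#' @param fold normalized fold-change vector.
#' @param times sample times, seconds.
#' @param threshold fold threshold (default 1.10, strict).
#' @param minRun minimum run length (default 5 samples).
#' @param window run-start search window, default `[200, 780)` s.
#' @return one-row data.frame: `detected`, `peak_fold`, `time_to_peak`,
#'   `auc`, `rule`.
#' @export
callCapsaicinPeak <- function(fold, times, threshold = 1.10, minRun = 5,
                              window = stimulusWindows()$caps_search) {
  run <- findThresholdRun(fold, times, threshold, minRun, window)
  if (is.null(run)) return(.noCall("capsaicin"))
  cbind(data.frame(detected = TRUE),
        as.data.frame(.excursionPeak(fold, times, run$start)),
        data.frame(rule = "capsaicin"))
}

#' Call the high-K+ (KCl) response of a normalized trace
#'
#' As the capsaicin call, but the threshold is a 20% raise above baseline and
#' the qualifying run must start strictly after 780 s.
#'
#' @inheritParams callCapsaicinPeak
#' @param threshold fold threshold (default 1.20, strict).
#' @param window run-start search window, default `(780, Inf)` s (left bound
#'   exclusive).
#' @return one-row data.frame as for [callCapsaicinPeak()].
#' @export
callKclPeak <- function(fold, times, threshold = 1.20, minRun = 5,
                        window = stimulusWindows()$kcl_search) {
  run <- findThresholdRun(fold, times, threshold, minRun, window,
                          leftOpen = TRUE)
  if (is.null(run)) return(.noCall("kcl"))
  cbind(data.frame(detected = TRUE),
        as.data.frame(.excursionPeak(fold, times, run$start)),
        data.frame(rule = "kcl"))
}

#' Peak calls for every neuron of a trace set
#'
#' Normalizes each trace to its baseline mean and applies both stimulus
#' rules.
#'
#' @param x a [CalciumTraceSet-class].
#' @param capsThreshold,kclThreshold fold thresholds of the two rules.
#' @param minRun minimum run length in samples.
#' @param baselineWindow baseline window, seconds.
#' @param ... ignored.
#' @return data.frame with one row per neuron per rule; neuron metadata
#'   columns are carried through.
#' @export
setMethod("callPeaks", "CalciumTraceSet",
  function(x, capsThreshold = 1.10, kclThreshold = 1.20, minRun = 5,
           baselineWindow = c(0, 200), ...) {
    fold <- normalizeToBaseline(x, baselineWindow = baselineWindow)
    times <- traceTimes(x)
    info <- neuronInfo(x)
    out <- lapply(seq_len(ncol(fold)), function(j) {
      rbind(callCapsaicinPeak(fold[, j], times, capsThreshold, minRun),
            callKclPeak(fold[, j], times, kclThreshold, minRun))
    })
    calls <- do.call(rbind, out)
    cbind(info[rep(seq_len(nrow(info)), each = 2L), , drop = FALSE], calls,
          row.names = NULL)
  })

#' Population summary of peak calls
#'
#' Per group and rule: number of neurons, responder fraction (detected /
#' total), and the peak-fold / time-to-peak / AUC distributions summarized by
#' mean, SD and median. The underlying call table feeds the group-statistics
#' layer.
#'
#' @param calls data.frame from [callPeaks()] (needs `group`, `rule`,
#'   `detected`, `peak_fold`, `time_to_peak`, `auc`).
#' @return data.frame with one row per (group, rule).
#' @export
summarizePopulation <- function(calls) {
  .stopIf(!nrow(calls), "empty call table")
  .stopIf(any(!table(calls$group)), "empty group")
  units <- split(calls, list(calls$group, calls$rule), drop = TRUE)
  out <- lapply(units, function(u) {
    det <- u[u$detected, , drop = FALSE]
    data.frame(group = u$group[1], rule = u$rule[1], n = nrow(u),
               n_detected = nrow(det),
               responder_fraction = nrow(det) / nrow(u),
               mean_peak_fold = mean(det$peak_fold),
               sd_peak_fold = stats::sd(det$peak_fold),
               median_peak_fold = stats::median(det$peak_fold),
               mean_time_to_peak = mean(det$time_to_peak),
               mean_auc = mean(det$auc))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
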