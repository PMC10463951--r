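# Shared fixture builders (all fixtures are constructed in code).

# minimal visit table: one row per (animal, corner, start, end) triple
makeVisits <- function(animal, corner, start, end, np = 0, licks = 0,
                       lickDur = 0, task = "FA", group = "g1") {
  n <- length(start)
  data.frame(animal_id = rep_len(animal, n), group = rep_len(group, n),
             corner = rep_len(corner, n), start = start, end = end,
             np_count = rep_len(np, n),
             np_correct_count = rep_len(0L, n),
             first_np_s = ifelse(rep_len(np, n) > 0, 1, NA_real_),
             door_opened = rep_len(np, n) > 0,
             lick_count = rep_len(licks, n),
             lick_duration_s = rep_len(lickDur, n),
             task = rep_len(task, n),
             day = floor(start / 86400) + 1,
             stringsAsFactors = FALSE)
}

makeExperiment <- function(v, totalDays = NULL, task = "FA") {
  hi <- if (is.null(totalDays)) max(v$end) + 1 else totalDays * 86400
  IntelliCageExperiment(v, data.frame(task = task, start = 0, end = hi))
}

# noise-free calcium trace on the 2 s protocol grid with chosen fold values
# patched into a flat baseline-normalized series
makeFoldTrace <- function(duration = 900, step = 2) {
  times <- seq(0, duration, by = step)
  list(times = times, fold = rep(1, length(times)))
}

# triangular excursion rising 1 -> peak -> 1 linearly, centred on the grid
addTriangle <- function(trace, tStart, width, peak) {
  tt <- trace$times
  half <- width / 2
  tri <- pmax(0, 1 - abs(tt - (tStart + half)) / half) * (peak - 1)
  trace$fold <- trace$fold + tri
  trace
}
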