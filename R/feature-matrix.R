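#' Implemented behavioral parameters
#'
#' Names accepted by [taskFeatureMatrix()]. Each is computed per animal per
#' observation day (except `repetitiveness`, computed per task from all task
#' visits - per-day shuffle statistics on the order of a hundred visits are
#' noise-dominated) and then averaged per task and over the whole
#' observation.
#'
#' @return character vector of parameter names.
#' @export
behavioralParameters <- function() {
  c("visits_h_day", "visits_h_night", "np_per_visit", "np_h", "licks_h",
    "lick_duration_h", "licks_per_visit", "correct_fraction",
    "fast_reentry_h", "repetitiveness", "mean_visit_duration_s", "mean_ivi_s",
    "frac_visits_with_np", "door_latency_s")
}

# per-day parameter values for one animal's visits (one observation day)
.dayFeatures <- function(u, pairs, correctSetByTask) {
  dayHours <- 12
  phase <- (u$start %% 86400) < 12 * 3600
  nDay <- sum(phase); nNight <- sum(!phase)
  nv <- nrow(u)
  corrFrac <- NA_real_
  cs <- correctSetByTask[[u$task[1]]]
  if (!is.null(cs)) corrFrac <- mean(u$corner %in% cs)
  c(visits_h_day = nDay / dayHours,
    visits_h_night = nNight / dayHours,
    np_per_visit = sum(u$np_count) / nv,
    np_h = sum(u$np_count) / 24,
    licks_h = sum(u$lick_count) / 24,
    lick_duration_h = sum(u$lick_duration_s) / 24,
    licks_per_visit = sum(u$lick_count) / nv,
    correct_fraction = corrFrac,
    fast_reentry_h = if (is.null(pairs) || !nrow(pairs)) 0
      else sum(pairs$same & pairs$fast) / 24,
    mean_visit_duration_s = mean(u$end - u$start),
    mean_ivi_s = if (is.null(pairs) || !nrow(pairs)) NA_real_
      else mean(pairs$ivi),
    frac_visits_with_np = mean(u$np_count > 0),
    door_latency_s = if (any(!is.na(u$first_np_s)))
      mean(u$first_np_s, na.rm = TRUE) else NA_real_)
}

#' Per-animal per-task behavioral feature matrix
#'
#' Computes the implemented parameter set per observation day, averages the
#' per-day values over the duration of each task (FA, NP3c, PPL, PPLrev) and
#' over the whole observation ("overall"), yielding exactly five task-level
#' values per parameter per animal. Missing days yield missing values.
#'
#' @param x an [IntelliCageExperiment-class].
#' @param parameters parameter names, a subset of [behavioralParameters()].
#' @param iviThreshold IVI threshold for fast re-entries and repetitiveness,
#'   seconds.
#' @param nShuffles shuffle count for the repetitiveness null.
#' @param seed seed for the shuffle null.
#' @return numeric matrix, animals x (parameter . task) with tasks ordered
#'   as scheduled plus `overall`; attributes `parameters`, `tasks`,
#'   `animals`, `groups`.
#' @export
taskFeatureMatrix <- function(x, parameters = behavioralParameters(),
                              iviThreshold = 60, nShuffles = 1000, seed = 1) {
  unknown <- setdiff(parameters, behavioralParameters())
  .stopIf(length(unknown) > 0, "unknown parameter(s): %s",
          paste(unknown, collapse = ", "))
  v <- visits(x)
  .stopIf(!nrow(v), "empty visit stream")
  tasks <- schedule(x)$task
  .stopIf(anyDuplicated(tasks) > 0, "duplicated task names in schedule")
  asg <- cornerAssignments(x)
  animals <- asg$animal_id
  needRep <- "repetitiveness" %in% parameters
  repTab <- if (needRep)
    repetitiveness(x, iviThreshold, nShuffles, seed, byTask = TRUE) else NULL

  perAnimal <- lapply(animals, function(a) {
    va <- v[v$animal_id == a, , drop = FALSE]
    va <- va[order(va$start), , drop = FALSE]
    csets <- stats::setNames(
      lapply(tasks, function(tk) .correctSet(tk, asg$ppl_corner[match(a, asg$animal_id)])),
      tasks)
    # consecutive pairs, attributed to the day/task of the second visit
    n <- nrow(va)
    pairs <- if (n >= 2L) data.frame(
      ivi = va$start[-1L] - va$end[-n],
      same = va$corner[-1L] == va$corner[-n],
      day = va$day[-1L], task = va$task[-1L]) else NULL
    if (!is.null(pairs)) pairs$fast <- pairs$ivi < iviThreshold
    days <- sort(unique(va$day))
    perDay <- vapply(days, function(d) {
      u <- va[va$day == d, , drop = FALSE]
      p <- if (!is.null(pairs)) pairs[pairs$day == d, , drop = FALSE] else NULL
      .dayFeatures(u, p, csets)
    }, numeric(13L))
    dayTask <- va$task[match(days, va$day)]
    taskMean <- function(param, tk) {
      vals <- perDay[param, if (tk == "overall") TRUE else dayTask == tk]
      if (!length(vals) || all(is.na(vals))) NA_real_
      else mean(vals, na.rm = TRUE)
    }
    vals <- c()
    for (param in parameters) {
      for (tk in c(tasks, "overall")) {
        val <- if (param == "repetitiveness") {
          r <- repTab[repTab$animal_id == a & repTab$task == tk, "value"]
          if (length(r)) r[1] else NA_real_
        } else taskMean(param, tk)
        vals <- c(vals, stats::setNames(val, paste(param, tk, sep = ".")))
      }
    }
    vals
  })
  m <- do.call(rbind, perAnimal)
  rownames(m) <- animals
  attr(m, "parameters") <- parameters
  attr(m, "tasks") <- c(tasks, "overall")
  attr(m, "animals") <- animals
  attr(m, "groups") <- asg$group
  m
}
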