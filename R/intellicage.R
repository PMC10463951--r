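#' Correct corner set per animal and task
#'
#' NP3c rewards three corners (all but the future PPLrev corner), PPL the
#' assigned corner, PPLrev the opposite-side corner; FA has no correct set.
#'
#' @param x an [IntelliCageExperiment-class].
#' @param animalId animal label.
#' @param task task name.
#' @return integer vector of correct corners, or NULL for FA.
#' @export
correctCorners <- function(x, animalId, task) {
  asg <- cornerAssignments(x)
  i <- match(animalId, asg$animal_id)
  .stopIf(is.na(i), "unknown animal '%s'", animalId)
  .correctSet(task, asg$ppl_corner[i])
}

#' Binned activity time course
#'
#' Per-animal per-bin rates in half-open bins `[t, t + width)` aligned to the
#' lights-on anchor: visits/h, nosepokes/h, licks/h and licking duration per
#' hour. A visit belongs to the bin containing its start; bins with no visits
#' are reported with rate 0, so binned counts sum to stream totals.
#'
#' @param x an [IntelliCageExperiment-class].
#' @param binWidth bin width in hours (default 12: the day/night raster).
#' @return long data.frame: `animal_id`, `group`, `bin`, `bin_start_h`,
#'   `n_visits`, `visits_h`, `np_h`, `licks_h`, `lick_duration_s_h`.
#' @export
binTimecourse <- function(x, binWidth = 12) {
  .stopIf(binWidth <= 0, "binWidth must be positive")
  v <- visits(x)
  .stopIf(!nrow(v), "empty visit stream")
  wS <- binWidth * 3600
  total <- max(schedule(x)$end)
  nBins <- ceiling(total / wS)
  grid <- expand.grid(bin = seq_len(nBins),
                      animal_id = unique(v$animal_id),
                      stringsAsFactors = FALSE)
  v$bin <- floor((v$start - lightsOn(x)) / wS) + 1L
  agg <- function(val) {
    s <- tapply(val, list(v$animal_id, v$bin), sum)
    idx <- cbind(match(grid$animal_id, rownames(s)),
                 match(as.character(grid$bin), colnames(s)))
    out <- s[idx]
    out[is.na(out)] <- 0
    out
  }
  res <- data.frame(
    animal_id = grid$animal_id,
    bin = grid$bin,
    bin_start_h = (grid$bin - 1L) * binWidth,
    n_visits = agg(rep(1, nrow(v))),
    np = agg(v$np_count),
    licks = agg(v$lick_count),
    lick_duration_s = agg(v$lick_duration_s))
  res$visits_h <- res$n_visits / binWidth
  res$np_h <- res$np / binWidth
  res$licks_h <- res$licks / binWidth
  res$lick_duration_s_h <- res$lick_duration_s / binWidth
  if ("group" %in% names(v))
    res$group <- v$group[match(res$animal_id, v$animal_id)]
  res[order(res$animal_id, res$bin), ]
}

# attach a unit column: "task", "day" or "bin<width>"
.unitColumn <- function(v, x, by, binWidth = 12) {
  switch(by,
         task = v$task,
         day = v$day,
         bin = floor((v$start - lightsOn(x)) / (binWidth * 3600)) + 1L,
         stop("unknown grouping: ", by, call. = FALSE))
}

#' Nosepokes per visit
#'
#' Total nosepokes over total visits within each (animal, unit); units with
#' zero visits are absent (missing), never reported as 0.
#'
#' @param x an [IntelliCageExperiment-class].
#' @param by grouping unit: `"task"`, `"day"` or `"bin"`.
#' @param binWidth bin width in hours when `by = "bin"`.
#' @return data.frame: `animal_id`, `group`, unit column, `np_per_visit`.
#' @export
npPerVisit <- function(x, by = "task", binWidth = 12) {
  v <- visits(x)
  .stopIf(!nrow(v), "empty visit stream")
  v$unit <- .unitColumn(v, x, by, binWidth)
  sp <- split(v, list(v$animal_id, v$unit), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(u) data.frame(
    animal_id = u$animal_id[1], group = u$group[1], unit = u$unit[1],
    n_visits = nrow(u), np_per_visit = sum(u$np_count) / nrow(u))))
  names(out)[names(out) == "unit"] <- by
  rownames(out) <- NULL
  out
}

#' Proportion of correct corner visits
#'
#' Per animal per task day, the fraction of visits whose corner is in the
#' animal's correct set for that task (NP3c: three corners; PPL/PPLrev: one).
#' FA visits are excluded (no correct corner is defined there).
#'
#' @param x an [IntelliCageExperiment-class].
#' @return data.frame: `animal_id`, `group`, `task`, `day`, `n_visits`,
#'   `correct_fraction`.
#' @export
correctVisitFraction <- function(x) {
  v <- visits(x)
  asg <- cornerAssignments(x)
  v <- v[v$task %in% c("NP3c", "PPL", "PPLrev"), , drop = FALSE]
  if (!nrow(v)) return(data.frame(animal_id = character(0),
                                  group = character(0), task = character(0),
                                  day = numeric(0), n_visits = integer(0),
                                  correct_fraction = numeric(0)))
  ppl <- asg$ppl_corner[match(v$animal_id, asg$animal_id)]
  ok <- mapply(function(crn, task, pc) crn %in% .correctSet(task, pc),
               v$corner, v$task, ppl)
  v$ok <- ok
  sp <- split(v, list(v$animal_id, v$task, v$day), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(u) data.frame(
    animal_id = u$animal_id[1], group = u$group[1], task = u$task[1],
    day = u$day[1], n_visits = nrow(u),
    correct_fraction = mean(u$ok))))
  rownames(out) <- NULL
  out[order(out$animal_id, out$day), ]
}

# consecutive-pair table per animal: ivi (end -> next start) and same-corner
.pairTable <- function(v) {
  sp <- split(v, v$animal_id)
  do.call(rbind, lapply(sp, function(u) {
    u <- u[order(u$start), , drop = FALSE]
    n <- nrow(u)
    if (n < 2L) return(NULL)
    data.frame(animal_id = u$animal_id[1],
               group = if ("group" %in% names(u)) u$group[1] else NA,
               ivi = u$start[-1L] - u$end[-n],
               same = u$corner[-1L] == u$corner[-n],
               corner_prev = u$corner[-n], corner_next = u$corner[-1L],
               task = if ("task" %in% names(u)) u$task[-1L] else NA,
               day = if ("day" %in% names(u)) u$day[-1L] else NA,
               stringsAsFactors = FALSE)
  }))
}

#' Rapid same-corner re-entries (short inter-visit intervals)
#'
#' Counts, per animal, consecutive visit pairs that return to the same corner
#' with an inter-visit interval (gap from the end of one visit to the start
#' of the next) strictly below `iviThreshold` (default 60 s; an IVI of
#' exactly 60 s is not counted). A pair is attributed to the unit of the
#' re-entering (second) visit.
#'
#' @param x an [IntelliCageExperiment-class] (or a visit data.frame).
#' @param iviThreshold IVI threshold, seconds (strict).
#' @param by optional grouping unit (`"task"` or `"day"`); NULL for per
#'   animal overall.
#' @return data.frame with `n_fast` (count) and `fast_per_h` (count per hour
#'   of unit duration).
#' @export
fastReentries <- function(x, iviThreshold = 60, by = NULL) {
  v <- if (methods::is(x, "IntelliCageExperiment")) visits(x) else x
  .stopIf(!nrow(v), "empty visit stream")
  p <- .pairTable(v)
  hours <- function(u) (max(u$end) - min(u$start)) / 3600
  if (is.null(by)) {
    sp <- split(p, p$animal_id)
    out <- do.call(rbind, lapply(sp, function(u) {
      va <- v[v$animal_id == u$animal_id[1], ]
      data.frame(animal_id = u$animal_id[1], group = u$group[1],
                 n_fast = sum(u$same & u$ivi < iviThreshold),
                 fast_per_h = sum(u$same & u$ivi < iviThreshold) / hours(va))
    }))
  } else {
    p$unit <- p[[by]]
    sp <- split(p, list(p$animal_id, p$unit), drop = TRUE)
    out <- do.call(rbind, lapply(sp, function(u) {
      va <- v[v$animal_id == u$animal_id[1] & v[[by]] == u$unit[1], ]
      data.frame(animal_id = u$animal_id[1], group = u$group[1],
                 unit = u$unit[1],
                 n_fast = sum(u$same & u$ivi < iviThreshold),
                 fast_per_h = sum(u$same & u$ivi < iviThreshold) / hours(va))
    }))
    names(out)[names(out) == "unit"] <- by
  }
  rownames(out) <- NULL
  out
}

#' Repetitiveness: log-ratio of observed versus expected early returns
#'
#' The compulsivity readout: per animal and task (plus overall), the observed
#' number of early returns (same-corner re-entries with IVI strictly below
#' `iviThreshold`) is compared against its expectation under a shuffle null
#' that permutes the corner-label sequence while holding every timestamp
#' fixed - preserving each corner's visit count and the empirical IVI
#' structure. The statistic is `log2(observed / expected)`; a pseudo-count of
#' 0.5 is added to both terms when either is 0 (flagged). Units with fewer
#' than `minVisits` visits are flagged undefined (NA).
#'
#' @param x an [IntelliCageExperiment-class].
#' @param iviThreshold IVI threshold, seconds (strict).
#' @param nShuffles number of label permutations.
#' @param seed integer seed (per-unit child seeds are derived).
#' @param byTask if TRUE compute per task plus an `overall` unit; if FALSE
#'   one overall value per animal.
#' @param minVisits minimum visits per unit.
#' @return data.frame: `animal_id`, `group`, `task`, `observed`, `expected`,
#'   `value`, `pseudo` (pseudo-count applied), `n_visits`.
#' @export
repetitiveness <- function(x, iviThreshold = 60, nShuffles = 1000, seed = 1,
                           byTask = TRUE, minVisits = 10) {
  v <- visits(x)
  .stopIf(!nrow(v), "empty visit stream")
  units <- list()
  for (a in unique(v$animal_id)) {
    va <- v[v$animal_id == a, , drop = FALSE]
    if (byTask) {
      for (tk in unique(va$task))
        units[[length(units) + 1L]] <-
          list(v = va[va$task == tk, , drop = FALSE], task = tk)
    }
    units[[length(units) + 1L]] <- list(v = va, task = "overall")
  }
  out <- vector("list", length(units))
  for (k in seq_along(units)) {
    u <- units[[k]]$v
    n <- nrow(u)
    res <- data.frame(animal_id = u$animal_id[1], group = u$group[1],
                      task = units[[k]]$task, observed = NA_real_,
                      expected = NA_real_, value = NA_real_, pseudo = FALSE,
                      n_visits = n)
    if (n >= minVisits) {
      u <- u[order(u$start), , drop = FALSE]
      ivi <- u$start[-1L] - u$end[-n]
      fast <- ivi < iviThreshold
      crn <- u$corner
      obs <- sum(fast & crn[-1L] == crn[-n])
      set.seed(childSeed(seed, k))
      shuf <- numeric(nShuffles)
      for (s in seq_len(nShuffles)) {
        p <- crn[sample.int(n)]
        shuf[s] <- sum(fast & p[-1L] == p[-n])
      }
      expc <- mean(shuf)
      pseudo <- obs == 0 || expc == 0
      if (pseudo) {
        obsA <- obs + 0.5
        expA <- expc + 0.5
      } else {
        obsA <- obs
        expA <- expc
      }
      res$observed <- obs
      res$expected <- expc
      res$value <- log2(obsA / expA)
      res$pseudo <- pseudo
    }
    out[[k]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Licking metrics
#'
#' Licks/h, licking duration/h and licks per visit within each (animal,
#' unit), with an optional day/night split based on the lights-on anchor
#' (12 h light phase).
#'
#' @param x an [IntelliCageExperiment-class].
#' @param by grouping unit: `"task"`, `"day"` or `"bin"`.
#' @param binWidth bin width in hours when `by = "bin"`.
#' @param dayNight if TRUE add a `phase` (day/night) split within units.
#' @return long data.frame with `licks_h`, `lick_duration_s_h`,
#'   `licks_per_visit`.
#' @export
lickMetrics <- function(x, by = "task", binWidth = 12, dayNight = FALSE) {
  v <- visits(x)
  .stopIf(!nrow(v), "empty visit stream")
  v$unit <- .unitColumn(v, x, by, binWidth)
  dayLen <- 12 * 3600
  v$phase <- ifelse(((v$start - lightsOn(x)) %% 86400) < dayLen,
                    "day", "night")
  keys <- if (dayNight) list(v$animal_id, v$unit, v$phase)
          else list(v$animal_id, v$unit)
  sp <- split(v, keys, drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(u) {
    hrs <- if (dayNight) {
      # half of each observation day is in each phase
      nDays <- length(unique(u$day))
      nDays * 12
    } else (max(u$end) - min(u$start)) / 3600
    data.frame(animal_id = u$animal_id[1], group = u$group[1],
               unit = u$unit[1],
               phase = if (dayNight) u$phase[1] else NA_character_,
               n_visits = nrow(u),
               licks_h = sum(u$lick_count) / hrs,
               lick_duration_s_h = sum(u$lick_duration_s) / hrs,
               licks_per_visit = sum(u$lick_count) / nrow(u))
  }))
  names(out)[names(out) == "unit"] <- by
  rownames(out) <- NULL
  out
}
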