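#' IntelliCage simulation configuration
#'
#' Emulates a two-group home-cage experiment on the standard task sequence:
#' free adaptation (FA), nosepoke adaptation with three correct corners
#' (NP3c), place preference learning (PPL) and its reversal (PPLrev, rewarded
#' corner switched to the opposite side). Corner choices follow a Markov
#' chain with `P(same corner) = stayProbability` and the remainder split over
#' the other corners (uniformly, or biased towards the correct set by a
#' logistic learning curve in learning tasks). Visit onsets form a Poisson
#' stream with piecewise-constant day/night rates sampled exactly by
#' thinning; the inter-visit interval is the gap between one visit's end and
#' the next visit's start. Nosepoke counts per visit are negative-binomial
#' (over-dispersed); licks attach to a visit only when the door opened in
#' door-controlled tasks, while licking in FA is unconstrained.
#'
#' Group-level defaults reflect the emulated study: 15 control and 16 treated
#' animals observed over FA (14 d), NP3c (14 d), PPL (10 d), PPLrev (10 d),
#' with the treated group showing more nosepokes per visit and roughly
#' doubled licking.
#'
#' @param nAnimalsPerGroup animals per group (length-2 vector).
#' @param groupLabels the two group labels.
#' @param stayProbability per-group probability of revisiting the same corner
#'   next (0.25 is the uniform null).
#' @param visitRateDay,visitRateNight visit rates, visits/hour (night is the
#'   active phase).
#' @param npPerVisitMean per-group mean nosepokes per visit.
#' @param npDispersion negative-binomial size parameter of nosepoke counts.
#' @param lickRate per-group mean licks per (rewarded) visit.
#' @param lickDurationMean mean duration of a single lick, seconds.
#' @param meanVisitDuration mean visit duration, seconds (gamma, shape 2).
#' @param learningCurve list(`midpoint`, `slope`, `ceiling`) of the logistic
#'   probability of choosing a correct corner over task days, or NULL for no
#'   learning (pure Markov corner choice throughout).
#' @param taskSchedule data.frame with columns `task`, `days`, in order.
#' @param dayLengthH length of the light phase, hours (12 h/12 h cycle).
#' @param seed integer seed.
#' @return a validated config list of class `ICSimConfig`.
#' @export
icSimConfig <- function(nAnimalsPerGroup = c(15, 16),
                        groupLabels = c("control", "treated"),
                        stayProbability = c(0.25, 0.25),
                        visitRateDay = 4, visitRateNight = 10,
                        npPerVisitMean = c(2, 3), npDispersion = 4,
                        lickRate = c(8, 16), lickDurationMean = 0.25,
                        meanVisitDuration = 20,
                        learningCurve = list(midpoint = 4, slope = 1,
                                             ceiling = 0.9),
                        taskSchedule = data.frame(
                          task = c("FA", "NP3c", "PPL", "PPLrev"),
                          days = c(14, 14, 10, 10)),
                        dayLengthH = 12, seed = 1) {
  .stopIf(length(nAnimalsPerGroup) != 2 || any(nAnimalsPerGroup < 1),
          "nAnimalsPerGroup must be two positive counts")
  .stopIf(any(stayProbability < 0) || any(stayProbability > 1),
          "stayProbability must be in [0, 1]")
  .stopIf(visitRateDay < 0 || visitRateNight < 0 || any(lickRate < 0) ||
            any(npPerVisitMean < 0), "rates must be non-negative")
  .stopIf(!nrow(taskSchedule), "empty task schedule")
  .stopIf(any(taskSchedule$days <= 0), "task durations must be positive")
  structure(list(nAnimalsPerGroup = as.integer(nAnimalsPerGroup),
                 groupLabels = groupLabels,
                 stayProbability = rep_len(stayProbability, 2),
                 visitRateDay = visitRateDay, visitRateNight = visitRateNight,
                 npPerVisitMean = rep_len(npPerVisitMean, 2),
                 npDispersion = npDispersion,
                 lickRate = rep_len(lickRate, 2),
                 lickDurationMean = lickDurationMean,
                 meanVisitDuration = meanVisitDuration,
                 learningCurve = learningCurve,
                 taskSchedule = taskSchedule,
                 dayLengthH = dayLengthH, seed = as.integer(seed)),
            class = "ICSimConfig")
}

# correct corner set for one animal in one task (NULL = no correct set)
.correctSet <- function(task, pplCorner) {
  switch(task,
         FA = NULL,
         NP3c = setdiff(1:4, oppositeCorner(pplCorner)),
         PPL = pplCorner,
         PPLrev = oppositeCorner(pplCorner),
         NULL)
}

#' Simulate an IntelliCage visit stream with known ground truth
#'
#' @param config an [icSimConfig()].
#' @return list with `experiment` (an [IntelliCageExperiment-class]) and
#'   `truth` (per-animal generating parameters).
#' @export
simulateIntelliCage <- function(config) {
  stopifnot(inherits(config, "ICSimConfig"))
  set.seed(config$seed)
  sched <- config$taskSchedule
  taskEnd <- cumsum(sched$days) * 86400
  taskStart <- c(0, taskEnd[-length(taskEnd)])
  schedule <- data.frame(task = sched$task, start = taskStart, end = taskEnd)
  total <- taskEnd[length(taskEnd)]
  dayLen <- config$dayLengthH * 3600
  rateDay <- config$visitRateDay / 3600   # per second
  rateNight <- config$visitRateNight / 3600
  rateMax <- max(rateDay, rateNight, 1e-12)
  isDay <- function(t) (t %% 86400) < dayLen
  lc <- config$learningCurve

  nA <- sum(config$nAnimalsPerGroup)
  ids <- sprintf("m%02d", seq_len(nA))
  grpIdx <- rep(1:2, config$nAnimalsPerGroup)
  groups <- config$groupLabels[grpIdx]
  pplCorner <- rep_len(1:4, nA)  # each ~4 mice share one corner

  allVisits <- vector("list", nA)
  for (a in seq_len(nA)) {
    g <- grpIdx[a]
    stay <- config$stayProbability[g]
    npMu <- config$npPerVisitMean[g]
    lickMu <- config$lickRate[g]
    cap <- ceiling(total / 3600 * config$visitRateNight * 1.6) + 50
    start <- numeric(cap); end <- numeric(cap); corner <- integer(cap)
    np <- integer(cap); npCorrect <- integer(cap); firstNp <- numeric(cap)
    door <- logical(cap); licks <- integer(cap); lickDur <- numeric(cap)
    taskCol <- character(cap)
    t <- 0; i <- 0L; prevCorner <- sample.int(4L, 1L)
    repeat {
      # exact thinning for the piecewise-constant visit-onset rate
      repeat {
        t <- t + stats::rexp(1, rateMax)
        if (t > total) break
        r <- if (isDay(t)) rateDay else rateNight
        if (stats::runif(1) < r / rateMax) break
      }
      if (t > total) break
      i <- i + 1L
      seg <- findInterval(t, schedule$start)
      task <- schedule$task[seg]
      dayInTask <- floor((t - schedule$start[seg]) / 86400) + 1
      correct <- .correctSet(task, pplCorner[a])
      # corner choice: stay, else pick among the other three (learning-biased)
      if (stats::runif(1) < stay) {
        crn <- prevCorner
      } else {
        others <- setdiff(1:4, prevCorner)
        w <- rep(1, 3)
        if (!is.null(correct) && !is.null(lc)) {
          chance <- length(correct) / 4
          pLearn <- chance + (lc$ceiling - chance) *
            stats::plogis(lc$slope * (dayInTask - lc$midpoint))
          wAll <- numeric(4)
          wAll[correct] <- pLearn / length(correct)
          wAll[setdiff(1:4, correct)] <- (1 - pLearn) /
            (4 - length(correct))
          w <- wAll[others]
        }
        crn <- sample(others, 1L, prob = w)
      }
      dur <- stats::rgamma(1, shape = 2, scale = config$meanVisitDuration / 2)
      dur <- max(dur, 1)
      nNp <- stats::rnbinom(1, mu = npMu, size = config$npDispersion)
      cornerCorrect <- is.null(correct) || crn %in% correct
      doorOpened <- if (task == "FA") TRUE else (nNp > 0L && cornerCorrect)
      nLick <- if (task == "FA" || doorOpened)
        stats::rpois(1, lickMu) else 0L
      start[i] <- t; end[i] <- t + dur; corner[i] <- crn
      np[i] <- nNp
      npCorrect[i] <- if (cornerCorrect) nNp else 0L
      firstNp[i] <- if (nNp > 0L) stats::runif(1, 0, min(dur, 10)) else NA_real_
      door[i] <- doorOpened
      licks[i] <- nLick
      lickDur[i] <- if (nLick > 0L)
        stats::rgamma(1, shape = nLick, scale = config$lickDurationMean) else 0
      taskCol[i] <- task
      prevCorner <- crn
      t <- t + dur  # next onset gap starts at visit end
    }
    if (i == 0L) next
    sel <- seq_len(i)
    allVisits[[a]] <- data.frame(
      animal_id = ids[a], group = groups[a], corner = corner[sel],
      start = start[sel], end = end[sel], np_count = np[sel],
      np_correct_count = npCorrect[sel], first_np_s = firstNp[sel],
      door_opened = door[sel], lick_count = licks[sel],
      lick_duration_s = lickDur[sel], task = taskCol[sel],
      day = floor(start[sel] / 86400) + 1, stringsAsFactors = FALSE)
  }
  visitsDf <- do.call(rbind, allVisits)
  assignments <- data.frame(animal_id = ids, group = groups,
                            ppl_corner = pplCorner, stringsAsFactors = FALSE)
  exp <- IntelliCageExperiment(visitsDf, schedule, assignments, lightsOn = 0)
  truth <- list(animals = data.frame(
    animal_id = ids, group = groups,
    stay_probability = config$stayProbability[grpIdx],
    np_per_visit_mean = config$npPerVisitMean[grpIdx],
    lick_rate = config$lickRate[grpIdx],
    ppl_corner = pplCorner, stringsAsFactors = FALSE),
    config = config)
  list(experiment = exp, truth = truth)
}
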