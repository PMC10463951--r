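# Behavioral feature extraction: binning conventions, IVI semantics,
# repetitiveness shuffle null, feature-matrix shape.

test_that("loadVisits validates the schema and names offending rows", {
  dir <- withr::local_tempdir()
  v <- makeVisits("a1", c(1, 2), start = c(0, 100), end = c(10, 110),
                  np = 2)
  vp <- file.path(dir, "v.csv")
  write.csv(v[, c("animal_id", "group", "corner", "start", "end",
                  "np_count", "np_correct_count", "lick_count",
                  "lick_duration_s")], vp, row.names = FALSE)
  x <- loadVisits(vp)
  expect_s4_class(x, "IntelliCageExperiment")
  expect_equal(nrow(visits(x)), 2)

  bad <- v; bad$end[2] <- 90  # end before start on row 2
  write.csv(bad[, c("animal_id", "group", "corner", "start", "end",
                    "np_count", "np_correct_count", "lick_count",
                    "lick_duration_s")], vp, row.names = FALSE)
  expect_error(loadVisits(vp), "row 2")

  bad2 <- v; bad2$corner[1] <- 7
  write.csv(bad2[, c("animal_id", "group", "corner", "start", "end",
                     "np_count", "np_correct_count", "lick_count",
                     "lick_duration_s")], vp, row.names = FALSE)
  expect_error(loadVisits(vp), "corner")

  ovl <- makeVisits("a1", c(1, 2), start = c(0, 5), end = c(10, 15))
  write.csv(ovl[, c("animal_id", "group", "corner", "start", "end",
                    "np_count", "np_correct_count", "lick_count",
                    "lick_duration_s")], vp, row.names = FALSE)
  expect_error(loadVisits(vp), "overlap")

  writeLines("animal_id,corner,start,end,np_count,np_correct_count,lick_count,lick_duration_s",
             vp)
  expect_warning(x0 <- loadVisits(vp), "empty")
  expect_equal(nrow(visits(x0)), 0)
})

test_that("the packaged 20-visit fixture loads as 2 animals", {
  vp <- system.file("extdata", "demo_visits.csv", package = "NeuroPheno")
  sp <- system.file("extdata", "demo_schedule.csv", package = "NeuroPheno")
  x <- loadVisits(vp, sp)
  expect_equal(nrow(visits(x)), 20)
  expect_length(unique(visits(x)$animal_id), 2)
  expect_equal(schedule(x)$task, "FA")
})

test_that("visit/schedule CSV round-trip preserves the experiment", {
  sim <- simulateIntelliCage(icSimConfig(
    nAnimalsPerGroup = c(2, 2),
    taskSchedule = data.frame(task = c("FA", "PPL"), days = c(1, 1)),
    seed = 5))
  dir <- withr::local_tempdir()
  vp <- file.path(dir, "v.csv"); sp <- file.path(dir, "s.csv")
  writeVisitsCSV(sim$experiment, vp, sp)
  back <- loadVisits(vp, sp)
  expect_equal(nrow(visits(back)), nrow(visits(sim$experiment)))
  expect_equal(visits(back)$corner, visits(sim$experiment)$corner)
  expect_equal(schedule(back)$task, schedule(sim$experiment)$task)
  expect_equal(cornerAssignments(back)$ppl_corner,
               cornerAssignments(sim$experiment)$ppl_corner)
})

test_that("binTimecourse uses half-open lights-on-aligned bins and conserves counts", {
  # 24 visits uniformly inside the first 12 h bin -> 2 visits/h
  starts <- seq(0, 12 * 3600 - 600, length.out = 24)
  v <- makeVisits("a1", 1, starts, starts + 30)
  x <- makeExperiment(v, totalDays = 1)
  tc <- binTimecourse(x, 12)
  expect_equal(tc$visits_h[tc$bin == 1], 2.0)
  expect_equal(sum(tc$n_visits), 24)

  # a visit starting exactly on a bin edge belongs to the later bin
  v2 <- makeVisits("a1", 1, c(100, 12 * 3600), c(200, 12 * 3600 + 60))
  tc2 <- binTimecourse(makeExperiment(v2, totalDays = 1), 12)
  expect_equal(tc2$n_visits[tc2$bin == 1], 1)
  expect_equal(tc2$n_visits[tc2$bin == 2], 1)

  # conservation across all rate columns
  sim <- simulateIntelliCage(icSimConfig(
    nAnimalsPerGroup = c(2, 2),
    taskSchedule = data.frame(task = "FA", days = 3), seed = 7))
  tc3 <- binTimecourse(sim$experiment, 12)
  v3 <- visits(sim$experiment)
  expect_equal(sum(tc3$n_visits), nrow(v3))
  expect_equal(sum(tc3$np), sum(v3$np_count))
  expect_equal(sum(tc3$licks), sum(v3$lick_count))
  expect_error(binTimecourse(sim$experiment, 0), "binWidth")
})

test_that("npPerVisit is total pokes over total visits; empty units missing", {
  starts <- seq(0, 900, by = 100)
  v <- makeVisits("a1", 1, starts, starts + 50, np = 3)
  x <- makeExperiment(v, totalDays = 1)
  r <- npPerVisit(x, by = "day")
  expect_equal(r$np_per_visit, 3.0)

  # no zero-visit rows are fabricated for empty bins
  rb <- npPerVisit(x, by = "bin")
  expect_true(all(rb$n_visits > 0))
})

test_that("correctVisitFraction respects task-specific correct sets", {
  # constructed: animal assigned PPL corner 1 -> PPLrev corner 3,
  # NP3c correct set {1, 2, 4}
  starts <- seq(0, 990, by = 90)
  v <- makeVisits("a1", rep(c(1, 2, 3, 4), length.out = length(starts)),
                  starts, starts + 30, task = "NP3c")
  x <- IntelliCageExperiment(
    v, data.frame(task = "NP3c", start = 0, end = 86400),
    data.frame(animal_id = "a1", group = "g1", ppl_corner = 1))
  r <- correctVisitFraction(x)
  expect_equal(r$correct_fraction, mean(v$corner %in% c(1, 2, 4)))

  # all visits to the assigned corner in PPL -> fraction 1
  vp <- makeVisits("a1", 1, starts, starts + 30, task = "PPL")
  xp <- IntelliCageExperiment(
    vp, data.frame(task = "PPL", start = 0, end = 86400),
    data.frame(animal_id = "a1", group = "g1", ppl_corner = 1))
  expect_equal(correctVisitFraction(xp)$correct_fraction, 1.0)

  # FA visits are excluded, not an error
  vf <- makeVisits("a1", 1, starts, starts + 30, task = "FA")
  xf <- makeExperiment(vf, totalDays = 1)
  expect_equal(nrow(correctVisitFraction(xf)), 0)
})

test_that("uniform random corners give chance-level correct fractions", {
  # binomial checks: 1 of 4 corners correct (PPL) and 3 of 4 (NP3c)
  set.seed(101)
  n <- 10000
  starts <- seq(0, by = 8, length.out = n)
  v <- makeVisits("a1", sample(1:4, n, replace = TRUE), starts, starts + 4,
                  task = "PPL")
  v$day <- 1  # single day unit
  x <- IntelliCageExperiment(
    v, data.frame(task = "PPL", start = 0, end = max(v$end) + 1),
    data.frame(animal_id = "a1", group = "g1", ppl_corner = 2))
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(correctVisitFraction(x)$correct_fraction - 0.25), 3 * se)

  v$task <- "NP3c"
  x3 <- IntelliCageExperiment(
    v, data.frame(task = "NP3c", start = 0, end = max(v$end) + 1),
    data.frame(animal_id = "a1", group = "g1", ppl_corner = 2))
  expect_lt(abs(correctVisitFraction(x3)$correct_fraction - 0.75), 3 * se)
})

test_that("fastReentries uses end-to-start gaps with a strict 60 s bound", {
  # A[0,10], A[30,40], B[200,210]: one fast re-entry (gap 20 s)
  v <- makeVisits("a1", c(1, 1, 2), start = c(0, 30, 200),
                  end = c(10, 40, 210))
  x <- makeExperiment(v, totalDays = 1)
  expect_equal(fastReentries(x)$n_fast, 1)

  # gap exactly 60 s is not counted
  v60 <- makeVisits("a1", c(1, 1), start = c(0, 70), end = c(10, 80))
  expect_equal(fastReentries(makeExperiment(v60, totalDays = 1))$n_fast, 0)
  v59 <- makeVisits("a1", c(1, 1), start = c(0, 69.9), end = c(10, 80))
  expect_equal(fastReentries(makeExperiment(v59, totalDays = 1))$n_fast, 1)

  # strictly alternating corners: zero
  starts <- seq(0, 990, by = 30)
  va <- makeVisits("a1", rep(c(1, 2), length.out = length(starts)),
                   starts, starts + 10)
  expect_equal(fastReentries(makeExperiment(va, totalDays = 1))$n_fast, 0)
})

test_that("fastReentries is invariant under global time translation", {
  sim <- simulateIntelliCage(icSimConfig(
    nAnimalsPerGroup = c(1, 1),
    taskSchedule = data.frame(task = "FA", days = 2), seed = 11))
  v <- visits(sim$experiment)
  f1 <- fastReentries(sim$experiment)
  v2 <- v; v2$start <- v2$start + 12345; v2$end <- v2$end + 12345
  x2 <- IntelliCageExperiment(v2, data.frame(task = "FA", start = 0,
                                             end = max(v2$end) + 1))
  f2 <- fastReentries(x2)
  expect_equal(f1$n_fast, f2$n_fast)
})

test_that("repetitiveness is 0 when observed equals expected, NA when sparse", {
  # deterministic alternation: observed 0 -> pseudo-count kicks in
  starts <- seq(0, by = 30, length.out = 40)
  v <- makeVisits("a1", rep(c(1, 2), 20), starts, starts + 10)
  r <- repetitiveness(makeExperiment(v, totalDays = 1), nShuffles = 200,
                      seed = 1, byTask = FALSE)
  expect_true(r$pseudo)
  expect_lt(r$value, 0)  # fewer returns than expected under shuffling

  # fewer than 10 visits: flagged undefined
  vs <- makeVisits("a1", 1, c(0, 100), c(10, 110))
  rs <- repetitiveness(makeExperiment(vs, totalDays = 1), nShuffles = 50,
                       byTask = FALSE)
  expect_true(is.na(rs$value))
})

test_that("repetitiveness null is centred at 0 and increases with stay probability", {
  vals <- sapply(c(0.25, 0.4, 0.6), function(p) {
    sim <- simulateIntelliCage(icSimConfig(
      nAnimalsPerGroup = c(1, 1), stayProbability = p,
      visitRateDay = 60, visitRateNight = 60, learningCurve = NULL,
      taskSchedule = data.frame(task = "FA", days = 2), seed = 303))
    r <- repetitiveness(sim$experiment, nShuffles = 1000, seed = 7,
                        byTask = FALSE)
    mean(r$value)
  })
  expect_lt(abs(vals[1]), 0.12)        # near 0 under the uniform null
  expect_true(all(diff(vals) > 0))     # monotone in stay probability
  expect_gt(vals[3], 1)                # log2(0.6/0.25) ~ 1.26
})

test_that("lick metrics normalize by unit hours and split day/night", {
  # 120 licks in one 12 h bin -> 10 licks/h
  starts <- seq(0, 12 * 3600 - 600, length.out = 12)
  v <- makeVisits("a1", 1, starts, starts + 30, licks = 10, lickDur = 2.5)
  x <- makeExperiment(v, totalDays = 1)
  lm <- lickMetrics(x, by = "bin", dayNight = TRUE)
  expect_equal(lm$licks_h[lm$phase == "day"], 120 / 12)
  expect_equal(lm$licks_per_visit, 10)

  vz <- makeVisits("a1", 1, starts, starts + 30, licks = 0)
  lz <- lickMetrics(makeExperiment(vz, totalDays = 1), by = "task")
  expect_equal(lz$licks_h, 0)
})

test_that("doubled generator lick rate doubles licks/h between groups", {
  sim <- simulateIntelliCage(icSimConfig(
    nAnimalsPerGroup = c(6, 6), lickRate = c(8, 16),
    npPerVisitMean = c(2, 2), learningCurve = NULL,
    taskSchedule = data.frame(task = "FA", days = 4), seed = 13))
  lm <- lickMetrics(sim$experiment, by = "task")
  m <- tapply(lm$licks_h, lm$group, mean)
  expect_equal(unname(m["treated"] / m["control"]), 2, tolerance = 0.1)
})

test_that("task feature matrix has five task-level values per parameter", {
  sim <- simulateIntelliCage(icSimConfig(
    nAnimalsPerGroup = c(2, 2),
    taskSchedule = data.frame(task = c("FA", "NP3c", "PPL", "PPLrev"),
                              days = c(2, 2, 2, 2)), seed = 17))
  fm <- taskFeatureMatrix(sim$experiment, nShuffles = 100, seed = 1)
  params <- attr(fm, "parameters")
  expect_equal(nrow(fm), 4)  # one row per animal
  expect_equal(ncol(fm), length(params) * 5)
  for (p in params)
    expect_length(grep(paste0("^", p, "\\."), colnames(fm)), 5)
  expect_error(taskFeatureMatrix(sim$experiment, parameters = "nope"),
               "unknown parameter")
})

test_that("constant behavior makes every task mean equal the overall mean", {
  # identical visit pattern every day across two tasks
  day <- function(d, task) {
    starts <- (d - 1) * 86400 + seq(0, 86000, by = 2000)
    makeVisits("a1", rep(c(1, 2, 3, 4), length.out = length(starts)),
               starts, starts + 60, np = 2, licks = 4, lickDur = 1,
               task = task)
  }
  v <- rbind(day(1, "FA"), day(2, "FA"), day(3, "NP3c"), day(4, "NP3c"))
  x <- IntelliCageExperiment(
    v, data.frame(task = c("FA", "NP3c"), start = c(0, 2 * 86400),
                  end = c(2 * 86400, 4 * 86400)),
    data.frame(animal_id = "a1", group = "g1", ppl_corner = 1))
  fm <- taskFeatureMatrix(x, parameters = c("np_per_visit", "licks_h",
                                            "frac_visits_with_np"),
                          nShuffles = 50)
  for (p in c("np_per_visit", "licks_h", "frac_visits_with_np")) {
    cols <- grep(paste0("^", p, "\\."), colnames(fm))
    expect_equal(var(as.numeric(fm[1, cols])), 0, tolerance = 1e-20)
  }
})

test_that("metrics are equivariant under animal relabeling", {
  sim <- simulateIntelliCage(icSimConfig(
    nAnimalsPerGroup = c(2, 2),
    taskSchedule = data.frame(task = "FA", days = 2), seed = 19))
  v <- visits(sim$experiment)
  f1 <- fastReentries(sim$experiment)
  # swap two animal labels
  v2 <- v
  v2$animal_id[v$animal_id == "m01"] <- "zz"
  v2$animal_id[v$animal_id == "m03"] <- "m01"
  v2$animal_id[v2$animal_id == "zz"] <- "m03"
  x2 <- IntelliCageExperiment(v2, schedule(sim$experiment))
  f2 <- fastReentries(x2)
  expect_equal(f1$n_fast[f1$animal_id == "m01"],
               f2$n_fast[f2$animal_id == "m03"])
  expect_equal(f1$n_fast[f1$animal_id == "m03"],
               f2$n_fast[f2$animal_id == "m01"])
})
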