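#' Pipeline configuration with protocol defaults
#'
#' One nested configuration for all stages. Analysis defaults are the
#' protocol values: 5x-SD spike threshold and 100-spikes-per-5-min activity
#' rule behind a 200 Hz second-order highpass; 10% / 20% calcium thresholds
#' with 5-sample runs; 60 s IVI bound, 12 h bins and 1000 shuffles for the
#' behavioral stage. Simulation sizes here are a reduced demo regime so a
#' full pipeline run stays interactive; pass the generator configs directly
#' for study-scale simulations.
#'
#' @param seed global seed; stage seeds are derived with [childSeed()].
#' @param mea,calcium,icage,lipids named lists overriding stage defaults.
#' @return nested config list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(seed = 1, mea = list(), calcium = list(),
                           icage = list(), lipids = list()) {
  def <- list(
    seed = as.integer(seed),
    mea = list(nChannels = 8, duration = 60, samplingRate = 50000,
               spikeRates = 1, spikeAmplitude = 8, cutoff = 200,
               filterOrder = 2, thresholdMultiple = 5, deadTime = 0.001,
               minSpikes = 100, referenceDuration = 300),
    calcium = list(nNeurons = 60, capsThreshold = 1.10, kclThreshold = 1.20,
                   minRun = 5),
    icage = list(nAnimalsPerGroup = c(4, 4),
                 taskDays = c(FA = 3, NP3c = 3, PPL = 2, PPLrev = 2),
                 iviThreshold = 60, binWidth = 12, nShuffles = 1000),
    lipids = list(nSpecies = 100, affectedSpecies = 1:5, log2Effect = -1,
                  cv = 0.1))
  def$mea[names(mea)] <- mea
  def$calcium[names(calcium)] <- calcium
  def$icage[names(icage)] <- icage
  def$lipids[names(lipids)] <- lipids
  .validatePipelineConfig(structure(def, class = "PipelineConfig"))
}

.validatePipelineConfig <- function(config) {
  num <- c("thresholdMultiple", "minSpikes", "cutoff")
  for (k in num)
    .stopIf(config$mea[[k]] <= 0, "invalid config: mea$%s must be positive", k)
  .stopIf(config$calcium$capsThreshold <= 1 || config$calcium$kclThreshold <= 1,
          "invalid config: calcium thresholds are folds over baseline (> 1)")
  .stopIf(config$icage$iviThreshold <= 0,
          "invalid config: icage$iviThreshold must be positive")
  config
}

#' Read / write a pipeline configuration (YAML)
#'
#' Configurations round-trip losslessly through YAML.
#'
#' @param config a [pipelineConfig()].
#' @param path YAML file path.
#' @return (invisibly) the path; `readPipelineConfig` returns the config.
#' @export
writePipelineConfig <- function(config, path) {
  raw <- unclass(config)
  raw$icage$taskDays <- as.list(raw$icage$taskDays)  # keep names in YAML
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$icage$taskDays))  # YAML maps load as lists
    raw$icage$taskDays <- unlist(raw$icage$taskDays)
  pipelineConfig(seed = raw$seed, mea = raw$mea, calcium = raw$calcium,
                 icage = raw$icage, lipids = raw$lipids)
}

#' Run the analysis pipeline on synthetic data
#'
#' Orchestrates the stages (`mea`, `calcium`, `icage`, `lipids`, or `all`):
#' simulates each requested modality with a stage seed derived from the
#' global seed, runs the corresponding analysis, writes stage outputs under
#' `outDir` (`mea/`, `calcium/`, `icage/`, `lipids/`) and records a
#' `manifest.json` with the configuration, seeds, package version and every
#' output file. Outputs are deterministic for a fixed seed; a stage failure
#' halts only that stage's dependents.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @param stages character vector of stages, or `"all"`.
#' @return (invisibly) the manifest list.
#' @export
runPipeline <- function(config, outDir, stages = "all") {
  stopifnot(inherits(config, "PipelineConfig"))
  all <- c("mea", "calcium", "icage", "lipids")
  if (identical(stages, "all")) stages <- all
  .stopIf(!all(stages %in% all), "unknown stage(s): %s",
          paste(setdiff(stages, all), collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "NeuroPheno",
                   version = as.character(utils::packageVersion("NeuroPheno")),
                   seed = config$seed, config = unclass(config),
                   stages = list())
  for (stage in stages) {
    sdir <- file.path(outDir, stage)
    dir.create(sdir, showWarnings = FALSE)
    seed <- childSeed(config$seed, match(stage, all))
    outputs <- switch(stage,
      mea = .runMeaStage(config$mea, sdir, seed),
      calcium = .runCalciumStage(config$calcium, sdir, seed),
      icage = .runIcageStage(config$icage, sdir, seed),
      lipids = .runLipidStage(config$lipids, sdir, seed))
    manifest$stages[[stage]] <- list(seed = seed, outputs = outputs)
  }
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

.runMeaStage <- function(p, dir, seed) {
  cfg <- meaSimConfig(nChannels = p$nChannels, duration = p$duration,
                      samplingRate = p$samplingRate, spikeRates = p$spikeRates,
                      spikeAmplitude = p$spikeAmplitude, seed = seed)
  sim <- simulateMEARecording(cfg)
  summ <- summarizeSlice(sim$recording, cutoff = p$cutoff,
                         filterOrder = p$filterOrder,
                         thresholdMultiple = p$thresholdMultiple,
                         deadTime = p$deadTime, minSpikes = p$minSpikes,
                         referenceDuration = p$referenceDuration)
  f1 <- file.path(dir, "channel_summary.csv")
  utils::write.csv(summ, f1, row.names = FALSE)
  f2 <- file.path(dir, "slice_summary.json")
  jsonlite::write_json(list(n_active = attr(summ, "nActive"),
                            n_channels = nrow(summ),
                            duration_s = attr(summ, "duration"),
                            mean_mua_hz_active =
                              mean(summ$mua_hz[summ$active])),
                       f2, auto_unbox = TRUE, digits = NA)
  c(f1, f2)
}

.runCalciumStage <- function(p, dir, seed) {
  sim <- simulateCalciumTraces(caSimConfig(nNeurons = p$nNeurons, seed = seed))
  calls <- callPeaks(sim$traces, capsThreshold = p$capsThreshold,
                     kclThreshold = p$kclThreshold, minRun = p$minRun)
  f1 <- file.path(dir, "peak_calls.csv")
  utils::write.csv(calls, f1, row.names = FALSE)
  f2 <- file.path(dir, "population_summary.csv")
  utils::write.csv(summarizePopulation(calls), f2, row.names = FALSE)
  c(f1, f2)
}

.runIcageStage <- function(p, dir, seed) {
  ts <- data.frame(task = names(p$taskDays), days = as.numeric(p$taskDays))
  sim <- simulateIntelliCage(icSimConfig(
    nAnimalsPerGroup = p$nAnimalsPerGroup, taskSchedule = ts, seed = seed))
  x <- sim$experiment
  f1 <- file.path(dir, "visits.csv")
  f1b <- file.path(dir, "schedule.csv")
  writeVisitsCSV(x, f1, f1b)
  f2 <- file.path(dir, "timecourse_12h.csv")
  utils::write.csv(binTimecourse(x, p$binWidth), f2, row.names = FALSE)
  f3 <- file.path(dir, "feature_matrix.csv")
  fm <- taskFeatureMatrix(x, iviThreshold = p$iviThreshold,
                          nShuffles = p$nShuffles, seed = seed)
  utils::write.csv(data.frame(animal_id = rownames(fm),
                              group = attr(fm, "groups"), fm,
                              check.names = FALSE),
                   f3, row.names = FALSE)
  c(f1, f1b, f2, f3)
}

.runLipidStage <- function(p, dir, seed) {
  sim <- simulateLipidTable(lipidSimConfig(
    nSpecies = p$nSpecies, affectedSpecies = p$affectedSpecies,
    log2Effect = p$log2Effect, cv = p$cv, seed = seed))
  f1 <- file.path(dir, "lipid_table.csv")
  writeLipidCSV(sim$table, f1)
  f2 <- file.path(dir, "volcano.csv")
  utils::write.csv(volcanoTable(sim$table), f2, row.names = FALSE)
  c(f1, f2)
}
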