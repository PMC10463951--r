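#' Lipid-table simulation configuration
#'
#' Emulates a samples x species AUC/IS feature table for two groups of the
#' study's size (15/16 samples), with log-normal intensities and a planted
#' log2 shift in a subset of species in the second group.
#'
#' @param nSamplesPerGroup samples per group (length-2 vector, each >= 2; a
#'   two-sample t-test is undefined below that).
#' @param nSpecies number of lipid species.
#' @param affectedSpecies indices of species carrying the planted effect.
#' @param log2Effect signed log2 shift applied to affected species in the
#'   second group (negative = reduced).
#' @param cv coefficient of variation of the log-normal noise.
#' @param groupLabels the two group labels.
#' @param seed integer seed.
#' @return a validated config list of class `LipidSimConfig`.
#' @export
lipidSimConfig <- function(nSamplesPerGroup = c(15, 16), nSpecies = 200,
                           affectedSpecies = 1:10, log2Effect = -1, cv = 0.1,
                           groupLabels = c("control", "treated"), seed = 1) {
  .stopIf(length(nSamplesPerGroup) != 2 || any(nSamplesPerGroup < 2),
          "need at least 2 samples per group (t-test undefined otherwise)")
  .stopIf(cv <= 0, "cv must be positive")
  .stopIf(length(affectedSpecies) > 0 &&
            !all(affectedSpecies %in% seq_len(nSpecies)),
          "affectedSpecies must be a subset of the species indices")
  structure(list(nSamplesPerGroup = as.integer(nSamplesPerGroup),
                 nSpecies = as.integer(nSpecies),
                 affectedSpecies = as.integer(affectedSpecies),
                 log2Effect = log2Effect, cv = cv,
                 groupLabels = groupLabels, seed = as.integer(seed)),
            class = "LipidSimConfig")
}

# lipid-style species names: CLASS(C:D)
.speciesNames <- function(n) {
  classes <- c("SM", "PC", "PE", "LPC", "Cer", "HexCer", "PS", "PI")
  cls <- rep_len(classes, n)
  carbons <- 30 + (seq_len(n) * 7) %% 15
  dbl <- seq_len(n) %% 5
  make.unique(sprintf("%s(%d:%d)", cls, carbons, dbl), sep = "_")
}

#' Simulate a lipid feature table with planted group effects
#'
#' Intensities are log-normal around per-species base abundances; the
#' affected species are multiplied by `2^log2Effect` in the second group.
#'
#' @param config a [lipidSimConfig()].
#' @return list with `table` (a [LipidTable-class]) and `truth`
#'   (`affected` indices and `species` names).
#' @export
simulateLipidTable <- function(config) {
  stopifnot(inherits(config, "LipidSimConfig"))
  set.seed(config$seed)
  nS <- sum(config$nSamplesPerGroup)
  groups <- rep(config$groupLabels, config$nSamplesPerGroup)
  species <- .speciesNames(config$nSpecies)
  baseMu <- stats::rlnorm(config$nSpecies, meanlog = 2, sdlog = 1)
  sdlog <- sqrt(log(1 + config$cv^2))
  m <- matrix(stats::rlnorm(nS * config$nSpecies, meanlog = 0, sdlog = sdlog),
              nrow = nS)
  m <- sweep(m, 2, baseMu, "*")
  inB <- groups == config$groupLabels[2]
  if (length(config$affectedSpecies))
    m[inB, config$affectedSpecies] <-
      m[inB, config$affectedSpecies] * 2^config$log2Effect
  colnames(m) <- species
  rownames(m) <- sprintf("s%02d", seq_len(nS))
  list(table = LipidTable(m, groups, species),
       truth = list(affected = config$affectedSpecies,
                    species = species[config$affectedSpecies]))
}
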