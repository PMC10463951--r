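#' Write / read an MEA recording as raw binary plus JSON sidecar
#'
#' The on-disk container is a little-endian float32 binary of the voltage
#' matrix (sample-major, channel by channel) with a JSON sidecar holding
#' sampling rate, dimensions, channel ids and metadata.
#'
#' @param x an [MEARecording-class].
#' @param prefix path prefix; writes `<prefix>.bin` and `<prefix>.json`.
#' @return (invisibly) the two file paths.
#' @export
writeMEABinary <- function(x, prefix) {
  bin <- paste0(prefix, ".bin")
  con <- file(bin, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(voltages(x))), con, size = 4L, endian = "little")
  meta <- list(n_channels = nrow(voltages(x)), n_samples = ncol(voltages(x)),
               sampling_rate = samplingRate(x), channel_ids = channelIds(x),
               slice_id = x@sliceId, group = x@group, dtype = "float32")
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(c(bin, paste0(prefix, ".json")))
}

#' @rdname writeMEABinary
#' @param prefix path prefix used at write time.
#' @return an [MEARecording-class].
#' @export
readMEABinary <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  n <- meta$n_channels * meta$n_samples
  v <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  MEARecording(t(matrix(v, nrow = meta$n_samples)), meta$sampling_rate,
               meta$channel_ids, meta$slice_id, meta$group)
}

#' Write / read calcium traces as CSV
#'
#' Layout: optional metadata comment lines `#animal,<id per neuron>` and
#' `#group,<label per neuron>`, then a header `time_s,<neuron ids>` and one
#' row per time point.
#'
#' @param x a [CalciumTraceSet-class].
#' @param path output file.
#' @return (invisibly) the path.
#' @export
writeCalciumCSV <- function(x, path) {
  info <- neuronInfo(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(c("#animal", info$animal_id), collapse = ","),
               paste(c("#group", info$group), collapse = ",")), con)
  df <- data.frame(time_s = traceTimes(x), traceRatios(x))
  names(df) <- c("time_s", info$neuron_id)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCalciumCSV
#' @return a [CalciumTraceSet-class].
#' @export
readCalciumCSV <- function(path) {
  lines <- readLines(path)
  metaLines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (l in metaLines) {
    parts <- strsplit(sub("^#", "", l), ",")[[1]]
    meta[[parts[1]]] <- parts[-1]
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        check.names = FALSE)
  ratios <- as.matrix(df[, -1, drop = FALSE])
  ids <- colnames(ratios)
  info <- data.frame(
    neuron_id = ids,
    animal_id = if (!is.null(meta$animal)) meta$animal else "unknown",
    group = if (!is.null(meta$group)) meta$group else "unknown",
    stringsAsFactors = FALSE)
  CalciumTraceSet(df$time_s, ratios, info)
}

#' Load an IntelliCage visit stream from CSV
#'
#' Documented visit schema (one row per visit): `animal_id`, `corner` (1-4),
#' `start`, `end` (seconds from the lights-on anchor, or ISO-8601
#' timestamps), `np_count`, `np_correct_count`, `lick_count`,
#' `lick_duration_s`; optional `group`, `first_np_s`, `door_opened`.
#' Companion schedule CSV: `task`, `start`, `end` (same time base),
#' `animal_id`, `correct_corner` (the PPL corner; one row per task x animal).
#'
#' Schema violations (end before start, unknown corner, per-animal visit
#' overlap) abort with the offending row number; an empty file yields an
#' empty stream with a warning.
#'
#' @param visitPath visit CSV path.
#' @param schedulePath schedule CSV path (NULL derives a single FA segment
#'   spanning the data).
#' @param lightsOnHour hour of lights-on used to anchor ISO timestamps.
#' @return an [IntelliCageExperiment-class].
#' @export
loadVisits <- function(visitPath, schedulePath = NULL, lightsOnHour = 0) {
  v <- utils::read.csv(visitPath, stringsAsFactors = FALSE)
  if (!nrow(v)) {
    warning("empty visit file: ", visitPath)
    v <- data.frame(animal_id = character(0), corner = integer(0),
                    start = numeric(0), end = numeric(0),
                    np_count = integer(0), np_correct_count = integer(0),
                    lick_count = integer(0), lick_duration_s = numeric(0))
  }
  need <- c("animal_id", "corner", "start", "end", "np_count",
            "np_correct_count", "lick_count", "lick_duration_s")
  miss <- setdiff(need, names(v))
  .stopIf(length(miss) > 0, "visit file misses columns: %s",
          paste(miss, collapse = ", "))
  toSec <- function(z) {
    if (is.numeric(z)) return(z)
    tt <- as.POSIXct(z, tz = "UTC")
    .stopIf(anyNA(tt), "unparseable timestamps in visit file")
    anchor <- trunc(min(tt), "days") + lightsOnHour * 3600
    as.numeric(difftime(tt, anchor, units = "secs"))
  }
  v$start <- toSec(v$start)
  v$end <- toSec(v$end)
  if (nrow(v)) {
    bad <- which(v$end <= v$start)
    .stopIf(length(bad) > 0, "row %d: visit end is not after start", bad[1])
    bad <- which(!v$corner %in% 1:4)
    .stopIf(length(bad) > 0, "row %d: unknown corner %s", bad[1],
            v$corner[bad[1]])
    v$row <- seq_len(nrow(v))
    for (a in unique(v$animal_id)) {
      va <- v[v$animal_id == a, ]
      va <- va[order(va$start), ]
      ov <- which(va$start[-1] < va$end[-nrow(va)])
      .stopIf(length(ov) > 0,
              "row %d: visit overlaps previous visit of animal %s",
              va$row[ov[1] + 1], a)
    }
    v$row <- NULL
  }
  if (!"group" %in% names(v)) v$group <- rep("unknown", nrow(v))
  if (!"first_np_s" %in% names(v)) v$first_np_s <- rep(NA_real_, nrow(v))
  if (!"door_opened" %in% names(v)) v$door_opened <- v$np_count > 0
  assignments <- NULL
  if (!is.null(schedulePath)) {
    s <- utils::read.csv(schedulePath, stringsAsFactors = FALSE)
    s$start <- toSec(s$start)
    s$end <- toSec(s$end)
    schedule <- unique(s[, c("task", "start", "end")])
    schedule <- schedule[order(schedule$start), ]
    if (all(c("animal_id", "correct_corner") %in% names(s))) {
      ppl <- s[s$task == "PPL", c("animal_id", "correct_corner")]
      if (nrow(ppl)) {
        assignments <- data.frame(
          animal_id = ppl$animal_id,
          group = if (nrow(v)) v$group[match(ppl$animal_id, v$animal_id)]
                  else "unknown",
          ppl_corner = ppl$correct_corner, stringsAsFactors = FALSE)
      }
    }
  } else {
    hi <- if (nrow(v)) max(v$end) else 86400
    schedule <- data.frame(task = "FA", start = 0, end = hi)
  }
  if (nrow(v)) {
    seg <- findInterval(v$start, schedule$start)
    seg[seg < 1L] <- 1L
    v$task <- schedule$task[seg]
    v$day <- floor(v$start / 86400) + 1
  } else {
    v$task <- character(0)
    v$day <- numeric(0)
  }
  IntelliCageExperiment(v, schedule, assignments, lightsOn = 0)
}

#' Write an IntelliCage experiment to visit + schedule CSVs
#'
#' @param x an [IntelliCageExperiment-class].
#' @param visitPath,schedulePath output paths (schedule skipped when NULL).
#' @return (invisibly) the visit path.
#' @export
writeVisitsCSV <- function(x, visitPath, schedulePath = NULL) {
  v <- visits(x)
  cols <- c("animal_id", "group", "corner", "start", "end", "np_count",
            "np_correct_count", "first_np_s", "door_opened", "lick_count",
            "lick_duration_s")
  utils::write.csv(v[, intersect(cols, names(v))], visitPath,
                   row.names = FALSE)
  if (!is.null(schedulePath)) {
    s <- schedule(x)
    asg <- cornerAssignments(x)
    rows <- merge(s, asg[, c("animal_id", "ppl_corner")])
    names(rows)[names(rows) == "ppl_corner"] <- "correct_corner"
    utils::write.csv(rows[, c("task", "start", "end", "animal_id",
                              "correct_corner")],
                     schedulePath, row.names = FALSE)
  }
  invisible(visitPath)
}

#' Write / read a lipid table as CSV
#'
#' Layout: first column `sample`, second `group`, then one column per
#' species.
#'
#' @param x a [LipidTable-class].
#' @param path file path.
#' @return (invisibly) the path.
#' @export
writeLipidCSV <- function(x, path) {
  m <- intensities(x)
  df <- data.frame(sample = rownames(m), group = sampleGroups(x), m,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLipidCSV
#' @return a [LipidTable-class].
#' @export
readLipidCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$sample
  LipidTable(m, df$group)
}
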