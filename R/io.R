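#' Write a mono waveform as 32-bit float WAV with a JSON sidecar
#'
#' Minimal RIFF/WAVE writer (IEEE float, mono). WAV headers store integer
#' sample rates, but the nominal acquisition rate here (97656.25 Hz) is not
#' an integer; the true rate is therefore written to a JSON sidecar
#' (\code{<path>.json}) which takes precedence on reading.
#'
#' @param wave a [Waveform-class].
#' @param path output path (".wav").
#' @return \code{path}, invisibly.
#' @export
writeWaveform <- function(wave, path) {
  x <- samples(wave)
  sr <- sampleRate(wave)
  srInt <- as.integer(round(sr))
  con <- file(path, "wb")
  on.exit(close(con))
  dataBytes <- 4L * length(x)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataBytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")   # IEEE float
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(srInt, con, size = 4, endian = "little")
  writeBin(srInt * 4L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(dataBytes, con, size = 4, endian = "little")
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  jsonlite::write_json(list(sampleRate = sr, nSamples = length(x)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a mono WAV file (with sidecar rate override)
#'
#' Reads 32-bit IEEE-float or 16-bit PCM mono WAV. If \code{<path>.json}
#' exists, its \code{sampleRate} (which can carry a non-integer true rate)
#' overrides the integer header rate.
#'
#' @param path input ".wav" path.
#' @return A [Waveform-class].
#' @export
readWaveform <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAV file: ", path)
  fmt <- NULL; samplesRaw <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!length(id) || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audioFormat = readBin(con, "integer", 1, 2, endian = "little"),
        channels = readBin(con, "integer", 1, 2, endian = "little"),
        sampleRate = readBin(con, "integer", 1, 4, endian = "little"),
        byteRate = readBin(con, "integer", 1, 4, endian = "little"),
        blockAlign = readBin(con, "integer", 1, 2, endian = "little"),
        bits = readBin(con, "integer", 1, 2, endian = "little"))
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (id == "data") {
      if (is.null(fmt)) stop("malformed WAV: data before fmt chunk")
      if (fmt$channels != 1)
        stop("only mono WAV is supported (file has ", fmt$channels,
             " channels)")
      n <- sz %/% (fmt$bits %/% 8)
      samplesRaw <- if (fmt$audioFormat == 3 && fmt$bits == 32) {
        readBin(con, "numeric", n, size = 4, endian = "little")
      } else if (fmt$audioFormat == 1 && fmt$bits == 16) {
        readBin(con, "integer", n, size = 2, signed = TRUE,
                endian = "little") / 32768
      } else stop("unsupported WAV encoding (format ", fmt$audioFormat,
                  ", ", fmt$bits, " bit)")
      break
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
  }
  if (is.null(samplesRaw)) stop("no data chunk found in ", path)
  sr <- fmt$sampleRate
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$sampleRate)) sr <- as.numeric(meta$sampleRate)
  }
  Waveform(samplesRaw, sr)
}

eventSchemaVersion <- "1.0"

#' Write an EventTrainSet to a JSON container
#'
#' Hierarchical schema: \code{units[[i]]$cf}, \code{units[[i]]$trials[[j]]}
#' with parallel \code{times} (seconds, sorted) and \code{labels}
#' ("success"/"failure"), plus \code{duration}, \code{n_trials} and a
#' \code{schema_version} field.
#'
#' @param events an [EventTrainSet-class].
#' @param path output ".json" path.
#' @return \code{path}, invisibly.
#' @export
writeEvents <- function(events, path) {
  ev <- eventTable(events)
  unitsList <- lapply(seq_len(nUnits(events)), function(u) {
    trials <- lapply(seq_len(nTrials(events)), function(j) {
      e <- ev[ev$unit == u & ev$trial == j, , drop = FALSE]
      list(times = e$time, labels = e$label)
    })
    list(cf = events@units$cf[u], trials = trials)
  })
  jsonlite::write_json(
    list(schema_version = eventSchemaVersion, duration = duration(events),
         n_trials = nTrials(events), units = unitsList),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an EventTrainSet from a JSON container
#'
#' Validates the schema version, label values and within-trial time
#' ordering; validation errors name the offending unit and trial.
#'
#' @param path input ".json" path.
#' @return An [EventTrainSet-class].
#' @export
readEvents <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  need <- c("schema_version", "duration", "n_trials", "units")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("event container missing fields: ", paste(miss, collapse = ", "))
  if (!identical(as.character(d$schema_version), eventSchemaVersion))
    stop("unsupported event schema version: ", d$schema_version)
  rows <- list(); k <- 0L
  cfs <- numeric(length(d$units))
  for (u in seq_along(d$units)) {
    uu <- d$units[[u]]
    if (is.null(uu$cf)) stop("unit ", u, ": missing cf")
    cfs[u] <- as.numeric(uu$cf)
    for (j in seq_along(uu$trials)) {
      tr <- uu$trials[[j]]
      tt <- as.numeric(unlist(tr$times))
      lb <- as.character(unlist(tr$labels))
      if (length(tt) != length(lb))
        stop("unit ", u, " trial ", j, ": times/labels length mismatch")
      if (length(tt) > 1 && any(diff(tt) <= 0))
        stop("unit ", u, " trial ", j, ": times not strictly increasing")
      if (length(lb) && !all(lb %in% c("success", "failure")))
        stop("unit ", u, " trial ", j, ": invalid label(s)")
      if (length(tt)) {
        k <- k + 1L
        rows[[k]] <- data.frame(unit = u, trial = j, time = tt, label = lb)
      }
    }
  }
  ev <- if (k) do.call(rbind, rows) else
    data.frame(unit = integer(0), trial = integer(0), time = numeric(0),
               label = character(0))
  EventTrainSet(ev, units = data.frame(unit = seq_along(cfs), cf = cfs),
                duration = as.numeric(d$duration),
                nTrials = as.integer(d$n_trials))
}
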