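## File interfaces: multi-page TIFF frame stacks with a timestamp sidecar,
## mono PCM WAV, pulse/event/tally CSVs, and the bundled example count
## tables.

#' Write a frame stack as multi-page TIFF plus timestamp sidecar
#'
#' @param frames a \code{\link{FrameSequence}}
#' @param dir output directory (created if needed)
#' @param basename file stem; writes <stem>.tif and <stem>.csv
#' @return invisibly, the TIFF path
#' @export
writeFrameStack <- function(frames, dir, basename = "frames") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, paste0(basename, ".tif"))
  tiff::writeTIFF(frames@frames, path, bits.per.sample = 16)
  utils::write.csv(data.frame(frame_index = seq_len(nFrames(frames)) - 1,
                              t_seconds = frames@times),
                   file.path(dir, paste0(basename, ".csv")),
                   row.names = FALSE)
  invisible(path)
}

#' Read a frame stack written by \code{\link{writeFrameStack}}
#'
#' @param dir directory
#' @param basename file stem
#' @param camera the \code{\link{CameraModel}} the frames belong to
#' @return a \code{\link{FrameSequence}}
#' @export
readFrameStack <- function(dir, basename = "frames", camera = cameraModel()) {
  pages <- tiff::readTIFF(file.path(dir, paste0(basename, ".tif")),
                          all = TRUE)
  side <- utils::read.csv(file.path(dir, paste0(basename, ".csv")))
  FrameSequence(pages, side$t_seconds, camera)
}

#' Write a mono waveform as 16-bit PCM WAV
#'
#' Minimal RIFF/WAVE codec for mono 16-bit PCM; samples are clipped to
#' [-1, 1].
#'
#' @param waveform numeric vector in [-1, 1]
#' @param path output file
#' @param sample_rate Hz
#' @return invisibly, the path
#' @export
writeWav <- function(waveform, path, sample_rate = 192000) {
  x <- as.integer(round(pmax(-1, pmin(1, waveform)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- length(x) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path file written by \code{\link{writeWav}} or any mono 16-bit
#'   PCM WAV
#' @return list(waveform in [-1, 1], sample_rate)
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file")
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!length(id) || nchar(id) < 4) stop("no data chunk found")
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, 2, endian = "little")
      if (fmt[1] != 1 || fmt[2] != 1)
        stop("only mono PCM supported")
      sample_rate <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))
      blk <- readBin(con, "integer", 2, 2, endian = "little")
      if (blk[2] != 16) stop("only 16-bit PCM supported")
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (id == "data") {
      x <- readBin(con, "integer", sz / 2, 2, endian = "little",
                   signed = TRUE)
      return(list(waveform = x / 32767, sample_rate = sample_rate))
    } else invisible(readBin(con, "raw", sz))
  }
}

#' Write the simulated night's outputs to disk
#'
#' Writes pulses.csv (recorded pulse metrics), truth.csv (per-pass ground
#' truth) and optionally a synthesized WAV of the recorded pulse stream.
#'
#' @param truth a channel-processed \code{\link{GroundTruthLog}}
#' @param dir output directory
#' @param wav also synthesize calls.wav (can be large)
#' @return invisibly, the directory
#' @export
writeNightOutputs <- function(truth, dir, wav = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- recordedPulses(truth)
  utils::write.csv(rec, file.path(dir, "pulses.csv"), row.names = FALSE)
  utils::write.csv(truthPasses(truth), file.path(dir, "truth.csv"),
                   row.names = FALSE)
  if (wav && nrow(rec)) {
    w <- synthesizeWaveform(rec)
    writeWav(w, file.path(dir, "calls.wav"))
  }
  invisible(dir)
}

#' Read a pre-detected pulse table
#'
#' CSV bypass of waveform detection: columns onset, duration_ms,
#' fmin_khz, fmax_khz, fpeak_khz, amp_db.
#'
#' @param path CSV file
#' @return data.frame of pulses
#' @export
readPulseTable <- function(path) {
  q <- utils::read.csv(path)
  need <- c("onset", "duration_ms", "fmin_khz", "fmax_khz", "fpeak_khz")
  if (!all(need %in% names(q)))
    stop("pulse table must have columns: ", paste(need, collapse = ", "))
  q[order(q$onset), , drop = FALSE]
}

## ---- bundled example data --------------------------------------------

#' Published nightly detection counts
#'
#' Acoustic, visual and synchronous detection counts for 20 nights of a
#' paired thermal-video / acoustic field survey of Hawaiian hoary bats
#' (one row per night), as printed in the study's nightly tally table.
#'
#' @return data.frame: night, acoustic_n, visual_n, synchronous_n
#' @export
exampleNightlyCounts <- function() {
  utils::read.csv(system.file("extdata", "nightly_counts.csv",
                              package = "echoSync"),
                  colClasses = c(night = "character"))
}

#' Published event counts by proximity and flight type
#'
#' Visual detections with and without synchronous acoustics, broken down
#' by proximity class and flight-path type.
#'
#' @return data.frame: proximity, flight, acoustics_n, no_acoustics_n
#' @export
exampleEventCounts <- function() {
  utils::read.csv(system.file("extdata", "events_by_flight.csv",
                              package = "echoSync"))
}

#' Published multi-bat event counts by proximity and interaction
#'
#' The multi-bat subset of visual detections, by proximity class and
#' agonistic-interaction status.
#'
#' @return data.frame: proximity, interaction, acoustics_n, no_acoustics_n
#' @export
exampleInteractionCounts <- function() {
  utils::read.csv(system.file("extdata", "events_by_interaction.csv",
                              package = "echoSync"))
}

#' Expand labelled event counts into one row per event
#'
#' Turns a count table (as from \code{\link{exampleEventCounts}}) into a
#' per-event data.frame with a logical synchronous column, the shape the
#' table builders consume.
#'
#' @param counts data.frame with acoustics_n and no_acoustics_n plus any
#'   label columns
#' @return data.frame with one row per event
#' @export
expandEventCounts <- function(counts) {
  lab <- counts[, setdiff(names(counts), c("acoustics_n", "no_acoustics_n")),
                drop = FALSE]
  idx <- rep(seq_len(nrow(counts)), counts$acoustics_n + counts$no_acoustics_n)
  out <- lab[idx, , drop = FALSE]
  out$synchronous <- unlist(lapply(seq_len(nrow(counts)), function(i)
    rep(c(TRUE, FALSE), c(counts$acoustics_n[i], counts$no_acoustics_n[i]))))
  rownames(out) <- NULL
  out
}
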