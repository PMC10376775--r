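#' Write a mono waveform as 16-bit PCM WAV
#'
#' Minimal RIFF/WAVE writer (no audio package is required). Samples are
#' clipped to `[-1, 1]` and quantised to signed 16-bit integers.
#'
#' @param x numeric vector of samples in `[-1, 1]`.
#' @param path output file path.
#' @param sr sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, sr = 44100) {
  x <- pmax(pmin(x, 1), -1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sr), con, size = 4, endian = "little")
  writeBin(as.integer(sr * 2L), con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' Companion reader for [write_wav()] round trips.
#'
#' @param path WAV file path.
#' @return list with `x` (samples in `[-1, 1]`) and `sr`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file")
  sr <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!nzchar(id)) stop("no data chunk found")
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      sr <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "raw", size - 8))
      if (fmt[1] != 1L || fmt[2] != 1L) stop("only mono PCM supported")
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", size / 2, size = 2, endian = "little")
      return(list(x = pcm / 32767, sr = sr))
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
}

#' Write stimulus metadata sidecar as JSON
#'
#' Stores tone lists, specs and the seed next to a rendered WAV so a trial
#' can be reproduced exactly.
#'
#' @param trial an `im_trial` from [build_trial_stimulus()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_trial_sidecar <- function(trial, path) {
  jsonlite::write_json(
    list(masker_spec = unclass(trial$masker_spec),
         target_spec = unclass(trial$target_spec),
         trial_duration = trial$trial_duration, seed = trial$seed,
         masker = trial$masker, target = trial$target),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
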