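# Minimal RIFF/WAVE I/O: PCM 16-bit mono, the only flavour the stimulus
# bank uses.  Samples are kept in [-1, 1] doubles in memory.

#' Construct a waveform object
#'
#' @param samples Numeric vector of samples in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz.
#' @return A `waveform` object.
#' @export
waveform <- function(samples, sample_rate) {
  stopifnot(is.numeric(samples), all(is.finite(samples)),
            is.numeric(sample_rate), sample_rate > 0)
  if (length(samples) && max(abs(samples)) > 1 + 1e-9) {
    stop("samples must lie in [-1, 1]", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.3f s), peak %.3f>\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w A `waveform`.
#' @return Duration in seconds (sample count / sample rate).
#' @export
wave_duration <- function(w) length(w$samples) / w$sample_rate

#' Write a waveform as 16-bit PCM mono WAV
#'
#' @param w A `waveform`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  pcm <- as.integer(round(pmax(pmin(w$samples, 1), -1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  nbytes <- 2L * length(pcm)
  sr <- as.integer(round(w$sample_rate))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L,  con, size = 2L, endian = "little")  # PCM
  writeBin(1L,  con, size = 2L, endian = "little")  # mono
  writeBin(sr,  con, size = 4L, endian = "little")
  writeBin(2L * sr, con, size = 4L, endian = "little")  # byte rate
  writeBin(2L,  con, size = 2L, endian = "little")  # block align
  writeBin(16L, con, size = 2L, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(nbytes, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path WAV file path.
#' @return A `waveform`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  if (!identical(readChar(con, 4L), "RIFF")) stop("not a RIFF file")
  readBin(con, "integer", size = 4L, endian = "little")
  if (!identical(readChar(con, 4L), "WAVE")) stop("not a WAVE file")
  sr <- NULL
  repeat {
    id <- readChar(con, 4L)
    if (length(id) == 0L || !nzchar(id)) stop("no data chunk found")
    sz <- readBin(con, "integer", size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", n = 2L, size = 2L, endian = "little")
      sr <- readBin(con, "integer", size = 4L, endian = "little")
      if (fmt[1L] != 1L || fmt[2L] != 1L) stop("only PCM mono supported")
      readBin(con, "raw", n = sz - 8L)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", n = sz %/% 2L, size = 2L,
                     endian = "little")
      return(waveform(pcm / 32767, sr))
    } else {
      readBin(con, "raw", n = sz)
    }
  }
}
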