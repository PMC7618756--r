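# Minimal RIFF/WAVE I/O for single-channel stimuli.
#
# Only what the pipeline needs: mono, either 32-bit IEEE float (format 3,
# lossless for synthesized waveforms in [-1, 1]) or 16-bit PCM (format 1).

#' Write a mono waveform as a WAV file
#'
#' @param waveform numeric vector, amplitudes nominally in \[-1, 1\].
#' @param sample_rate sampling rate in Hz.
#' @param path output file path.
#' @param bits 32 (IEEE float, default) or 16 (integer PCM).
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, sample_rate, path, bits = 32L) {
  stopifnot(is.numeric(waveform), length(waveform) > 0, bits %in% c(16L, 32L))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(waveform)
  bytes_per_sample <- bits %/% 8L
  data_size <- n * bytes_per_sample
  fmt_code <- if (bits == 32L) 3L else 1L   # 3 = IEEE float, 1 = PCM
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # channels
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per_sample), con, size = 4,
           endian = "little")                                    # byte rate
  writeBin(as.integer(bytes_per_sample), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 32L) {
    writeBin(as.numeric(waveform), con, size = 4, endian = "little")
  } else {
    x <- as.integer(round(pmax(pmin(waveform, 1), -1) * 32767))
    writeBin(x, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file written by [write_wav()]
#'
#' Understands canonical mono RIFF/WAVE files with a single `data` chunk in
#' 32-bit float or 16-bit PCM encoding.
#'
#' @param path WAV file path.
#' @return list with `waveform` (numeric) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  }
  sample_rate <- NULL; bits <- NULL; fmt_code <- NULL; waveform <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_code <- readBin(con, integer(), size = 2, endian = "little")
      channels <- readBin(con, integer(), size = 2, endian = "little")
      if (channels != 1L) stop("only mono WAV supported", call. = FALSE)
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16) readBin(con, raw(), n = size - 16)
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("malformed WAV: data before fmt", call. = FALSE)
      n <- size %/% (bits %/% 8L)
      waveform <- if (bits == 32L && fmt_code == 3L) {
        readBin(con, numeric(), n = n, size = 4, endian = "little")
      } else if (bits == 16L && fmt_code == 1L) {
        readBin(con, integer(), n = n, size = 2, endian = "little",
                signed = TRUE) / 32767
      } else {
        stop("unsupported WAV encoding", call. = FALSE)
      }
      break
    } else {
      readBin(con, raw(), n = size)
    }
  }
  if (is.null(waveform)) stop("no data chunk found in ", path, call. = FALSE)
  list(waveform = waveform, sample_rate = sample_rate)
}
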