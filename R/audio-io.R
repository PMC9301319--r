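#' Audio container for a single stimulus
#'
#' Wraps a mono waveform together with its sample rate and optional
#' stimulus metadata (culture, envelope class, synthesis parameters).
#'
#' @param samples numeric vector of waveform samples in \[-1, 1\].
#' @param sample_rate sampling rate in Hz.
#' @param meta named list of stimulus metadata (may be empty).
#' @return an object of class `audio_stimulus`.
#' @export
audio_stimulus <- function(samples, sample_rate, meta = list()) {
  stopifnot(is.numeric(samples), length(samples) > 0L,
            is.numeric(sample_rate), sample_rate > 0)
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate),
                 meta = meta),
            class = "audio_stimulus")
}

#' @export
print.audio_stimulus <- function(x, ...) {
  cat(sprintf("<audio_stimulus: %.3f s @ %g Hz, rms %.4g>\n",
              length(x$samples) / x$sample_rate, x$sample_rate,
              rms(x$samples)))
  invisible(x)
}

#' Root-mean-square amplitude
#'
#' @param x numeric vector.
#' @return scalar RMS value.
#' @export
rms <- function(x) sqrt(mean(x^2))

#' Write a mono waveform as a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer for the canonical uncompressed PCM layout
#' (fmt chunk + data chunk). Samples are clipped to \[-1, 1\] and
#' quantized to signed 16-bit integers.
#'
#' @param audio an [audio_stimulus()] or numeric vector.
#' @param path output file path.
#' @param sample_rate required when `audio` is a bare numeric vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, sample_rate = NULL) {
  if (inherits(audio, "audio_stimulus")) {
    samples <- audio$samples
    sample_rate <- audio$sample_rate
  } else {
    stopifnot(!is.null(sample_rate))
    samples <- as.numeric(audio)
  }
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")        # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")         # PCM
  writeBin(1L, con, size = 2, endian = "little")         # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")         # block align
  writeBin(16L, con, size = 2, endian = "little")        # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' Counterpart of [write_wav()]. Stereo files are downmixed to mono by
#' channel averaging, with a warning.
#'
#' @param path input file path.
#' @return an [audio_stimulus()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)
  sample_rate <- NULL; n_channels <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only uncompressed PCM WAV is supported")
      n_channels <- fmt[2]
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (bits != 16L) stop("only 16-bit PCM WAV is supported")
      if (size > 16L) invisible(readBin(con, raw(), n = size - 16L))
    } else if (identical(id, "data")) {
      samples <- readBin(con, integer(), n = size / 2L, size = 2,
                         signed = TRUE, endian = "little")
      break
    } else {
      invisible(readBin(con, raw(), n = size))
    }
  }
  if (is.null(samples) || is.null(sample_rate))
    stop("malformed WAV file: ", path)
  x <- samples / 32768
  if (n_channels > 1L) {
    warning("stereo input downmixed to mono")
    x <- colMeans(matrix(x, nrow = n_channels))
  }
  audio_stimulus(x, sample_rate)
}
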