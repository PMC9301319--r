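# STFT front end and spectral-shape descriptors. Frame defaults follow
# the descriptor-toolbox convention of a 23.2 ms Hann window with a
# 5.8 ms hop at 44.1 kHz.

#' Short-time spectral analysis of a waveform
#'
#' Hann-windowed magnitude STFT with per-frame energy bookkeeping.
#' The FFT length is the next power of two above the window length.
#'
#' @param audio an [audio_stimulus()].
#' @param window_s analysis window length (s), default 23.2 ms.
#' @param hop_s hop between frame starts (s), default 5.8 ms.
#' @return object of class `spectral_frames`: `mag` (bins x frames
#'   magnitude matrix), `freq` (Hz per bin), `times` (frame centers,
#'   s), `rms` (per-frame time-domain RMS), `sample_rate`, `nfft`,
#'   `window`, `win_len`, `hop`.
#' @export
analyze_frames <- function(audio, window_s = 0.0232, hop_s = 0.0058) {
  stopifnot(inherits(audio, "audio_stimulus"))
  x <- audio$samples
  sr <- audio$sample_rate
  win_len <- round(window_s * sr)
  hop <- max(1L, round(hop_s * sr))
  if (length(x) < win_len) stop("signal shorter than one analysis window")
  starts <- seq(1L, length(x) - win_len + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win_len) - 1) / (win_len - 1))
  nfft <- 2^ceiling(log2(win_len))
  frames <- vapply(starts, function(s) x[s:(s + win_len - 1L)],
                   numeric(win_len))
  frames <- matrix(frames, win_len, length(starts))
  rms_t <- sqrt(colMeans(frames^2))
  padded <- rbind(frames * w, matrix(0, nfft - win_len, length(starts)))
  spec <- stats::mvfft(padded)
  n_bins <- nfft / 2 + 1
  mag <- Mod(spec[seq_len(n_bins), , drop = FALSE])
  structure(list(mag = mag,
                 freq = (seq_len(n_bins) - 1) * sr / nfft,
                 times = (starts - 1 + win_len / 2) / sr,
                 rms = rms_t, sample_rate = sr, nfft = nfft,
                 window = w, win_len = win_len, hop = hop),
            class = "spectral_frames")
}

#' Per-frame energy-probability spectrum
#'
#' Normalizes each frame's power spectrum to sum to one, giving the
#' probability weighting used by the moment descriptors.
#'
#' @param frames a `spectral_frames` object.
#' @return matrix of the same shape as `frames$mag`; all-zero frames
#'   come back as NA columns.
#' @export
energy_probability <- function(frames) {
  p <- frames$mag^2
  tot <- colSums(p)
  out <- sweep(p, 2, tot, `/`)
  out[, tot == 0] <- NA_real_
  out
}

#' Spectral-shape descriptor series
#'
#' Computes, per analysis frame: the spectral centroid (energy-weighted
#' mean frequency), spread, skewness and kurtosis (standardized
#' spectral moments), spectral decrease, the 95%-energy roll-off
#' frequency, spectral flatness (geometric / arithmetic mean of the
#' power spectrum averaged into `flatness_bands` equal sub-bands, the
#' MPEG-7-style convention: near 1 for noise, near 0 for tones),
#' spectral crest (max / mean magnitude), spectral
#' flux (Euclidean change of the unit-normalized magnitude spectrum),
#' and the time-domain frame RMS. All shape descriptors are invariant
#' to a positive rescaling of the waveform; RMS is not.
#'
#' Frames with zero energy yield NA descriptors and are excluded from
#' downstream statistics; their count is attached as attribute
#' `"n_invalid"`.
#'
#' @param frames a `spectral_frames` object.
#' @param rolloff_threshold cumulative-energy fraction for the
#'   roll-off frequency (default 0.95).
#' @param flatness_bands number of equal sub-bands for the flatness
#'   measure (default 32).
#' @return data.frame, one row per frame: time, spectral_centroid,
#'   spectral_spread, spectral_skewness, spectral_kurtosis,
#'   spectral_decrease, spectral_rolloff, spectral_flatness,
#'   spectral_crest, spectral_flux, rms_energy.
#' @export
spectral_descriptors <- function(frames, rolloff_threshold = 0.95,
                                 flatness_bands = 32) {
  stopifnot(inherits(frames, "spectral_frames"))
  mag <- frames$mag
  freq <- frames$freq
  p <- mag^2
  tot <- colSums(p)
  valid <- tot > 0
  P <- sweep(p, 2, ifelse(valid, tot, NA_real_), `/`)
  m1 <- colSums(freq * P)
  m2 <- colSums(freq^2 * P)
  m3 <- colSums(freq^3 * P)
  m4 <- colSums(freq^4 * P)
  spread2 <- pmax(m2 - m1^2, 0)
  spread <- sqrt(spread2)
  skewness <- (m3 - 3 * m1 * m2 + 2 * m1^3) / spread^3
  kurtosis <- (m4 - 4 * m1 * m3 + 6 * m1^2 * m2 - 3 * m1^4) / spread2^2
  # spectral decrease (average magnitude slope weighted by 1/(k-1))
  k <- seq_len(nrow(mag))
  wdec <- 1 / (k[-1] - 1)
  dec_num <- colSums((mag[-1, , drop = FALSE] -
                        matrix(mag[1, ], nrow(mag) - 1, ncol(mag),
                               byrow = TRUE)) * wdec)
  dec_den <- colSums(mag[-1, , drop = FALSE])
  decrease <- ifelse(dec_den > 0, dec_num / dec_den, NA_real_)
  rolloff <- apply(p, 2, function(col) {
    s <- sum(col)
    if (s == 0) return(NA_real_)
    freq[which(cumsum(col) >= rolloff_threshold * s)[1]]
  })
  eps <- 1e-30
  band <- cut(seq_len(nrow(p)), breaks = flatness_bands, labels = FALSE)
  band_power <- apply(p, 2, function(col) tapply(col, band, mean))
  flatness <- exp(colMeans(log(band_power + eps))) /
    colMeans(band_power + eps)
  crest <- apply(mag, 2, max) / colMeans(mag)
  unit <- sweep(mag, 2, sqrt(tot), `/`)
  flux <- c(0, sqrt(colSums((unit[, -1, drop = FALSE] -
                               unit[, -ncol(unit), drop = FALSE])^2)))
  out <- data.frame(time = frames$times,
                    spectral_centroid = m1,
                    spectral_spread = spread,
                    spectral_skewness = skewness,
                    spectral_kurtosis = kurtosis,
                    spectral_decrease = decrease,
                    spectral_rolloff = rolloff,
                    spectral_flatness = flatness,
                    spectral_crest = crest,
                    spectral_flux = flux,
                    rms_energy = frames$rms)
  out[!valid, -1] <- NA_real_
  attr(out, "n_invalid") <- sum(!valid)
  out
}
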