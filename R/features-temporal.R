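# Envelope-based temporal descriptors. The energy envelope is the
# frame RMS of the waveform (20 ms windows, 5 ms hop); attack and
# release use 10%/90% thresholds of the envelope peak and the
# effective duration a 40% threshold, the conventional settings for
# timbre descriptor sets.

envelope_track <- function(audio, window_s = 0.02, hop_s = 0.005) {
  x <- audio$samples
  sr <- audio$sample_rate
  win <- max(2L, round(window_s * sr))
  hop <- max(1L, round(hop_s * sr))
  if (length(x) < win) stop("signal shorter than one envelope window")
  starts <- seq(1L, length(x) - win + 1L, by = hop)
  env <- vapply(starts, function(s) sqrt(mean(x[s:(s + win - 1L)]^2)),
                numeric(1))
  list(env = env, times = (starts - 1 + win / 2) / sr, hop_s = hop / sr)
}

first_time_at <- function(times, env, level) {
  i <- which(env >= level)[1]
  if (is.na(i)) NA_real_ else times[i]
}

#' Temporal descriptors of a waveform
#'
#' Scalar (per-note) descriptors: attack time (10% to 90% of envelope
#' peak), log10 attack time, attack slope (0.8 * peak / attack time),
#' decrease time (peak to 10% of peak, or to the end), decrease slope
#' (least-squares slope of the envelope after the peak), release time
#' (last 90% crossing to last 10% crossing), effective duration (total
#' time the envelope is at or above 40% of peak), plus frequency
#' modulation (relative spread of the per-frame dominant-frequency
#' track) and amplitude modulation (relative envelope fluctuation
#' depth in the 4-8 Hz band).
#'
#' Frame-varying descriptors, returned as series for mean/IQR
#' summaries: the zero-crossing rate (sign changes per second inside
#' each frame) and the within-frame temporal centroid (energy-weighted
#' mean time of the frame's samples, relative to the frame start).
#'
#' @param audio an [audio_stimulus()]; must not be silent.
#' @param window_s,hop_s framing for the per-frame series (defaults
#'   23.2 ms / 5.8 ms, matching [analyze_frames()]).
#' @return list with `scalars` (named numeric, the 9 per-note
#'   descriptors) and `series` (data.frame: time, temporal_centroid,
#'   zero_crossing_rate).
#' @export
temporal_descriptors <- function(audio, window_s = 0.0232, hop_s = 0.0058) {
  stopifnot(inherits(audio, "audio_stimulus"))
  x <- audio$samples
  sr <- audio$sample_rate
  if (all(x == 0)) stop("silent input: temporal descriptors undefined")
  duration <- length(x) / sr
  tr <- envelope_track(audio)
  env <- tr$env
  times <- tr$times
  peak <- max(env)
  ipeak <- which.max(env)
  t10 <- first_time_at(times, env, 0.1 * peak)
  t90 <- first_time_at(times, env, 0.9 * peak)
  attack <- max(t90 - t10, tr$hop_s)
  after <- env[ipeak:length(env)]
  t_after <- times[ipeak:length(env)]
  below <- which(after <= 0.1 * peak)[1]
  decrease_time <- if (is.na(below)) duration - times[ipeak]
                   else t_after[below] - times[ipeak]
  decrease_time <- max(decrease_time, tr$hop_s)
  dec_slope <- if (length(after) >= 2)
    unname(stats::coef(stats::lm(after ~ t_after))[2]) else 0
  last90 <- max(times[env >= 0.9 * peak])
  last10 <- max(times[env >= 0.1 * peak])
  release <- max(last10 - last90, tr$hop_s)
  effective_duration <- sum(env >= 0.4 * peak) * tr$hop_s
  # zero-crossing rate (global and per frame)
  sgn <- sign(x)
  sgn <- sgn[sgn != 0]
  # AM: relative envelope fluctuation in the 4-8 Hz band
  fs_env <- 1 / tr$hop_s
  am <- {
    e <- env - mean(env)
    n <- length(e)
    sp <- stats::fft(e)
    f <- (seq_len(n) - 1) * fs_env / n
    keep <- (f >= 4 & f <= 8) | (f >= fs_env - 8 & f <= fs_env - 4)
    sp[!keep] <- 0
    band <- Re(stats::fft(sp, inverse = TRUE)) / n
    stats::sd(band) / mean(env)
  }
  # FM: relative deviation of the per-frame dominant-frequency track
  frames <- analyze_frames(audio, window_s, hop_s)
  dom <- frames$freq[apply(frames$mag, 2, which.max)]
  strong <- frames$rms >= 0.25 * max(frames$rms)
  dom <- dom[strong & dom > 0]
  fm <- if (length(dom) >= 2 && mean(dom) > 0) stats::sd(dom) / mean(dom) else 0
  # per-frame series on the analysis grid
  win_len <- frames$win_len
  hop <- frames$hop
  starts <- round(frames$times * sr - win_len / 2) + 1L
  tc <- numeric(length(starts))
  zcr <- numeric(length(starts))
  rel_t <- (seq_len(win_len) - 0.5) / sr
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + win_len - 1L)]
    e2 <- seg^2
    tc[i] <- if (sum(e2) > 0) sum(rel_t * e2) / sum(e2) else NA_real_
    s <- sign(seg)
    s <- s[s != 0]
    zcr[i] <- sum(diff(s) != 0) / (win_len / sr)
  }
  list(
    scalars = c(
      attack_time = attack,
      log_attack_time = log10(attack),
      attack_slope = 0.8 * peak / attack,
      decrease_time = decrease_time,
      decrease_slope = dec_slope,
      release_time = release,
      effective_duration = effective_duration,
      frequency_modulation = fm,
      amplitude_modulation = am),
    series = data.frame(time = frames$times,
                        temporal_centroid = tc,
                        zero_crossing_rate = zcr),
    global = c(temporal_centroid = sum(times * env^2) / sum(env^2),
               zero_crossing_rate = sum(diff(sgn) != 0) / duration))
}
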