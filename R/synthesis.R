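# Synthetic stimulus generation: additive-synthesis instrument dyads with
# controlled harmonicity, brightness, noise content and temporal envelope.

with_preserved_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specification of a synthetic two-voice (dyad) stimulus
#'
#' Describes one dyad for additive synthesis: two harmonic voices with
#' per-harmonic amplitude decay `h^(-slope)` (larger slope = duller
#' voice), a broadband noise component mixed at a target fraction of
#' total energy, and a sustaining or non-sustaining amplitude envelope
#' per voice.
#'
#' @param f0_a,f0_b fundamental frequencies of the two voices (Hz).
#' @param n_harmonics number of harmonics per voice.
#' @param spectral_slope_a,spectral_slope_b amplitude decay exponents.
#' @param noise_fraction target noise-to-total energy ratio in \[0, 1).
#' @param envelope_a,envelope_b `"sustaining"` or `"non_sustaining"`.
#' @param attack_s attack duration (s).
#' @param duration_s total duration (s).
#' @param sample_rate sampling rate (Hz).
#' @param seed integer seed controlling harmonic phases and the noise
#'   realization; the same spec and seed reproduce the same waveform
#'   bit for bit.
#' @return an object of class `dyad_spec`.
#' @export
dyad_spec <- function(f0_a = 440, f0_b = 440, n_harmonics = 10,
                      spectral_slope_a = 1, spectral_slope_b = 1,
                      noise_fraction = 0,
                      envelope_a = c("sustaining", "non_sustaining"),
                      envelope_b = c("sustaining", "non_sustaining"),
                      attack_s = 0.02, duration_s = 2,
                      sample_rate = 44100, seed = 1L) {
  envelope_a <- match.arg(envelope_a)
  envelope_b <- match.arg(envelope_b)
  if (f0_a <= 0 || f0_b <= 0) stop("fundamental frequencies must be positive")
  if (noise_fraction < 0 || noise_fraction >= 1)
    stop("noise_fraction must lie in [0, 1)")
  if (attack_s < 0 || duration_s <= attack_s)
    stop("need duration_s > attack_s >= 0")
  nyquist <- sample_rate / 2
  if (n_harmonics * max(f0_a, f0_b) >= nyquist)
    stop("aliasing: highest harmonic at or above the Nyquist frequency")
  structure(list(f0_a = f0_a, f0_b = f0_b, n_harmonics = as.integer(n_harmonics),
                 spectral_slope_a = spectral_slope_a,
                 spectral_slope_b = spectral_slope_b,
                 noise_fraction = noise_fraction,
                 envelope_a = envelope_a, envelope_b = envelope_b,
                 attack_s = attack_s, duration_s = duration_s,
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "dyad_spec")
}

# Amplitude envelope on the sample grid. Sustaining: linear attack,
# plateau, short linear release. Non-sustaining: linear attack then
# exponential decay fast enough that the envelope is below 10% of peak
# by half the duration (the property used to classify envelope types).
voice_envelope <- function(t, type, attack_s, duration_s) {
  env <- rep(1, length(t))
  if (attack_s > 0) {
    ramp <- t < attack_s
    env[ramp] <- t[ramp] / attack_s
  }
  if (type == "non_sustaining") {
    tau <- max(duration_s / 8, 1e-3)
    decay <- t >= attack_s
    env[decay] <- env[decay] * exp(-(t[decay] - attack_s) / tau)
  } else {
    release_s <- min(0.05, 0.1 * duration_s)
    rel <- t > (duration_s - release_s)
    env[rel] <- env[rel] * (duration_s - t[rel]) / release_s
  }
  env
}

#' Synthesize a dyad waveform from its specification
#'
#' Each voice is a sum of harmonics `h * f0` with amplitudes
#' `h^(-slope)` and seeded random phases, shaped by its envelope; the
#' two voices are mixed at equal RMS. Gaussian broadband noise, shaped
#' by the combined voice envelope so the local noise-to-total energy
#' ratio is stationary, is added at the requested energy fraction. The
#' result is peak-normalized to 0.95.
#'
#' @param spec a [dyad_spec()].
#' @return an [audio_stimulus()]; `meta` records the spec together with
#'   the exact harmonic and noise component energies used in the mix.
#' @export
synth_dyad <- function(spec) {
  stopifnot(inherits(spec, "dyad_spec"))
  sr <- spec$sample_rate
  n <- round(spec$duration_s * sr)
  t <- (seq_len(n) - 1) / sr
  with_preserved_seed(spec$seed, {
    voice <- function(f0, slope) {
      h <- seq_len(spec$n_harmonics)
      amps <- h^(-slope)
      phases <- stats::runif(length(h), 0, 2 * pi)
      x <- numeric(n)
      for (k in seq_along(h))
        x <- x + amps[k] * sin(2 * pi * h[k] * f0 * t + phases[k])
      x / rms(x)  # equal-RMS voices before enveloping
    }
    va <- voice(spec$f0_a, spec$spectral_slope_a) *
      voice_envelope(t, spec$envelope_a, spec$attack_s, spec$duration_s)
    vb <- voice(spec$f0_b, spec$spectral_slope_b) *
      voice_envelope(t, spec$envelope_b, spec$attack_s, spec$duration_s)
    harm <- va + vb
    e_harm <- sum(harm^2)
    if (spec$noise_fraction > 0) {
      env_a <- voice_envelope(t, spec$envelope_a, spec$attack_s, spec$duration_s)
      env_b <- voice_envelope(t, spec$envelope_b, spec$attack_s, spec$duration_s)
      env_mix <- sqrt((env_a^2 + env_b^2) / 2)
      noise <- stats::rnorm(n) * env_mix
      # scale so noise / (noise + harmonic) energy = noise_fraction exactly
      e_target <- e_harm * spec$noise_fraction / (1 - spec$noise_fraction)
      noise <- noise * sqrt(e_target / sum(noise^2))
      e_noise <- sum(noise^2)
      x <- harm + noise
    } else {
      e_noise <- 0
      x <- harm
    }
    peak <- max(abs(x))
    x <- 0.95 * x / peak
    scale2 <- (0.95 / peak)^2
    audio_stimulus(x, sr, meta = list(
      spec = spec,
      harmonic_energy = e_harm * scale2,
      noise_energy = e_noise * scale2))
  })
}

#' Scale a waveform to a target RMS level
#'
#' Loudness equalization by RMS matching: the waveform is multiplied by
#' a single positive gain so its RMS equals `target_rms`.
#'
#' @param audio an [audio_stimulus()].
#' @param target_rms target RMS amplitude (linear units).
#' @return the rescaled [audio_stimulus()].
#' @export
loudness_normalize <- function(audio, target_rms = 0.1) {
  stopifnot(inherits(audio, "audio_stimulus"), target_rms > 0)
  r <- rms(audio$samples)
  if (r == 0) stop("cannot normalize an all-zero waveform")
  gain <- target_rms / r
  out <- audio
  out$samples <- audio$samples * gain
  for (nm in c("harmonic_energy", "noise_energy"))
    if (!is.null(out$meta[[nm]])) out$meta[[nm]] <- out$meta[[nm]] * gain^2
  out
}

#' Generate a full dyad stimulus set from an experiment design
#'
#' Builds the requested number of dyad specifications per culture
#' (Chinese / Western) and temporal-envelope class (S+S, S+N, N+N),
#' together with a metadata table. The default design reproduces the
#' 518-stimulus layout used throughout the package: 259 dyads per
#' culture split 113/113/33 (Chinese) and 113/114/32 (Western) over
#' S+S / S+N / N+N. Voices are in pitch unison or octave; Chinese
#' dyads draw somewhat larger noise fractions, reflecting the noisier
#' attack transients of plucked and percussive folk instruments.
#'
#' @param design named list `list(Chinese = c("S+S" = .., "S+N" = ..,
#'   "N+N" = ..), Western = ...)` of per-cell stimulus counts.
#' @param seed master seed; per-stimulus seeds are derived from it.
#' @param duration_s,sample_rate passed to each [dyad_spec()].
#' @param render if `TRUE`, also synthesize every waveform (memory
#'   heavy for large designs); otherwise return specs only and render
#'   on demand with [synth_dyad()].
#' @return list with `specs` (list of [dyad_spec()]), `metadata`
#'   (data.frame: stimulus_id, culture, envelope_class, f0_a, f0_b,
#'   noise_fraction, seed) and, when `render = TRUE`, `audio`.
#' @export
build_stimulus_set <- function(design = default_design(), seed = 1L,
                               duration_s = 2, sample_rate = 44100,
                               render = FALSE) {
  if (length(design) == 0L || sum(unlist(design)) == 0)
    stop("empty design")
  classes <- c("S+S", "S+N", "N+N")
  for (cu in names(design)) {
    if (!all(names(design[[cu]]) %in% classes))
      stop("unknown envelope class in design for ", cu)
    if (any(design[[cu]] < 1)) stop("all requested cells need counts >= 1")
  }
  pitches <- c(220, 261.63, 329.63, 440)  # A3, C4, E4, A4
  rows <- list()
  specs <- list()
  idx <- 0L
  with_preserved_seed(seed, {
    for (cu in names(design)) {
      for (cl in names(design[[cu]])) {
        for (i in seq_len(design[[cu]][[cl]])) {
          idx <- idx + 1L
          f0a <- sample(pitches, 1)
          f0b <- f0a * sample(c(1, 2), 1)          # unison or octave
          envs <- switch(cl,
            "S+S" = c("sustaining", "sustaining"),
            "N+N" = c("non_sustaining", "non_sustaining"),
            "S+N" = sample(c("sustaining", "non_sustaining")))
          nf <- if (cu == "Chinese") stats::runif(1, 0.05, 0.35)
                else stats::runif(1, 0.02, 0.25)
          sp <- dyad_spec(
            f0_a = f0a, f0_b = f0b,
            n_harmonics = max(2L, floor(sample_rate / 2 / f0b * 0.9)) |>
              min(12L),
            spectral_slope_a = stats::runif(1, 0.6, 1.8),
            spectral_slope_b = stats::runif(1, 0.6, 1.8),
            noise_fraction = nf,
            envelope_a = envs[1], envelope_b = envs[2],
            attack_s = min(if (cl == "S+S") stats::runif(1, 0.02, 0.08)
                           else stats::runif(1, 0.005, 0.03),
                           0.25 * duration_s),
            duration_s = duration_s, sample_rate = sample_rate,
            seed = sample.int(.Machine$integer.max - 1L, 1))
          specs[[idx]] <- sp
          rows[[idx]] <- data.frame(
            stimulus_id = sprintf("stim%04d", idx), culture = cu,
            envelope_class = cl, f0_a = f0a, f0_b = f0b,
            noise_fraction = nf, seed = sp$seed,
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  metadata <- do.call(rbind, rows)
  names(specs) <- metadata$stimulus_id
  out <- list(specs = specs, metadata = metadata)
  if (render) out$audio <- lapply(specs, synth_dyad)
  out
}

#' Default 518-dyad experiment design
#'
#' 259 Chinese and 259 Western dyads; cell counts per envelope class
#' chosen so the pooled classes hold 226 (S+S), 227 (S+N) and 65 (N+N)
#' stimuli.
#'
#' @return named list of per-culture count vectors.
#' @export
default_design <- function() {
  list(Chinese = c("S+S" = 113, "S+N" = 113, "N+N" = 33),
       Western = c("S+S" = 113, "S+N" = 114, "N+N" = 32))
}
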