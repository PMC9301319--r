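# Assembly of the 45-statistic feature vector and the 216 -> 54 -> 45
# screening rule.

# 18 frame-varying parameters summarized by mean and IQR
FRAME_PARAMS <- c(
  "temporal_centroid", "zero_crossing_rate",
  "spectral_centroid", "spectral_spread", "spectral_decrease",
  "spectral_skewness", "spectral_kurtosis", "spectral_rolloff",
  "spectral_flatness", "spectral_crest", "spectral_flux", "rms_energy",
  "harmonic_energy", "noisiness_energy", "tristimulus",
  "harmonic_spectral_deviation", "odd_even_ratio", "noisiness")

# 9 per-note parameters summarized by mean only
NOTE_PARAMS <- c(
  "attack_time", "log_attack_time", "decrease_time",
  "effective_duration", "release_time", "attack_slope",
  "decrease_slope", "frequency_modulation", "amplitude_modulation")

#' Canonical names of the 45 acoustic feature statistics
#'
#' 18 frame-varying parameters contribute a mean and an interquartile
#' range each; 9 per-note parameters contribute a mean only.
#'
#' @return character vector of length 45.
#' @export
feature_names <- function() {
  c(as.vector(rbind(paste0(FRAME_PARAMS, "_mean"),
                    paste0(FRAME_PARAMS, "_iqr"))),
    paste0(NOTE_PARAMS, "_mean"))
}

# linear-interpolation (type 7) quartiles; a fixed convention so the
# IQR of 1..100 is exactly 49.5
iqr_stat <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] - q[1]
}

#' Summarize descriptor series into the 45-statistic feature vector
#'
#' Takes per-frame spectral, harmonic and temporal series plus the
#' per-note scalars and reduces them to the canonical 45 statistics:
#' mean and IQR over valid frames for the 18 frame-varying parameters,
#' mean only for the 9 per-note parameters. Invalid (NA) frames are
#' excluded; the number excluded per parameter is attached as
#' attribute `"n_excluded"`.
#'
#' @param spectral data.frame from [spectral_descriptors()].
#' @param harmonic data.frame from [harmonic_descriptors()].
#' @param temporal list from [temporal_descriptors()].
#' @return named numeric vector of length 45 (class `feature_vector`).
#' @export
summarize_features <- function(spectral, harmonic, temporal) {
  series <- cbind(temporal$series[c("temporal_centroid", "zero_crossing_rate")],
                  spectral[setdiff(names(spectral), "time")],
                  harmonic[c("harmonic_energy", "noisiness_energy",
                             "tristimulus", "harmonic_spectral_deviation",
                             "odd_even_ratio", "noisiness")])
  out <- numeric(0)
  excluded <- integer(0)
  for (pn in FRAME_PARAMS) {
    v <- series[[pn]]
    ok <- is.finite(v)
    excluded[pn] <- sum(!ok)
    v <- v[ok]
    if (length(v) == 0) stop("no valid frames for parameter ", pn)
    out[paste0(pn, "_mean")] <- mean(v)
    out[paste0(pn, "_iqr")] <- iqr_stat(v)
  }
  for (pn in NOTE_PARAMS)
    out[paste0(pn, "_mean")] <- unname(temporal$scalars[[pn]])
  out <- out[feature_names()]
  attr(out, "n_excluded") <- excluded
  class(out) <- c("feature_vector", class(out))
  out
}

#' Extract the acoustic feature vector of one stimulus
#'
#' Convenience front end running [analyze_frames()],
#' [spectral_descriptors()], [harmonic_descriptors()] and
#' [temporal_descriptors()] and summarizing via
#' [summarize_features()].
#'
#' @param audio an [audio_stimulus()].
#' @param window_s,hop_s STFT framing parameters.
#' @param full if `TRUE`, return the unscreened 8-statistic battery
#'   (216 values: max, min, mean, var, sd, IQR, skewness, kurtosis of
#'   all 27 parameters) instead of the screened 45.
#' @param ... passed to [harmonic_descriptors()].
#' @return named numeric vector (45 entries, or 216 when
#'   `full = TRUE`).
#' @export
extract_features <- function(audio, window_s = 0.0232, hop_s = 0.0058,
                             full = FALSE, ...) {
  frames <- analyze_frames(audio, window_s, hop_s)
  spec <- spectral_descriptors(frames)
  harm <- harmonic_descriptors(frames, ...)
  temp <- temporal_descriptors(audio, window_s, hop_s)
  if (!full) return(summarize_features(spec, harm, temp))
  series <- cbind(temp$series[c("temporal_centroid", "zero_crossing_rate")],
                  spec[setdiff(names(spec), "time")],
                  harm[c("harmonic_energy", "noisiness_energy",
                         "tristimulus", "harmonic_spectral_deviation",
                         "odd_even_ratio", "noisiness")])
  out <- numeric(0)
  for (pn in c(FRAME_PARAMS, NOTE_PARAMS)) {
    v <- if (pn %in% FRAME_PARAMS) series[[pn]]
         else unname(temp$scalars[[pn]])
    v <- v[is.finite(v)]
    if (length(v) == 0) v <- NA_real_
    out[paste0(pn, "__max")] <- max(v)
    out[paste0(pn, "__min")] <- min(v)
    out[paste0(pn, "__mean")] <- mean(v)
    out[paste0(pn, "__var")] <- if (length(v) > 1) stats::var(v) else 0
    out[paste0(pn, "__sd")] <- if (length(v) > 1) stats::sd(v) else 0
    out[paste0(pn, "__iqr")] <- if (length(v) > 1) iqr_stat(v) else 0
    out[paste0(pn, "__skewness")] <- moment_skewness(v)
    out[paste0(pn, "__kurtosis")] <- moment_kurtosis(v)
  }
  out
}

moment_skewness <- function(v) {
  if (length(v) < 2 || stats::sd(v) == 0) return(0)
  mean((v - mean(v))^3) / stats::sd(v)^3
}

moment_kurtosis <- function(v) {
  if (length(v) < 2 || stats::sd(v) == 0) return(0)
  mean((v - mean(v))^4) / stats::sd(v)^4
}

#' Screen the 216-statistic battery down to 54 then 45
#'
#' Ranks every candidate statistic by the absolute Pearson correlation
#' with the target (fusion scale values), summarizes the ranking by
#' statistic family, and applies the screening rule: keep the mean and
#' IQR families of all 27 parameters (54 statistics), then drop the
#' IQR of the 9 per-note parameters, leaving the canonical 45.
#'
#' @param stats216 matrix / data.frame, stimuli x 216 statistics with
#'   names `parameter__statistic` (see `extract_features(full = TRUE)`).
#' @param target numeric target vector (one value per stimulus).
#' @return list: `ranking` (data.frame statistic, family, abs_r, in
#'   decreasing order; constant candidates dropped with a warning),
#'   `family_summary` (mean |r| per statistic family), `retained_54`,
#'   `retained_45` (character vectors).
#' @export
screen_features <- function(stats216, target) {
  x <- as.matrix(stats216)
  if (nrow(x) < 3) stop("need at least 3 observations")
  if (any(!is.finite(target))) stop("target must be finite")
  sds <- apply(x, 2, stats::sd)
  constant <- !is.finite(sds) | sds == 0
  if (any(constant)) {
    warning(sum(constant), " constant candidate(s) dropped from ranking")
  }
  usable <- colnames(x)[!constant]
  abs_r <- vapply(usable, function(cn)
    abs(stats::cor(x[, cn], target)), numeric(1))
  fam <- sub("^.*__", "", usable)
  ranking <- data.frame(statistic = usable, family = fam, abs_r = abs_r,
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$abs_r), ]
  rownames(ranking) <- NULL
  family_summary <- sort(tapply(ranking$abs_r, ranking$family, mean),
                         decreasing = TRUE)
  all_params <- c(FRAME_PARAMS, NOTE_PARAMS)
  retained_54 <- c(paste0(all_params, "__mean"), paste0(all_params, "__iqr"))
  retained_45 <- setdiff(retained_54, paste0(NOTE_PARAMS, "__iqr"))
  list(ranking = ranking, family_summary = family_summary,
       retained_54 = retained_54, retained_45 = retained_45)
}

#' Feature table for a stimulus set
#'
#' Renders (or reuses) each dyad's audio and extracts its 45-statistic
#' feature vector.
#'
#' @param stimulus_set result of [build_stimulus_set()].
#' @param normalize_rms if not `NULL`, loudness-normalize every
#'   stimulus to this RMS before analysis.
#' @param ... passed to [extract_features()].
#' @return data.frame: `stimulus_id` plus the 45 canonical columns.
#' @export
feature_table <- function(stimulus_set, normalize_rms = 0.1, ...) {
  ids <- stimulus_set$metadata$stimulus_id
  rows <- lapply(seq_along(ids), function(i) {
    audio <- if (!is.null(stimulus_set$audio))
      stimulus_set$audio[[i]] else synth_dyad(stimulus_set$specs[[i]])
    if (!is.null(normalize_rms))
      audio <- loudness_normalize(audio, normalize_rms)
    fv <- extract_features(audio, ...)
    as.data.frame(as.list(unclass(fv)))
  })
  out <- do.call(rbind, rows)
  cbind(data.frame(stimulus_id = ids, stringsAsFactors = FALSE), out)
}
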