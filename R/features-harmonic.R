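# Partial-based descriptors. Dyads carry two fundamentals, so partials
# are found by per-frame spectral peak picking rather than a single-f0
# harmonic sieve. Harmonic energy is the energy in the picked peak
# neighbourhoods after subtracting the broadband noise-floor estimate,
# so that tonal and noise energy separate even when noise sits under
# the partials.

#' Harmonic / noise descriptor series
#'
#' Per frame: partials are strict local maxima of the power spectrum
#' exceeding `peak_factor` times the frame's median bin power, each
#' owning a +/- `peak_halfwidth` bin neighbourhood (unioned when
#' partials are close). The mean power of the remaining bins estimates
#' the noise floor; harmonic energy is the floor-subtracted energy in
#' the peak neighbourhoods, noise energy the remainder, and noisiness
#' their ratio to total energy (in \[0, 1\]).
#'
#' Derived partial statistics (partials ranked by increasing
#' frequency): tristimulus (energy shares of partial 1, partials 2-4,
#' partials >= 5), odd-to-even partial energy ratio (NA when no even
#' partial exists), and harmonic spectral deviation (mean absolute
#' deviation of partial amplitudes from their 3-point local envelope).
#'
#' @param frames a `spectral_frames` object (see [analyze_frames()]).
#' @param peak_factor peak threshold as a multiple of the median bin
#'   power (default 8).
#' @param peak_halfwidth neighbourhood half-width in bins (default 2,
#'   matching the Hann main lobe).
#' @return data.frame per frame: time, harmonic_energy,
#'   noisiness_energy, noisiness, tristimulus (first component),
#'   tristimulus2, tristimulus3, odd_even_ratio,
#'   harmonic_spectral_deviation, n_partials. Frames without
#'   detectable partials report zero harmonic energy, noisiness 1 and
#'   NA partial statistics.
#' @export
harmonic_descriptors <- function(frames, peak_factor = 8, peak_halfwidth = 2) {
  stopifnot(inherits(frames, "spectral_frames"))
  p <- frames$mag^2
  n_bins <- nrow(p)
  n_frames <- ncol(p)
  res <- data.frame(time = frames$times,
                    harmonic_energy = numeric(n_frames),
                    noisiness_energy = numeric(n_frames),
                    noisiness = numeric(n_frames),
                    tristimulus = NA_real_, tristimulus2 = NA_real_,
                    tristimulus3 = NA_real_, odd_even_ratio = NA_real_,
                    harmonic_spectral_deviation = NA_real_,
                    n_partials = 0L)
  for (fr in seq_len(n_frames)) {
    col <- p[, fr]
    tot <- sum(col)
    if (tot == 0) {
      res[fr, -1] <- NA
      next
    }
    thr <- peak_factor * stats::median(col)
    is_peak <- c(FALSE, col[2:(n_bins - 1)] > col[1:(n_bins - 2)] &
                   col[2:(n_bins - 1)] >= col[3:n_bins], FALSE) & col > thr
    peaks <- which(is_peak)
    if (length(peaks) == 0L) {
      res$harmonic_energy[fr] <- 0
      res$noisiness_energy[fr] <- tot
      res$noisiness[fr] <- 1
      next
    }
    member <- rep(FALSE, n_bins)
    for (pk in peaks)
      member[max(1, pk - peak_halfwidth):min(n_bins, pk + peak_halfwidth)] <- TRUE
    floor_est <- if (all(member)) 0 else mean(col[!member])
    # per-partial energy: floor-subtracted energy of each neighbourhood
    e_partial <- vapply(peaks, function(pk) {
      win <- max(1, pk - peak_halfwidth):min(n_bins, pk + peak_halfwidth)
      sum(pmax(col[win] - floor_est, 0))
    }, numeric(1))
    keep <- e_partial > 0
    peaks <- peaks[keep]
    e_partial <- e_partial[keep]
    e_harm <- sum(pmax(col[member] - floor_est, 0))
    e_harm <- min(e_harm, tot)
    res$harmonic_energy[fr] <- e_harm
    res$noisiness_energy[fr] <- tot - e_harm
    res$noisiness[fr] <- (tot - e_harm) / tot
    H <- length(peaks)
    res$n_partials[fr] <- H
    if (H == 0L) next
    ord <- order(frames$freq[peaks])      # rank by increasing frequency
    e_rank <- e_partial[ord]
    etot <- sum(e_rank)
    res$tristimulus[fr] <- e_rank[1] / etot
    res$tristimulus2[fr] <- sum(e_rank[seq_len(min(4, H))][-1]) / etot
    res$tristimulus3[fr] <- if (H >= 5) sum(e_rank[5:H]) / etot else 0
    if (H >= 2) {
      odd <- sum(e_rank[seq(1, H, by = 2)])
      even <- sum(e_rank[seq(2, H, by = 2)])
      res$odd_even_ratio[fr] <- odd / even
    }
    a <- sqrt(e_rank)
    env <- vapply(seq_len(H), function(h)
      mean(a[max(1, h - 1):min(H, h + 1)]), numeric(1))
    res$harmonic_spectral_deviation[fr] <- mean(abs(a - env))
  }
  res
}
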