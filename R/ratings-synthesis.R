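# Simulation of ordinal listener ratings from a latent Thurstonian
# response model: each stimulus has a latent position per attribute,
# each rater adds normal discriminal noise, and fixed category
# boundaries turn the noisy value into a 1..9 response.

#' Attributes rated in a dyad listening experiment
#' @export
TIMBRE_ATTRIBUTES <- c("fusion", "segregation", "roughness", "pleasantness")

#' Latent perceptual model for rating simulation
#'
#' Defines the planted structure of a simulated listening experiment:
#' per-envelope-class mean latent values for fusion and roughness (in
#' category units), negative mirror coefficients deriving segregation
#' from fusion and pleasantness from roughness, between-stimulus and
#' within-rater normal spreads, and the category boundaries.
#'
#' Defaults place class means at the values observed in dyad-fusion
#' listening studies: fusion highest for two sustaining voices and
#' lowest for mixed envelopes (S+S 5.97, N+N 5.51, S+N 3.98),
#' roughness increasing with the number of sustaining voices
#' (S+S 4.96, S+N 4.42, N+N 3.54).
#'
#' @param class_means numeric matrix with rows `fusion`, `roughness`
#'   and columns `S+S`, `S+N`, `N+N` (category units).
#' @param mirror named vector of negative coefficients: segregation is
#'   mirrored from fusion and pleasantness from roughness about
#'   `center`.
#' @param mirror_sd residual spread of the mirrored attributes.
#' @param stimulus_sd between-stimulus spread around the class mean.
#' @param rater_sd within-rater discriminal noise (must be > 0).
#' @param boundaries strictly increasing category cut points
#'   `t_1 .. t_{m-1}`; defaults to 1.5 .. 8.5 so latent values live on
#'   the 1..9 category scale.
#' @param center mirror point (default 5, the middle of the scale).
#' @return an object of class `latent_percept_model`.
#' @export
latent_percept_model <- function(
    class_means = rbind(
      fusion    = c("S+S" = 5.97, "S+N" = 3.98, "N+N" = 5.51),
      roughness = c("S+S" = 4.96, "S+N" = 4.42, "N+N" = 3.54)),
    mirror = c(segregation = -1, pleasantness = -1),
    mirror_sd = 0.25, stimulus_sd = 0.8, rater_sd = 1.2,
    boundaries = seq(1.5, 8.5, by = 1), center = 5) {
  if (any(diff(boundaries) <= 0)) stop("boundaries must be strictly increasing")
  if (rater_sd <= 0) stop("rater_sd must be positive")
  if (any(mirror >= 0)) stop("mirror coefficients must be negative")
  stopifnot(all(c("fusion", "roughness") %in% rownames(class_means)))
  structure(list(class_means = class_means, mirror = mirror,
                 mirror_sd = mirror_sd, stimulus_sd = stimulus_sd,
                 rater_sd = rater_sd, boundaries = boundaries,
                 center = center, m = length(boundaries) + 1L),
            class = "latent_percept_model")
}

#' Threshold latent values into ordinal categories
#'
#' Lowest-level rating generator: given per-stimulus latent values and
#' category boundaries, each rater's response is the category `g` with
#' `t_{g-1} < x + noise <= t_g` (with `t_0 = -Inf`, `t_m = +Inf`).
#'
#' @param latent numeric vector of per-stimulus latent values.
#' @param boundaries strictly increasing cut points.
#' @param n_raters number of simulated raters (>= 2).
#' @param rater_sd SD of the per-response normal noise (0 allowed here
#'   for the noiseless thresholding limit).
#' @param seed integer seed.
#' @return integer matrix, stimuli x raters, entries in `1..m`.
#' @export
ratings_from_latent <- function(latent, boundaries, n_raters = 32,
                                rater_sd = 1.2, seed = 1L) {
  if (any(diff(boundaries) <= 0)) stop("boundaries must be strictly increasing")
  if (n_raters < 2) stop("need at least 2 raters")
  n <- length(latent)
  with_preserved_seed(seed, {
    noise <- matrix(stats::rnorm(n * n_raters, sd = rater_sd), n, n_raters)
    x <- latent + noise
    resp <- matrix(findInterval(x, boundaries) + 1L, n, n_raters)
    storage.mode(resp) <- "integer"
    resp
  })
}

#' Simulate a complete rating matrix for a stimulus set
#'
#' Draws one latent value per stimulus and attribute (class mean plus
#' between-stimulus noise; segregation and pleasantness as negatively
#' coupled mirrors of fusion and roughness) and then thresholds
#' per-rater noisy copies into categories. Every rater rates every
#' stimulus on every attribute.
#'
#' @param latent a [latent_percept_model()].
#' @param metadata data.frame with columns `stimulus_id` and
#'   `envelope_class` (as produced by [build_stimulus_set()]).
#' @param n_raters number of raters (>= 2).
#' @param seed integer seed.
#' @return a long-format data.frame of class `rating_matrix` with
#'   columns `rater_id`, `stimulus_id`, `attribute`, `category`; the
#'   planted per-stimulus latent values are attached as attribute
#'   `"latent"` for recovery checks.
#' @export
synth_ratings <- function(latent, metadata, n_raters = 32, seed = 1L) {
  stopifnot(inherits(latent, "latent_percept_model"),
            all(c("stimulus_id", "envelope_class") %in% names(metadata)))
  if (n_raters < 2) stop("need at least 2 raters")
  cls <- metadata$envelope_class
  if (!all(cls %in% colnames(latent$class_means)))
    stop("metadata contains an envelope class absent from the model")
  n <- nrow(metadata)
  with_preserved_seed(seed, {
    lat <- matrix(NA_real_, n, 4,
                  dimnames = list(metadata$stimulus_id, TIMBRE_ATTRIBUTES))
    lat[, "fusion"] <- latent$class_means["fusion", cls] +
      stats::rnorm(n, sd = latent$stimulus_sd)
    lat[, "roughness"] <- latent$class_means["roughness", cls] +
      stats::rnorm(n, sd = latent$stimulus_sd)
    lat[, "segregation"] <- latent$center +
      latent$mirror[["segregation"]] * (lat[, "fusion"] - latent$center) +
      stats::rnorm(n, sd = latent$mirror_sd)
    lat[, "pleasantness"] <- latent$center +
      latent$mirror[["pleasantness"]] * (lat[, "roughness"] - latent$center) +
      stats::rnorm(n, sd = latent$mirror_sd)
    seeds <- sample.int(.Machine$integer.max - 1L, 4)
    out <- vector("list", 4)
    for (a in seq_along(TIMBRE_ATTRIBUTES)) {
      resp <- ratings_from_latent(lat[, a], latent$boundaries, n_raters,
                                  latent$rater_sd, seed = seeds[a])
      out[[a]] <- data.frame(
        rater_id = rep(sprintf("rater%02d", seq_len(n_raters)), each = n),
        stimulus_id = rep(metadata$stimulus_id, n_raters),
        attribute = TIMBRE_ATTRIBUTES[a],
        category = as.vector(resp),
        stringsAsFactors = FALSE)
    }
    ratings <- do.call(rbind, out)
    rownames(ratings) <- NULL
    class(ratings) <- c("rating_matrix", "data.frame")
    attr(ratings, "latent") <- lat
    attr(ratings, "m") <- latent$m
    ratings
  })
}

#' Reshape long-format ratings to a stimulus x rater matrix
#'
#' @param ratings a long `rating_matrix` data.frame.
#' @param attribute which attribute to extract.
#' @return numeric matrix, stimuli in rows, raters in columns.
#' @export
ratings_wide <- function(ratings, attribute) {
  stopifnot(attribute %in% ratings$attribute)
  sub <- ratings[ratings$attribute == attribute, , drop = FALSE]
  stim <- unique(sub$stimulus_id)
  raters <- unique(sub$rater_id)
  m <- matrix(NA_real_, length(stim), length(raters),
              dimnames = list(stim, raters))
  m[cbind(match(sub$stimulus_id, stim), match(sub$rater_id, raters))] <-
    sub$category
  if (anyNA(m)) stop("incomplete rating matrix for attribute ", attribute)
  m
}
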