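# Shared fixture builders; everything is generated in code.

make_tone <- function(freq, duration_s = 1, sr = 44100, amp = 1) {
  t <- (seq_len(round(duration_s * sr)) - 1) / sr
  audio_stimulus(amp * sin(2 * pi * freq * t), sr)
}

make_noise <- function(duration_s = 1, sr = 44100, seed = 1) {
  n <- round(duration_s * sr)
  set.seed(seed)
  audio_stimulus(rnorm(n) * 0.2, sr)
}

# small complete long-format rating table built from a wide matrix
long_ratings <- function(mat, attribute = "fusion") {
  df <- data.frame(
    rater_id = rep(colnames(mat) %||% paste0("r", seq_len(ncol(mat))),
                   each = nrow(mat)),
    stimulus_id = rep(rownames(mat) %||% paste0("s", seq_len(nrow(mat))),
                      ncol(mat)),
    attribute = attribute,
    category = as.vector(mat))
  class(df) <- c("rating_matrix", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# parallel raters with a common factor: pairwise correlation r_target
parallel_raters <- function(n_stim, k, r_target, seed = 1) {
  set.seed(seed)
  common <- rnorm(n_stim)
  sapply(seq_len(k), function(i)
    sqrt(r_target) * common + sqrt(1 - r_target) * rnorm(n_stim))
}

# planted linear problem in the shape of the 45-feature fusion fit
planted_fusion_problem <- function(n = 518, noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 45), n, 45, dimnames = list(NULL, feature_names()))
  beta <- numeric(45)
  beta[1:6] <- c(14.2, 7.7, -7.6, -6.9, 5.6, 4.8)
  list(x = X, y = drop(X %*% beta) + rnorm(n, sd = noise_sd), beta = beta)
}
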