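# Reliability and validity screening of ordinal rating matrices.

#' Cronbach's alpha for one attribute's rating table
#'
#' Internal-consistency reliability with raters treated as items and
#' stimuli as cases:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`.
#'
#' @param x numeric matrix, stimuli in rows, raters (items) in columns.
#' @return scalar alpha (<= 1; can be negative for inconsistent raters).
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  k <- ncol(x)
  if (k < 2 || nrow(x) < 2) stop("need at least 2 raters and 2 stimuli")
  total_var <- stats::var(rowSums(x))
  if (total_var == 0)
    stop("total-score variance is zero; alpha is undefined")
  item_var <- sum(apply(x, 2, stats::var))
  k / (k - 1) * (1 - item_var / total_var)
}

#' Validity filter: SD-based outlier removal with mean imputation
#'
#' For each stimulus x attribute cell group, ratings farther than
#' `k_sd` sample standard deviations from the group mean (across
#' raters) are marked invalid and replaced by the mean of the retained
#' ratings, so the output matrix stays complete. Bounds are computed
#' once from the raw data (a single elimination pass).
#'
#' @param ratings long `rating_matrix` data.frame (`rater_id`,
#'   `stimulus_id`, `attribute`, `category`).
#' @param k_sd the outlier multiplier (default 1.5).
#' @param round_imputed round imputed values back to integer
#'   categories? Default `FALSE`: imputed means are carried as real
#'   values into the scaling stage.
#' @return list with `ratings` (cleaned data.frame, same shape) and
#'   `report` (class `qc_report`): per-attribute alpha computed on the
#'   raw data, removed-cell count and locations, and imputed values.
#' @export
validity_filter <- function(ratings, k_sd = 1.5, round_imputed = FALSE) {
  stopifnot(all(c("rater_id", "stimulus_id", "attribute", "category")
                %in% names(ratings)))
  out <- ratings
  removed <- list()
  key <- interaction(ratings$stimulus_id, ratings$attribute, drop = TRUE)
  for (cell in levels(key)) {
    idx <- which(key == cell)
    if (length(idx) < 3)
      stop("need at least 3 raters per stimulus x attribute cell")
    v <- ratings$category[idx]
    s <- stats::sd(v)
    if (s == 0) next
    mu <- mean(v)
    bad <- v < mu - k_sd * s | v > mu + k_sd * s
    if (all(bad))
      stop("all ratings removed for cell ", cell,
           "; validity filter is undefined here")
    if (any(bad)) {
      imp <- mean(v[!bad])
      if (round_imputed) imp <- round(imp)
      out$category[idx[bad]] <- imp
      removed[[length(removed) + 1L]] <- data.frame(
        rater_id = ratings$rater_id[idx[bad]],
        stimulus_id = ratings$stimulus_id[idx[bad]],
        attribute = ratings$attribute[idx[bad]],
        original = v[bad], imputed = imp,
        stringsAsFactors = FALSE)
    }
  }
  removed_df <- if (length(removed)) do.call(rbind, removed) else
    data.frame(rater_id = character(), stimulus_id = character(),
               attribute = character(), original = numeric(),
               imputed = numeric(), stringsAsFactors = FALSE)
  # alpha is reported when computable (>= 2 raters and stimuli with
  # nonzero total-score variance); degenerate tables yield NA
  alphas <- vapply(unique(ratings$attribute), function(a)
    tryCatch(cronbach_alpha(ratings_wide(ratings, a)),
             error = function(e) NA_real_), numeric(1))
  report <- structure(list(alpha = alphas,
                           n_removed = nrow(removed_df),
                           n_cells = nrow(ratings),
                           removed = removed_df,
                           k_sd = k_sd),
                      class = "qc_report")
  list(ratings = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Rating QC report\n")
  cat(sprintf("  removed %d of %d ratings (%.2f%%), k_sd = %g\n",
              x$n_removed, x$n_cells, 100 * x$n_removed / x$n_cells, x$k_sd))
  cat("  Cronbach's alpha by attribute:\n")
  for (a in names(x$alpha))
    cat(sprintf("    %-13s %.3f\n", a, x$alpha[[a]]))
  invisible(x)
}
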