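# Thurstonian scaling by the method of successive categories: stimulus
# scale values f(a_j) and category boundaries t_g are estimated jointly
# from inverse-normal transformed cumulative response proportions. The
# category-judgment layout z_gj = t_g - f(a_j) is solved by row and
# column means, which is the least-squares solution for a complete
# design under the zero-mean identifiability constraint.

#' Fit the method of successive categories to one attribute's ratings
#'
#' For stimulus `j` and interior category `g` in `1..m-1`, the
#' cumulative proportion `P_gj` of responses at or below `g` is
#' computed across raters (a response counts as "<= g" when its value
#' is below `g + 0.5`, so real-valued imputed ratings are handled
#' consistently). Proportions are clipped into
#' `[1/(2N), 1 - 1/(2N)]` (N raters) or, with `clip = "drop"`,
#' extreme cells are dropped and the incomplete layout solved by least
#' squares. The normal transform `z_gj = qnorm(P_gj)` then satisfies
#' `z_gj = t_g - f(a_j)`; boundaries are column means of z and scale
#' values are `mean(t) - ` row means of z, with `mean(f) = 0`.
#'
#' @param x stimulus x rater matrix of ratings (integer or real), or a
#'   long `rating_matrix` data.frame plus `attribute`.
#' @param m number of categories (default 9).
#' @param clip `"proportion"` (default: clip extreme proportions) or
#'   `"drop"` (drop 0/1 cells and solve the incomplete layout).
#' @param attribute attribute name when `x` is a long data.frame.
#' @return object of class `psych_scale`: `scale_values` (named,
#'   z-units, mean 0), `boundaries` (`t_1..t_{m-1}`), the `z` and `P`
#'   tables, `n_raters`, and `flagged` (stimuli whose responses gave no
#'   interior information before clipping).
#' @export
fit_successive_categories <- function(x, m = 9, clip = c("proportion", "drop"),
                                      attribute = NULL) {
  clip <- match.arg(clip)
  if (is.data.frame(x)) {
    if (is.null(attribute)) stop("attribute must be given for long input")
    x <- ratings_wide(x, attribute)
  }
  x <- as.matrix(x)
  n_stim <- nrow(x)
  n_raters <- ncol(x)
  if (m < 3) stop("need at least 3 categories")
  if (n_stim < 2) stop("need at least 2 stimuli")
  g <- seq_len(m - 1)
  # P[j, g] = proportion of responses below g + 0.5
  P <- vapply(g, function(gg) rowMeans(x < gg + 0.5), numeric(n_stim))
  P <- matrix(P, n_stim, m - 1,
              dimnames = list(rownames(x), paste0("C", g)))
  flagged <- rownames(x)[rowSums(P > 0 & P < 1) == 0]
  lo <- 1 / (2 * n_raters)
  if (clip == "proportion") {
    Pc <- pmin(pmax(P, lo), 1 - lo)
    sol <- scale_from_proportions(Pc)
    z <- sol$z
    boundaries <- sol$boundaries
    scale_values <- sol$scale_values
  } else {
    z <- stats::qnorm(P)
    z[!is.finite(z)] <- NA
    if (sum(colSums(!is.na(z)) > 0) < 2)
      stop("fewer than 2 usable boundary rows after dropping extreme cells")
    sol <- solve_category_layout(z)
    boundaries <- sol$t
    scale_values <- sol$f
    Pc <- P
  }
  names(scale_values) <- rownames(x)
  names(boundaries) <- paste0("t", g)
  structure(list(scale_values = scale_values, boundaries = boundaries,
                 z = z, P = Pc, n_raters = n_raters, m = m,
                 flagged = flagged, clip = clip),
            class = "psych_scale")
}

#' Scale values and boundaries from a cumulative-proportion table
#'
#' Core of the successive-categories estimator: given the table of
#' interior cumulative proportions `P[j, g]` (stimuli x boundaries,
#' all strictly inside (0, 1)), applies the inverse-normal transform
#' `z_gj = qnorm(P_gj)` and solves the category-judgment layout
#' `z_gj = t_g - f(a_j)` by column and row means under `mean(f) = 0`.
#'
#' @param P numeric matrix of cumulative proportions, stimuli in rows.
#' @return list with `scale_values`, `boundaries` and the `z` table.
#' @export
scale_from_proportions <- function(P) {
  P <- as.matrix(P)
  if (any(P <= 0 | P >= 1)) stop("proportions must lie strictly in (0, 1)")
  z <- stats::qnorm(P)
  boundaries <- colMeans(z)                     # t_g, with mean f = 0
  scale_values <- mean(boundaries) - rowMeans(z)
  list(scale_values = scale_values, boundaries = boundaries, z = z)
}

# Least-squares solve of z_gj = t_g - f_j (possibly with missing
# cells), under the constraint mean(f) = 0. Used for the "drop"
# clipping mode; on a complete layout it coincides with row/column
# means.
solve_category_layout <- function(z) {
  n <- nrow(z)
  k <- ncol(z)
  obs <- which(!is.na(z), arr.ind = TRUE)
  y <- z[obs]
  # parameters: t_1..t_k, f_1..f_{n-1} with f_n = -sum(f_1..f_{n-1})
  X <- matrix(0, length(y), k + n - 1)
  X[cbind(seq_along(y), obs[, 2])] <- 1
  for (r in seq_along(y)) {
    j <- obs[r, 1]
    if (j < n) X[r, k + j] <- X[r, k + j] - 1
    else X[r, k + seq_len(n - 1)] <- X[r, k + seq_len(n - 1)] + 1
  }
  beta <- stats::lm.fit(X, y)$coefficients
  beta[is.na(beta)] <- 0
  t_hat <- beta[seq_len(k)]
  f_hat <- c(beta[k + seq_len(n - 1)], -sum(beta[k + seq_len(n - 1)]))
  list(t = unname(t_hat), f = unname(f_hat))
}

#' @export
print.psych_scale <- function(x, ...) {
  cat(sprintf("<psych_scale: %d stimuli, %d categories, %d raters>\n",
              length(x$scale_values), x$m, x$n_raters))
  cat("  boundaries:", sprintf("%.3f", x$boundaries), "\n")
  if (length(x$flagged))
    cat("  flagged (no interior information):",
        paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Map a z-unit psychological scale onto category units
#'
#' Fits, by least squares, the affine map sending the estimated
#' boundaries `t_g` to their nominal positions `g + 0.5` on the 1..m
#' category axis, and applies the same map to the scale values. The
#' map is order preserving and invariant to positive affine changes of
#' the z-unit scale.
#'
#' @param scale a `psych_scale`.
#' @return the scale with elements `scale_cat` (category-unit values)
#'   and `boundaries_cat` added.
#' @export
rescale_to_categories <- function(scale) {
  stopifnot(inherits(scale, "psych_scale"))
  t_g <- scale$boundaries
  if (length(t_g) < 2 || stats::sd(t_g) == 0)
    stop("need at least 2 distinct finite boundaries")
  target <- seq_along(t_g) + 0.5
  fit <- stats::lm.fit(cbind(1, t_g), target)
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  if (b <= 0) stop("degenerate boundary configuration")
  scale$scale_cat <- a + b * scale$scale_values
  scale$boundaries_cat <- a + b * t_g
  scale
}

#' Fit and rescale all four attributes of a cleaned rating set
#'
#' Convenience wrapper running [fit_successive_categories()] and
#' [rescale_to_categories()] per attribute.
#'
#' @param ratings long cleaned rating data.frame.
#' @param m number of categories.
#' @param clip clipping mode, see [fit_successive_categories()].
#' @return list with `scales` (per-attribute `psych_scale`) and
#'   `values` (data.frame: stimulus_id, one z-unit and one
#'   category-unit column per attribute).
#' @export
fit_all_attributes <- function(ratings, m = 9, clip = "proportion") {
  attrs <- unique(ratings$attribute)
  scales <- lapply(attrs, function(a)
    rescale_to_categories(
      fit_successive_categories(ratings, m = m, clip = clip, attribute = a)))
  names(scales) <- attrs
  stim <- names(scales[[1]]$scale_values)
  values <- data.frame(stimulus_id = stim, stringsAsFactors = FALSE)
  for (a in attrs) {
    values[[paste0(a, "_z")]] <- unname(scales[[a]]$scale_values[stim])
    values[[paste0(a, "_cat")]] <- unname(scales[[a]]$scale_cat[stim])
  }
  list(scales = scales, values = values)
}
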