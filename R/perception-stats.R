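# Statistical battery over psychological scale values: category
# frequency tables, normal P-P coordinates, one- and two-way ANOVA,
# Student-Newman-Keuls homogeneous subsets, attribute correlations and
# a two-dimensional preference map.

#' Category frequency table by group
#'
#' Bins category-unit scale values (or raw ratings) into categories
#' `C1..Cm` (value v falls in category g when `g - 0.5 <= v < g + 0.5`,
#' clamped to the ends) and tabulates counts and percentages per group.
#'
#' @param values numeric vector of category-unit values.
#' @param groups grouping factor (e.g. envelope class), same length.
#' @param m number of categories.
#' @return data.frame: group, category, count, percent; counts per
#'   group sum to the group size and percentages to 100.
#' @export
category_frequencies <- function(values, groups, m = 9) {
  groups <- as.factor(groups)
  if (any(is.na(groups))) stop("unknown (NA) group label")
  if (nlevels(groups) == 0 || length(values) == 0) stop("empty input")
  cat_of <- pmin(pmax(round(values), 1L), m)
  out <- expand.grid(group = levels(groups), category = paste0("C", 1:m),
                     stringsAsFactors = FALSE)
  tab <- table(groups, factor(cat_of, levels = 1:m))
  out$count <- as.vector(tab)
  gsize <- as.vector(table(groups))
  out$percent <- 100 * out$count / gsize[match(out$group, levels(groups))]
  out[order(out$group), ]
}

#' Normal P-P plot coordinates
#'
#' Pairs the empirical cumulative probability of each sorted
#' observation with the fitted-normal model probability
#' `pnorm((x - mean)/sd)`. Points on the identity line indicate exact
#' normality.
#'
#' @param values numeric vector, n >= 3, nonzero variance.
#' @return data.frame with nondecreasing columns `empirical` and
#'   `model`, both in \[0, 1\].
#' @export
normality_pp <- function(values) {
  values <- sort(values[is.finite(values)])
  n <- length(values)
  if (n < 3) stop("need at least 3 observations")
  s <- stats::sd(values)
  if (s == 0) stop("zero variance: P-P coordinates undefined")
  data.frame(empirical = (seq_len(n) - 0.5) / n,
             model = stats::pnorm((values - mean(values)) / s))
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition via `stats::lm`/`anova`.
#'
#' @param values numeric response.
#' @param factor_ grouping factor with >= 2 levels.
#' @return data.frame of class `anova_result`: term, df, sum_sq,
#'   mean_sq, statistic (F), p_value; last row is the residual.
#' @export
one_way_anova <- function(values, factor_) {
  factor_ <- droplevels(as.factor(factor_))
  if (nlevels(factor_) < 2) stop("need at least 2 groups")
  fit <- stats::lm(values ~ factor_)
  tab <- stats::anova(fit)
  structure(data.frame(
    term = c("group", "residual"),
    df = tab$Df, sum_sq = tab$`Sum Sq`, mean_sq = tab$`Mean Sq`,
    statistic = tab$`F value`, p_value = tab$`Pr(>F)`,
    stringsAsFactors = FALSE),
    class = c("anova_result", "data.frame"))
}

#' Two-way analysis of variance with interaction screening
#'
#' Fits the full two-factor model with interaction using Type III sums
#' of squares under sum-to-zero contrasts (the appropriate choice for
#' the unbalanced designs typical of dyad experiments). If the
#' interaction is not significant at `alpha`, the model is refit with
#' main effects only, mirroring the usual model-simplification step.
#'
#' @param values numeric response.
#' @param factor_a,factor_b the two factors (e.g. envelope class and
#'   instrument culture); every cell of the cross must be nonempty.
#' @param alpha significance level for dropping the interaction.
#' @return list with `full` (anova_result incl. interaction row first)
#'   and `refit` (main-effects-only anova_result, or NULL when the
#'   interaction is retained).
#' @export
two_way_anova <- function(values, factor_a, factor_b, alpha = 0.05) {
  fa <- droplevels(as.factor(factor_a))
  fb <- droplevels(as.factor(factor_b))
  cells <- table(fa, fb)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: %s x %s",
                 rownames(cells)[bad[1]], colnames(cells)[bad[2]]))
  }
  dat <- data.frame(y = values, A = fa, B = fb)
  fit <- stats::lm(y ~ A * B, data = dat,
                   contrasts = list(A = "contr.sum", B = "contr.sum"))
  tab <- car::Anova(fit, type = 3)
  rows <- c("A:B", "A", "B", "Residuals")
  tab <- tab[rows, ]
  full <- structure(data.frame(
    term = c("interaction", "factor_a", "factor_b", "residual"),
    df = tab$Df, sum_sq = tab$`Sum Sq`,
    mean_sq = tab$`Sum Sq` / tab$Df,
    statistic = tab$`F value`, p_value = tab$`Pr(>F)`,
    stringsAsFactors = FALSE),
    class = c("anova_result", "data.frame"))
  refit <- NULL
  if (full$p_value[1] > alpha) {
    fit2 <- stats::lm(y ~ A + B, data = dat,
                      contrasts = list(A = "contr.sum", B = "contr.sum"))
    tab2 <- car::Anova(fit2, type = 3)[c("A", "B", "Residuals"), ]
    refit <- structure(data.frame(
      term = c("factor_a", "factor_b", "residual"),
      df = tab2$Df, sum_sq = tab2$`Sum Sq`,
      mean_sq = tab2$`Sum Sq` / tab2$Df,
      statistic = tab2$`F value`, p_value = tab2$`Pr(>F)`,
      stringsAsFactors = FALSE),
      class = c("anova_result", "data.frame"))
  }
  list(full = full, refit = refit)
}

#' Student-Newman-Keuls homogeneous subsets
#'
#' Stepwise studentized-range procedure on the ordered group means:
#' for a stretch of p adjacent ordered means, the range is compared to
#' `qtukey(1 - alpha, p, df) * sqrt(MSE / n_h)` with `n_h` the harmonic
#' mean of the group sizes in the stretch. Non-significant stretches
#' form homogeneous subsets (SPSS-style output); a subset contained in
#' another is dropped.
#'
#' @param values numeric response.
#' @param factor_ grouping factor; every group needs >= 2 observations.
#' @param alpha test level.
#' @return object of class `snk_result`: list with `means` (ordered
#'   group means), `subsets` (list of character vectors covering all
#'   groups) and `alpha`.
#' @export
snk_groups <- function(values, factor_, alpha = 0.05) {
  f <- droplevels(as.factor(factor_))
  if (nlevels(f) < 2) stop("need at least 2 groups")
  ns <- tapply(values, f, length)
  if (any(ns < 2)) stop("every group needs at least 2 observations")
  means <- sort(tapply(values, f, mean))
  k <- length(means)
  aov_tab <- one_way_anova(values, f)
  mse <- aov_tab$mean_sq[aov_tab$term == "residual"]
  df_err <- aov_tab$df[aov_tab$term == "residual"]
  ord_names <- names(means)
  ord_ns <- ns[ord_names]
  # significant[i, j]: means i..j (ordered) differ by SNK
  differs <- function(i, j) {
    p <- j - i + 1
    n_h <- p / sum(1 / ord_ns[i:j])
    q_obs <- (means[j] - means[i]) / sqrt(mse / n_h)
    q_crit <- stats::qtukey(1 - alpha, p, df_err)
    isTRUE(q_obs > q_crit)
  }
  # Stepwise: a stretch is homogeneous if its own range test fails AND
  # no tested enclosing stretch already declared it split. Standard
  # shortcut: find maximal stretches whose range test is non-significant.
  homo <- matrix(FALSE, k, k)
  for (span in seq(k, 1)) {
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      homo[i, j] <- if (i == j) TRUE else !differs(i, j)
    }
  }
  subsets <- list()
  i <- 1
  covered_to <- 0
  for (i in seq_len(k)) {
    j <- i
    while (j < k && homo[i, j + 1]) j <- j + 1
    if (j > covered_to) {
      subsets[[length(subsets) + 1L]] <- ord_names[i:j]
      covered_to <- j
    }
  }
  structure(list(means = means, subsets = subsets, alpha = alpha,
                 mse = mse, df_error = df_err),
            class = "snk_result")
}

#' @export
print.snk_result <- function(x, ...) {
  cat(sprintf("SNK homogeneous subsets (alpha = %g)\n", x$alpha))
  for (s in seq_along(x$subsets))
    cat(sprintf("  subset %d: %s\n", s,
                paste(sprintf("%s (%.3f)", x$subsets[[s]],
                              x$means[x$subsets[[s]]]), collapse = ", ")))
  invisible(x)
}

#' Pearson correlations among perception attributes
#'
#' @param scales data.frame or matrix of per-stimulus scale values,
#'   one column per attribute (>= 3 rows).
#' @return list with `r` (symmetric correlation matrix, unit diagonal)
#'   and `p` (two-tailed p-values, NA on the diagonal). Zero-variance
#'   attributes yield an error naming the column.
#' @export
attribute_correlations <- function(scales) {
  x <- as.matrix(scales)
  if (nrow(x) < 3) stop("need at least 3 stimuli")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance attribute: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  r <- stats::cor(x)
  p <- matrix(NA_real_, ncol(x), ncol(x), dimnames = dimnames(r))
  for (i in seq_len(ncol(x) - 1)) {
    for (j in seq((i + 1), ncol(x))) {
      pv <- stats::cor.test(x[, i], x[, j])$p.value
      p[i, j] <- pv
      p[j, i] <- pv
    }
  }
  list(r = r, p = p)
}

#' Multidimensional preference map of attributes and stimuli
#'
#' Two-dimensional principal-component decomposition of the
#' column-standardized stimulus x attribute matrix. Attribute loadings
#' are the correlations between each attribute and the component
#' scores, stimulus coordinates are the (scaled) scores, and class
#' centroids are the mean coordinates per metadata group. Dimension
#' signs are fixed so that fusion loads positively on dimension 1 and
#' segregation positively on dimension 2, making maps reproducible.
#'
#' @param scales per-stimulus attribute matrix (>= 3 stimuli, >= 2
#'   attributes, rank >= 2).
#' @param metadata optional data.frame aligned with rows of `scales`;
#'   columns `envelope_class` and/or `culture` define centroids.
#' @return object of class `preference_map`: `loadings` (attributes x
#'   2, |loading| <= 1), `scores` (stimuli x 2), `centroids`,
#'   `var_explained` (length 2, nonincreasing).
#' @export
mdpref_map <- function(scales, metadata = NULL) {
  x <- as.matrix(scales)
  if (nrow(x) < 3) stop("need at least 3 stimuli")
  xs <- scale(x)
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  if (length(pc$sdev) < 2 || pc$sdev[2] < 1e-10)
    stop("attribute matrix has rank < 2; no 2-d map exists")
  scores <- pc$x[, 1:2, drop = FALSE]
  loadings <- stats::cor(xs, scores)
  colnames(loadings) <- colnames(scores) <- c("dim1", "dim2")
  flip <- c(1, 1)
  if ("fusion" %in% rownames(loadings) && loadings["fusion", 1] < 0)
    flip[1] <- -1
  if ("segregation" %in% rownames(loadings) && loadings["segregation", 2] < 0)
    flip[2] <- -1
  loadings <- sweep(loadings, 2, flip, `*`)
  scores <- sweep(scores, 2, flip, `*`)
  var_explained <- pc$sdev[1:2]^2 / sum(pc$sdev^2)
  centroids <- NULL
  if (!is.null(metadata)) {
    keys <- intersect(c("envelope_class", "culture"), names(metadata))
    if (length(keys)) {
      grp <- interaction(metadata[keys], drop = TRUE, sep = " / ")
      centroids <- apply(scores, 2, function(cc) tapply(cc, grp, mean))
      centroids <- matrix(centroids, nlevels(grp), 2,
                          dimnames = list(levels(grp), c("dim1", "dim2")))
    }
  }
  structure(list(loadings = loadings, scores = scores,
                 centroids = centroids, var_explained = var_explained),
            class = "preference_map")
}

#' @export
print.preference_map <- function(x, ...) {
  cat(sprintf("Preference map: %.1f%% + %.1f%% variance explained\n",
              100 * x$var_explained[1], 100 * x$var_explained[2]))
  print(round(x$loadings, 3))
  invisible(x)
}
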