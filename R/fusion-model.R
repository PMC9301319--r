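# Fusion-prediction models: lasso-regularized linear regression,
# random forest, and a small multilayer perceptron, evaluated by
# 4-fold cross-validated R-squared, plus extraction of the
# large-coefficient linear fusion equation.

#' Goodness of fit R-squared
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. Equals 1 for
#' perfect prediction, 0 for predicting the mean; can be negative for
#' out-of-sample predictions worse than the mean.
#'
#' @param y observed values (nonconstant, length >= 2).
#' @param yhat predictions of the same length.
#' @return scalar R-squared.
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2)
    stop("y and yhat must have equal length >= 2")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("constant observed vector: R-squared undefined")
  1 - sum((y - yhat)^2) / sst
}

standardize_features <- function(x, center = NULL, sd_ = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  if (is.null(sd_)) {
    sd_ <- apply(x, 2, stats::sd)
    sd_[sd_ == 0] <- 1
  }
  list(x = sweep(sweep(x, 2, center), 2, sd_, `/`), center = center, sd = sd_)
}

# Minimal one-hidden-layer perceptron, ReLU activation, plain
# stochastic gradient descent. Written out explicitly so the
# optimizer, learning rate and seeding are fully under our control.
mlp_train <- function(x, y, hidden = 32, lr = 0.001, epochs = 300, seed = 1L) {
  n <- nrow(x); d <- ncol(x)
  with_preserved_seed(seed, {
    W1 <- matrix(stats::rnorm(d * hidden, sd = sqrt(2 / d)), d, hidden)
    b1 <- numeric(hidden)
    w2 <- stats::rnorm(hidden, sd = sqrt(1 / hidden))
    b2 <- 0
    for (ep in seq_len(epochs)) {
      for (i in sample.int(n)) {
        xi <- x[i, ]
        h_pre <- drop(xi %*% W1) + b1
        h <- pmax(h_pre, 0)
        pred <- sum(h * w2) + b2
        err <- pred - y[i]
        gw2 <- err * h
        gh <- err * w2 * (h_pre > 0)
        W1 <- W1 - lr * outer(xi, gh)
        b1 <- b1 - lr * gh
        w2 <- w2 - lr * gw2
        b2 <- b2 - lr * err
      }
    }
    list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
  })
}

mlp_predict <- function(net, x) {
  h <- pmax(sweep(x %*% net$W1, 2, net$b1, `+`), 0)
  drop(h %*% net$w2) + net$b2
}

#' Fit a fusion-prediction model
#'
#' Features are z-standardized internally (so linear coefficients are
#' comparable across features and the `|coef| > 4` selection rule is
#' meaningful). Model kinds:
#' * `linear_lasso` - [glmnet::glmnet()] with the penalty chosen by
#'   inner cross-validation on the training data;
#' * `random_forest` - [randomForest::randomForest()] with 10 trees
#'   and at most 6 candidate features per split;
#' * `mlp` - one hidden layer of 32 rectified-linear units trained by
#'   stochastic gradient descent at learning rate 0.001.
#'
#' @param x feature matrix / data.frame (no missing values, n >= 10).
#' @param y numeric target (fusion scale values).
#' @param kind model kind.
#' @param config named list of overrides: `lambda` (fixed lasso
#'   penalty), `ntree`, `mtry`, `hidden`, `lr`, `epochs`.
#' @param seed integer seed; results are deterministic given it.
#' @return object of class `model_result`: kind, the fitted object,
#'   `r_squared` (in-sample), `coefficients` (standardized scale;
#'   linear kind only), standardization constants, hyperparameters,
#'   seed.
#' @export
fit_model <- function(x, y, kind = c("linear_lasso", "random_forest", "mlp"),
                      config = list(), seed = 1L) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  if (nrow(x) < 10) stop("need at least 10 observations")
  bad <- !apply(is.finite(x), 2, all)
  if (any(bad))
    stop("non-finite feature column(s): ",
         paste(colnames(x)[bad], collapse = ", "))
  std <- standardize_features(x)
  xs <- std$x
  fitted_obj <- NULL
  coefs <- NULL
  hyper <- list()
  with_preserved_seed(seed, {
    if (kind == "linear_lasso") {
      if (!is.null(config$lambda)) {
        lambda <- config$lambda
      } else {
        cv <- glmnet::cv.glmnet(xs, y, alpha = 1, nfolds = 5)
        lambda <- cv$lambda.min
      }
      fitted_obj <- glmnet::glmnet(xs, y, alpha = 1, lambda = lambda)
      coefs <- drop(as.matrix(stats::coef(fitted_obj)))[-1]
      hyper <- list(lambda = lambda)
      yhat <- drop(stats::predict(fitted_obj, xs))
    } else if (kind == "random_forest") {
      ntree <- config$ntree %||% 10
      mtry <- min(config$mtry %||% 6, ncol(xs))
      fitted_obj <- randomForest::randomForest(xs, y, ntree = ntree,
                                               mtry = mtry)
      hyper <- list(ntree = ntree, mtry = mtry)
      yhat <- stats::predict(fitted_obj, xs)
    } else {
      hidden <- config$hidden %||% 32
      lr <- config$lr %||% 0.001
      epochs <- config$epochs %||% 300
      fitted_obj <- mlp_train(xs, y, hidden, lr, epochs,
                              seed = sample.int(.Machine$integer.max - 1L, 1))
      hyper <- list(hidden = hidden, lr = lr, epochs = epochs)
      yhat <- mlp_predict(fitted_obj, xs)
    }
  })
  structure(list(kind = kind, fit = fitted_obj,
                 r_squared = r_squared(y, yhat),
                 coefficients = coefs,
                 center = std$center, sd = std$sd,
                 hyper = hyper, seed = seed),
            class = "model_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict from a fitted fusion model
#'
#' @param object a `model_result`.
#' @param newdata feature matrix on the original (unstandardized) scale.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.model_result <- function(object, newdata, ...) {
  xs <- standardize_features(as.matrix(newdata), object$center, object$sd)$x
  switch(object$kind,
         linear_lasso = drop(stats::predict(object$fit, xs)),
         random_forest = stats::predict(object$fit, xs),
         mlp = mlp_predict(object$fit, xs))
}

#' k-fold cross-validated R-squared
#'
#' Random (seeded) partition of the index set into `k` folds; each
#' fold is predicted by a model trained on the remaining folds.
#'
#' @param x feature matrix.
#' @param y target vector.
#' @param kind model kind, see [fit_model()].
#' @param k number of folds (default 4).
#' @param config passed to [fit_model()].
#' @param seed integer seed for both the split and the fold models.
#' @return list: `fold_r_squared` (length k), `mean_r_squared`,
#'   `folds` (the index assignment).
#' @export
cross_validate <- function(x, y, kind = "linear_lasso", k = 4,
                           config = list(), seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 2) stop("need at least 2 folds")
  if (n < k) stop("fewer observations than folds")
  with_preserved_seed(seed, {
    folds <- sample(rep(seq_len(k), length.out = n))
    fold_seeds <- sample.int(.Machine$integer.max - 1L, k)
    r2 <- vapply(seq_len(k), function(fi) {
      tr <- folds != fi
      fit <- fit_model(x[tr, , drop = FALSE], y[tr], kind, config,
                       seed = fold_seeds[fi])
      r_squared(y[!tr], predict(fit, x[!tr, , drop = FALSE]))
    }, numeric(1))
    list(fold_r_squared = r2, mean_r_squared = mean(r2), folds = folds)
  })
}

#' Extract the large-coefficient fusion equation
#'
#' Retains standardized linear coefficients with `|coef| > threshold`,
#' ordered by decreasing magnitude, and renders them as a signed
#' linear equation over feature symbols.
#'
#' @param model a linear `model_result` (with coefficients).
#' @param threshold absolute-coefficient cutoff (default 4).
#' @param target_label label for the fitted subset
#'   (`"Chinese"`, `"Western"` or `"all"`).
#' @return object of class `fusion_equation`: data.frame `terms`
#'   (feature, coefficient), `target_label`, `threshold` and a
#'   rendered `text` like `F_all = 14.2*X_harmonic_energy_mean - ...`;
#'   empty (with a warning) when nothing passes the threshold.
#' @export
extract_fusion_equation <- function(model, threshold = 4,
                                    target_label = "all") {
  stopifnot(inherits(model, "model_result"))
  if (is.null(model$coefficients))
    stop("equation extraction needs a linear model with coefficients")
  co <- model$coefficients
  keep <- co[abs(co) > threshold]
  keep <- keep[order(-abs(keep))]
  if (length(keep) == 0)
    warning("no coefficient exceeds |", threshold, "|; empty equation")
  terms <- data.frame(feature = names(keep), coefficient = unname(keep),
                      stringsAsFactors = FALSE)
  text <- if (nrow(terms)) {
    pieces <- sprintf("%s%.1f*X_%s",
                      ifelse(terms$coefficient < 0, "- ", "+ "),
                      abs(terms$coefficient), terms$feature)
    pieces[1] <- sub("^\\+ ", "", pieces[1])
    pieces[1] <- sub("^- ", "-", pieces[1])
    paste0("F_", target_label, " = ", paste(pieces, collapse = " "))
  } else paste0("F_", target_label, " = (empty)")
  structure(list(terms = terms, target_label = target_label,
                 threshold = threshold, text = text),
            class = "fusion_equation")
}

#' @export
print.fusion_equation <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}

#' Fit all model kinds on pooled and per-culture subsets
#'
#' Cross-validates every model kind on the Chinese-only, Western-only
#' and pooled stimulus sets and extracts a fusion equation per subset
#' from the lasso fit on that subset.
#'
#' @param features data.frame with `stimulus_id` and feature columns.
#' @param target named numeric vector of fusion scale values (names =
#'   stimulus ids) or data.frame with `stimulus_id` and `fusion`.
#' @param metadata data.frame with `stimulus_id` and `culture`.
#' @param kinds model kinds to fit.
#' @param k folds.
#' @param threshold coefficient cutoff for the equations.
#' @param seed integer seed.
#' @return list: `grid` (data.frame kind x subset with mean CV
#'   R-squared), `cv` (nested per-kind/subset results), `equations`
#'   (per-subset `fusion_equation`).
#' @export
run_grouped_models <- function(features, target, metadata,
                               kinds = c("linear_lasso", "random_forest",
                                         "mlp"),
                               k = 4, threshold = 4, seed = 1L) {
  if (is.data.frame(target)) {
    tv <- target$fusion
    names(tv) <- target$stimulus_id
    target <- tv
  }
  stopifnot(all(features$stimulus_id %in% names(target)),
            all(features$stimulus_id %in% metadata$stimulus_id))
  x_all <- as.matrix(features[setdiff(names(features), "stimulus_id")])
  rownames(x_all) <- features$stimulus_id
  y_all <- target[features$stimulus_id]
  culture <- metadata$culture[match(features$stimulus_id,
                                    metadata$stimulus_id)]
  subsets <- list(Chinese = culture == "Chinese",
                  Western = culture == "Western",
                  all = rep(TRUE, length(culture)))
  subsets <- Filter(any, subsets)
  with_preserved_seed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L,
                        length(kinds) * length(subsets) + length(subsets))
  })
  si <- 0L
  cv <- list()
  rows <- list()
  for (sub in names(subsets)) {
    idx <- subsets[[sub]]
    if (sum(idx) < k) stop("subset ", sub, " smaller than the fold count")
    for (kind in kinds) {
      si <- si + 1L
      res <- cross_validate(x_all[idx, , drop = FALSE], y_all[idx], kind,
                            k = k, seed = seeds[si])
      cv[[sub]][[kind]] <- res
      rows[[length(rows) + 1L]] <- data.frame(
        kind = kind, subset = sub, mean_r_squared = res$mean_r_squared,
        stringsAsFactors = FALSE)
    }
  }
  equations <- list()
  for (sub in names(subsets)) {
    si <- si + 1L
    idx <- subsets[[sub]]
    lasso <- fit_model(x_all[idx, , drop = FALSE], y_all[idx],
                       "linear_lasso", seed = seeds[si])
    equations[[sub]] <- extract_fusion_equation(lasso, threshold,
                                                target_label = sub)
  }
  list(grid = do.call(rbind, rows), cv = cv, equations = equations)
}
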