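test_that("category frequencies conserve counts and percentages", {
  vals <- c(5, 5.2, 4.9, 5.4, 4.6)
  out <- category_frequencies(vals, rep("S+S", 5))
  expect_equal(sum(out$count), 5)
  expect_equal(sum(out$percent), 100)
  expect_equal(out$count[out$category == "C5"], 5)
  set.seed(41)
  vals <- runif(120, 1, 9)
  grp <- sample(c("S+S", "S+N", "N+N"), 120, replace = TRUE)
  out <- category_frequencies(vals, grp)
  for (g in unique(grp)) {
    expect_equal(sum(out$count[out$group == g]), sum(grp == g))
    expect_equal(sum(out$percent[out$group == g]), 100)
  }
})

test_that("high planted fusion lands in the upper categories", {
  design <- list(Chinese = c("S+S" = 40))
  ss <- build_stimulus_set(design, seed = 42, duration_s = 0.05)
  r <- synth_ratings(latent_percept_model(stimulus_sd = 0.6),
                     ss$metadata, n_raters = 32, seed = 43)
  sc <- rescale_to_categories(
    fit_successive_categories(r, attribute = "fusion"))
  out <- category_frequencies(sc$scale_cat, rep("S+S", 40))
  modal <- out$category[which.max(out$count)]
  expect_true(modal %in% c("C5", "C6", "C7", "C8"))
})

test_that("normal P-P coordinates behave as a normality check", {
  pp_exact <- normality_pp(qnorm((1:50 - 0.5) / 50))
  expect_lt(max(abs(pp_exact$empirical - pp_exact$model)), 0.01)
  expect_true(all(diff(pp_exact$empirical) >= 0))
  expect_true(all(diff(pp_exact$model) >= 0))
  set.seed(44)
  pp_norm <- normality_pp(rnorm(500))
  expect_lt(max(abs(pp_norm$empirical - pp_norm$model)), 0.05)
  pp_heavy <- normality_pp(rcauchy(500))
  expect_gt(max(abs(pp_heavy$empirical - pp_heavy$model)),
            max(abs(pp_norm$empirical - pp_norm$model)))
  expect_error(normality_pp(rep(3, 10)), "variance")
})

test_that("one-way ANOVA matches a direct sums-of-squares oracle", {
  vals <- c(3, 5, 4, 8, 9, 7)
  grp <- rep(c("a", "b"), each = 3)
  out <- one_way_anova(vals, grp)
  # brute-force decomposition
  gm <- mean(vals)
  means <- tapply(vals, grp, mean)
  ssb <- sum(3 * (means - gm)^2)
  ssw <- sum((vals - means[grp])^2)
  f_oracle <- (ssb / 1) / (ssw / 4)
  expect_equal(out$statistic[1], f_oracle, tolerance = 1e-9)
  expect_equal(out$sum_sq[1] + out$sum_sq[2], sum((vals - gm)^2),
               tolerance = 1e-9)
  expect_equal(out$p_value[1], pf(f_oracle, 1, 4, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("F is invariant to affine rescaling of the response", {
  set.seed(45)
  vals <- rnorm(30)
  grp <- rep(letters[1:3], 10)
  f1 <- one_way_anova(vals, grp)$statistic[1]
  f2 <- one_way_anova(3 * vals - 7, grp)$statistic[1]
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("equal-mean groups give a small F and large p", {
  set.seed(46)
  vals <- c(rnorm(40, 5), rnorm(40, 5))
  out <- one_way_anova(vals, rep(c("a", "b"), each = 40))
  expect_gt(out$p_value[1], 0.05)
})

test_that("two-way ANOVA screens and removes a null interaction", {
  set.seed(47)
  n <- 240
  A <- sample(c("S+S", "S+N", "N+N"), n, replace = TRUE)
  B <- sample(c("Chinese", "Western"), n, replace = TRUE)
  eff <- c("S+S" = 1.2, "S+N" = -1.2, "N+N" = 0)
  vals <- 5 + eff[A] + rnorm(n, sd = 0.8)    # additive, no interaction
  out <- two_way_anova(vals, A, B)
  expect_equal(out$full$term[1], "interaction")
  expect_gt(out$full$p_value[1], 0.05)
  expect_false(is.null(out$refit))
  expect_lt(out$refit$p_value[out$refit$term == "factor_a"], 0.001)
  expect_gt(out$refit$p_value[out$refit$term == "factor_b"], 0.05)
  expect_error(two_way_anova(vals[1:10], rep("S+S", 10),
                             rep(c("Chinese", "Western"), 5)),
               "2|level|contrast")
})

test_that("balanced two-way design: Type III matches the classic fit", {
  set.seed(48)
  vals <- rnorm(48, mean = rep(c(0, 1, 2, 0, 1, 2), each = 8))
  A <- rep(rep(c("x", "y", "z"), each = 8), 2)
  B <- rep(c("u", "v"), each = 24)
  out <- two_way_anova(vals, A, B)
  cls <- anova(lm(vals ~ A * B))
  expect_equal(out$full$sum_sq[out$full$term == "factor_a"],
               cls["A", "Sum Sq"], tolerance = 1e-9)
  expect_equal(out$full$sum_sq[out$full$term == "factor_b"],
               cls["B", "Sum Sq"], tolerance = 1e-9)
})

test_that("SNK keeps identical groups together and splits separated ones", {
  set.seed(49)
  base <- rnorm(15)
  vals <- c(base, base, base)
  grp <- rep(c("a", "b", "c"), each = 15)
  out <- snk_groups(vals, grp)
  expect_equal(length(out$subsets), 1)
  expect_setequal(out$subsets[[1]], c("a", "b", "c"))
  # 10 pooled SDs apart -> all singletons
  vals2 <- c(rnorm(15), rnorm(15, 10), rnorm(15, 20))
  out2 <- snk_groups(vals2, grp)
  expect_equal(length(out2$subsets), 3)
  expect_true(all(lengths(out2$subsets) == 1))
})

test_that("SNK subsets form an exhaustive non-overlapping-means cover", {
  set.seed(50)
  for (rep in 1:5) {
    k <- sample(3:5, 1)
    vals <- rnorm(20 * k, mean = rep(runif(k, 0, 3), each = 20))
    grp <- rep(paste0("g", 1:k), each = 20)
    out <- snk_groups(vals, grp)
    expect_setequal(unique(unlist(out$subsets)), paste0("g", 1:k))
  }
})

test_that("SNK recovers the planted two-subset envelope pattern", {
  set.seed(51)
  lat <- rep(c(5.95, 5.67, 3.94), each = 20) + rnorm(60, sd = 0.8)
  cls <- rep(c("S+S", "N+N", "S+N"), each = 20)
  out <- snk_groups(lat, cls)
  expect_equal(length(out$subsets), 2)
  expect_equal(out$subsets[[1]], "S+N")
  expect_setequal(out$subsets[[2]], c("N+N", "S+S"))
})

test_that("attribute correlations have the expected structure", {
  set.seed(52)
  f <- rnorm(100)
  x <- cbind(fusion = f, segregation = -f,
             roughness = rnorm(100), pleasantness = rnorm(100))
  out <- attribute_correlations(x)
  expect_equal(out$r["fusion", "segregation"], -1)
  expect_equal(out$r, t(out$r))
  expect_equal(unname(diag(out$r)), rep(1, 4))
  expect_true(all(abs(out$r) <= 1 + 1e-12))
  ev <- eigen(out$r, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))   # positive semidefinite
  expect_error(attribute_correlations(cbind(a = rep(1, 10), b = rnorm(10))),
               "zero-variance")
})

test_that("independent attributes correlate weakly at large n", {
  set.seed(53)
  x <- matrix(rnorm(500 * 4), 500, 4,
              dimnames = list(NULL, TIMBRE_ATTRIBUTES))
  r <- attribute_correlations(x)$r
  expect_lt(max(abs(r[upper.tri(r)])), 0.1)
})

test_that("preference map has the planted sign and variance structure", {
  set.seed(54)
  f <- rnorm(200)
  rough <- rnorm(200)
  x <- cbind(fusion = f, segregation = -f + rnorm(200, sd = 0.05),
             roughness = rough, pleasantness = -rough + rnorm(200, sd = 0.05))
  out <- mdpref_map(x)
  expect_gt(out$loadings["fusion", 1], 0)
  expect_lt(out$loadings["segregation", 1], 0)
  expect_true(all(abs(out$loadings) <= 1 + 1e-9))
  expect_gte(out$var_explained[1], out$var_explained[2])
  # two planted orthogonal factors + tiny noise -> 2 dims explain >= 95%
  expect_gte(sum(out$var_explained), 0.95)
})

test_that("preference map is stable under stimulus reordering", {
  set.seed(55)
  x <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, TIMBRE_ATTRIBUTES))
  m1 <- mdpref_map(x)
  perm <- sample(60)
  m2 <- mdpref_map(x[perm, ])
  expect_equal(abs(m1$loadings), abs(m2$loadings), tolerance = 1e-8)
  expect_equal(m1$scores[perm, ], m2$scores, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("preference map rejects rank-deficient input", {
  f <- rnorm(30)
  expect_error(mdpref_map(cbind(fusion = f, segregation = 2 * f)),
               "rank")
})

test_that("preference map centroids separate planted envelope classes", {
  design <- list(Chinese = c("S+S" = 20, "S+N" = 20, "N+N" = 20))
  ss <- build_stimulus_set(design, seed = 56, duration_s = 0.05)
  r <- synth_ratings(latent_percept_model(), ss$metadata, n_raters = 24,
                     seed = 57)
  sc <- fit_all_attributes(r)
  x <- as.matrix(sc$values[paste0(TIMBRE_ATTRIBUTES, "_cat")])
  colnames(x) <- TIMBRE_ATTRIBUTES
  out <- mdpref_map(x, data.frame(envelope_class =
                                    ss$metadata$envelope_class))
  expect_equal(nrow(out$centroids), 3)
  # S+S (high fusion) and S+N (low fusion) lie on opposite sides of dim 1
  expect_gt(out$centroids["S+S", "dim1"], out$centroids["S+N", "dim1"])
})
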