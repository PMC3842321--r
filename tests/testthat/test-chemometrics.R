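test_that("preprocess centers, scales and replays via stored params", {
  set.seed(1)
  X <- cbind(a = rnorm(10, 5), b = rnorm(10, -2, 4), c = rep(3, 10))
  pn <- preprocess(X, "none")
  expect_equal(unname(colMeans(pn$X)), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(pn$X[, "c"]), rep(0, 10))
  expect_warning(puv <- preprocess(X, "unit_variance"), "zero-variance")
  expect_equal(unname(apply(puv$X, 2, sd)), c(1, 1), tolerance = 1e-12)
  X2 <- X[, 1:2]
  puv2 <- preprocess(X2, "unit_variance")
  expect_equal(apply_preprocess(puv2$params, X2), puv2$X)
  pp <- preprocess(X2, "pareto")
  expect_equal(unname(apply(pp$X, 2, sd)), unname(sqrt(apply(X2, 2, sd))),
               tolerance = 1e-12)
  expect_error(apply_preprocess(puv2$params, X2[, 2:1]), "match")
})

test_that("pca matches a brute-force covariance eigendecomposition", {
  set.seed(42)
  X <- matrix(rnorm(24), 6, 4)
  Xc <- scale(X, scale = FALSE)
  res <- pca(Xc, n_components = 3)
  ev_oracle <- eigen(cov(Xc), symmetric = TRUE)$values
  expect_equal(res$explained_variance, ev_oracle / sum(ev_oracle),
               tolerance = 1e-10)
  # completeness: full-rank scores reproduce the centered data
  res_full <- pca(Xc, n_components = 4)
  expect_equal(res_full$scores %*% t(res_full$loadings),
               unclass(Xc)[, ], ignore_attr = TRUE, tolerance = 1e-10)
  # collinear data: PC1 explains everything
  line <- outer(seq(-2, 2, length.out = 8), c(1, 2, -1))
  res_line <- pca(line, n_components = 1)
  expect_equal(res_line$explained_variance[1], 1, tolerance = 1e-12)
  expect_error(pca(matrix(0, 4, 3), 2), "rank 0")
  expect_error(pca(Xc, 7), "exceeds")
  expect_length(res$outlier, 6)
})

test_that("the first NIPALS weight matches the X'y closed form", {
  set.seed(11)
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c("a", "b"), each = 5)
  fit <- plsda_fit(X, y, n_components = 1, scaling = "none")
  Xt <- scale(X, scale = FALSE)
  ytilde <- as.numeric(y == "a") - mean(y == "a")
  w_oracle <- crossprod(Xt, ytilde)
  w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
  # sign-insensitive comparison
  expect_equal(abs(sum(fit$W[, 1] * w_oracle)), 1, tolerance = 1e-8)
})

test_that("PLS scores are orthogonal and B reproduces the score route", {
  set.seed(5)
  for (g in 2:3) {
    X <- matrix(rnorm(60), 15, 4)
    y <- sample(letters[seq_len(g)], 15, replace = TRUE)
    while (length(unique(y)) < g) y <- sample(letters[seq_len(g)], 15, TRUE)
    fit <- plsda_fit(X, y, n_components = 2)
    gram <- crossprod(fit$scores)
    expect_lt(abs(gram[1, 2]),
              1e-8 * sqrt(gram[1, 1] * gram[2, 2]))
    # oracle equivalence: deflation-route prediction vs compact B route
    X_new <- matrix(rnorm(20), 5, 4)
    Xt <- apply_preprocess(fit$preprocess, X_new)
    x_res <- Xt
    yhat <- matrix(0, 5, g)
    for (a in seq_len(fit$n_components)) {
      t_a <- x_res %*% fit$W[, a, drop = FALSE]
      yhat <- yhat + t_a %*% t(fit$Q[, a, drop = FALSE])
      x_res <- x_res - t_a %*% t(fit$P[, a, drop = FALSE])
    }
    yhat <- sweep(yhat, 2, fit$y_means, "+")
    expect_equal(unname(plsda_predict(fit, X_new)$scores), unname(yhat),
                 tolerance = 1e-8)
  }
})

test_that("duplicated features leave predictions unchanged under mode none", {
  set.seed(9)
  x1 <- rnorm(12)
  y <- rep(c("a", "b"), 6)
  X_dup <- cbind(f1 = x1, f2 = x1)
  X_scaled <- cbind(f1 = 2 * x1)
  fit_dup <- plsda_fit(X_dup, y, n_components = 1, scaling = "none")
  fit_one <- plsda_fit(X_scaled, y, n_components = 1, scaling = "none")
  new1 <- rnorm(4)
  p_dup <- plsda_predict(fit_dup, cbind(f1 = new1, f2 = new1))
  p_one <- plsda_predict(fit_one, cbind(f1 = 2 * new1))
  expect_equal(p_dup$scores, p_one$scores, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(p_dup$class, p_one$class)
})

test_that("separable classes give perfect training classification", {
  d <- separable_xy()
  fit <- plsda_fit(d$X, d$y, n_components = 2)
  expect_equal(plsda_predict(fit, d$X)$class, d$y)
})

test_that("exact class-score ties break to the alphabetically first class", {
  d <- separable_xy()
  fit <- plsda_fit(d$X, d$y, n_components = 1)
  # at the feature centroid the transformed row is 0, so both class scores
  # equal the (balanced) training means: an engineered exact tie
  centroid <- matrix(fit$preprocess$center, 1,
                     dimnames = list(NULL, colnames(d$X)))
  pr <- plsda_predict(fit, centroid)
  expect_equal(unname(pr$scores[1, 1]), unname(pr$scores[1, 2]))
  expect_equal(pr$class, "a")
})

test_that("plsda_fit validates input and truncates beyond the rank", {
  d <- separable_xy()
  expect_error(plsda_fit(d$X, rep("a", nrow(d$X))), ">= 2 classes")
  expect_error(plsda_fit(d$X[1:3, ], d$y), "differ")
  rank1 <- outer(seq_len(8), c(1, 2, 3))
  colnames(rank1) <- paste0("f", 1:3)
  y <- rep(c("a", "b"), 4)
  expect_warning(fit <- plsda_fit(rank1 + 0, y, n_components = 3,
                                  scaling = "none"),
                 "truncating")
  expect_lt(fit$n_components, 3)
})

test_that("mccv is perfect on separated data and reproducible", {
  d <- separable_xy(n_per = 8)
  cfg <- mccv_config(n_iterations = 60, seed = 21)
  res <- mccv(d$X, d$y, cfg)
  expect_equal(sum(diag(res$confusion)) / sum(res$confusion), 1)
  # aggregated counts equal iterations x per-class test allocation
  expect_equal(unname(rowSums(res$confusion)),
               rep(60 * round(8 / 3), 2))
  res2 <- mccv(d$X, d$y, cfg)
  expect_identical(res$confusion, res2$confusion)
  expect_error(mccv(d$X, c("a", rep("b", 15)), cfg), "too small")
})

test_that("label permutation drives accuracy to chance", {
  set.seed(31)
  X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rep(c("a", "b"), 20)  # balanced: chance accuracy 0.5
  res <- mccv(X, y, mccv_config(n_iterations = 500, seed = 77))
  acc <- sum(diag(res$confusion)) / sum(res$confusion)
  expect_lt(abs(acc - 0.5), 0.1)
})

test_that("performance reproduces the published confusion-derived metrics", {
  # two-class sporadic-vs-SDHx counts: 11/12 and 9/10 correct
  cm2 <- matrix(c(11L, 1L, 1L, 9L), 2, byrow = TRUE,
                dimnames = list(truth = c("SDHx", "sporadic"),
                                predicted = c("SDHx", "sporadic")))
  p2 <- performance_percent(performance(cm2, "SDHx"))
  expect_equal(unname(p2), c(92, 90, 92, 90, 91))
  # carrier collapse of the three-class counts: TP 17, FN 1, FP 2, TN 8
  cm3 <- matrix(c(17L, 1L, 2L, 8L), 2, byrow = TRUE,
                dimnames = list(truth = c("carrier", "sporadic"),
                                predicted = c("carrier", "sporadic")))
  p3 <- performance_percent(performance(cm3, "carrier"))
  expect_equal(unname(p3), c(94, 80, 89, 89, 89))
  # all-correct confusion: every metric 100%
  cmA <- matrix(c(5L, 0L, 0L, 7L), 2, byrow = TRUE,
                dimnames = list(truth = c("a", "b"), predicted = c("a", "b")))
  expect_equal(unname(performance_percent(performance(cmA, "a"))),
               rep(100, 5))
})

test_that("performance is permutation-invariant and NA on empty denominators", {
  cm <- matrix(c(6L, 2L, 1L, 9L), 2, byrow = TRUE,
               dimnames = list(truth = c("x", "y"), predicted = c("x", "y")))
  perm <- cm[c(2, 1), c(2, 1)]
  a <- performance(cm, "x"); b <- performance(perm, "x")
  expect_equal(a$se, b$se)
  expect_equal(a$ppv, b$ppv)
  expect_equal(a$accuracy, b$accuracy)
  # no true or predicted positives: Se and PPV undefined, never 0
  cm0 <- matrix(c(0L, 0L, 0L, 10L), 2, byrow = TRUE,
                dimnames = list(truth = c("x", "y"), predicted = c("x", "y")))
  p0 <- performance(cm0, "x")
  expect_true(is.na(p0$se))
  expect_true(is.na(p0$ppv))
  expect_equal(p0$sp, 1)
})

test_that("collapse_confusion pools class sets", {
  cm <- matrix(c(8L, 1L, 1L, 0L, 12L, 0L, 1L, 0L, 5L), 3, byrow = TRUE,
               dimnames = list(truth = c("sporadic", "SDHx", "VHL"),
                               predicted = c("sporadic", "SDHx", "VHL")))
  cc <- collapse_confusion(cm, list(carrier = c("SDHx", "VHL"),
                                    sporadic = "sporadic"))
  expect_equal(unname(cc["carrier", "carrier"]), 17)
  expect_equal(unname(cc["carrier", "sporadic"]), 1)
  expect_equal(unname(cc["sporadic", "carrier"]), 2)
  expect_equal(sum(cc), sum(cm))
})

test_that("the Q2 selector prefers a small model on low-rank data", {
  d <- separable_xy(n_per = 7)
  sel <- select_ncomp(d$X, d$y, max_components = 3)
  expect_true(sel$n_components >= 1 && sel$n_components <= 3)
  expect_length(sel$q2, 3)
  expect_gt(max(sel$q2), 0.5)
})
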