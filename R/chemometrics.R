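#' Column preprocessing for chemometric models
#'
#' Mean-centers every feature and optionally scales: `"unit_variance"`
#' divides by the per-feature standard deviation (autoscaling, the usual
#' default of chemometric software), `"pareto"` by its square root,
#' `"none"` centers only. The returned parameters transform held-out rows
#' identically via [apply_preprocess()]. Zero-variance features are dropped
#' with a warning under unit-variance scaling.
#'
#' @param X Numeric matrix, samples x features (>= 2 rows).
#' @param mode `"unit_variance"`, `"pareto"` or `"none"`.
#' @return List with `X` (transformed) and `params` (center, scale, kept).
#' @export
preprocess <- function(X, mode = c("unit_variance", "pareto", "none")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (nrow(X) < 2) stopf("preprocess needs >= 2 samples")
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  kept <- rep(TRUE, ncol(X))
  scl <- switch(mode,
                none = rep(1, ncol(X)),
                unit_variance = sds,
                pareto = sqrt(sds))
  if (mode == "unit_variance" && any(sds == 0)) {
    kept <- sds > 0
    warning(sprintf("dropping %d zero-variance feature(s): %s",
                    sum(!kept), paste(colnames(X)[!kept], collapse = ", ")))
  }
  scl[scl == 0] <- 1
  params <- list(center = ctr, scale = scl, kept = kept, mode = mode,
                 features = colnames(X))
  list(X = apply_preprocess(params, X), params = params)
}

#' @rdname preprocess
#' @param params Parameter list returned by [preprocess()].
#' @export
apply_preprocess <- function(params, X) {
  X <- as.matrix(X)
  if (!is.null(params$features) && !is.null(colnames(X))) {
    if (!identical(colnames(X), params$features))
      stopf("feature columns do not match the training features")
  } else if (length(params$center) != ncol(X)) {
    stopf("feature count mismatch: %d vs %d", ncol(X), length(params$center))
  }
  Xc <- sweep(X, 2, params$center, "-")
  Xs <- sweep(Xc, 2, params$scale, "/")
  Xs[, params$kept, drop = FALSE]
}

#' Principal component analysis with Hotelling T2 outlier flags
#'
#' SVD-based PCA of an already-preprocessed matrix, used for quick data
#' quality screening. Samples outside the 95% Hotelling T2 limit (F
#' approximation) are flagged as candidate outliers.
#'
#' @param X Preprocessed (at least centered) samples x features matrix.
#' @param n_components Number of components (<= min(n-1, p)).
#' @return List with `scores`, `loadings` (orthonormal columns),
#'   `explained_variance` (proportions, all components), `t2`, `t2_limit`,
#'   and `outlier` (logical flags).
#' @export
pca <- function(X, n_components = 2L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n_components > min(n - 1, p))
    stopf("n_components %d exceeds min(n-1, p) = %d", n_components, min(n - 1, p))
  sv <- svd(X)
  ev <- sv$d^2 / (n - 1)
  if (sum(ev) <= 0) stopf("degenerate matrix of rank 0")
  a <- n_components
  scores <- sv$u[, seq_len(a), drop = FALSE] %*%
    diag(sv$d[seq_len(a)], nrow = a)
  loadings <- sv$v[, seq_len(a), drop = FALSE]
  lam <- ev[seq_len(a)]
  t2 <- rowSums(sweep(scores^2, 2, lam, "/"))
  t2_limit <- a * (n - 1) / (n - a) * stats::qf(0.95, a, n - a)
  list(scores = scores, loadings = loadings,
       explained_variance = ev / sum(ev),
       t2 = t2, t2_limit = t2_limit, outlier = t2 > t2_limit)
}

# Dummy (one column per class, 1/0) response for PLS-DA; columns in
# alphabetical class order.
class_dummy <- function(y) {
  classes <- sort(unique(as.character(y)))
  Y <- vapply(classes, function(k) as.numeric(y == k), numeric(length(y)))
  colnames(Y) <- classes
  Y
}

#' Fit a PLS-DA model by NIPALS
#'
#' Two-component (by default) partial least squares discriminant analysis.
#' The class vector is dummy-coded (one 1/0 column per class, columns then
#' mean-centered) and a PLS2 model is extracted component by component with
#' the NIPALS alternating iteration: `w = X'u / u'u` (normalized), `t = Xw`,
#' `q = Y't / t't`, `u = Yq / q'q`, iterated to convergence (tolerance 1e-10
#' on the score vector, at most 500 iterations), followed by deflation of
#' `X` by `t p'` (`p = X't / t't`) and of `Y` by `t q'`. The compact
#' regression coefficients are `B = W (P'W)^-1 Q'`.
#'
#' @param X Raw samples x features matrix (preprocessing is handled
#'   internally and its parameters stored in the model).
#' @param y Class labels (>= 2 classes, >= 1 sample each).
#' @param n_components Number of latent variables (default 2).
#' @param scaling Preprocessing mode, see [preprocess()].
#' @return An object of class `plsda_model` with weights `W`, loadings `P`,
#'   Y-loadings `Q`, coefficients `B`, training scores `T`, the class list,
#'   Y column means, and the preprocessing parameters.
#' @export
plsda_fit <- function(X, y, n_components = 2L,
                      scaling = c("unit_variance", "pareto", "none")) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(unique(y)) < 2) stopf("PLS-DA needs >= 2 classes")
  if (nrow(X) != length(y)) stopf("X rows and y length differ")
  pp <- preprocess(X, scaling)
  Xw <- pp$X
  Y0 <- class_dummy(y)
  y_means <- colMeans(Y0)
  Yw <- sweep(Y0, 2, y_means, "-")
  n <- nrow(Xw); p <- ncol(Xw); g <- ncol(Yw)
  a_max <- n_components
  W <- matrix(0, p, a_max); P <- matrix(0, p, a_max)
  Q <- matrix(0, g, a_max); Tm <- matrix(0, n, a_max)
  a_used <- 0L
  for (a in seq_len(a_max)) {
    if (sum(Xw^2) < 1e-12 * max(1, sum(pp$X^2))) {
      warning(sprintf("X deflated to rank %d; truncating to %d component(s)",
                      a - 1L, a - 1L))
      break
    }
    u <- Yw[, which.max(apply(Yw, 2, stats::var))]
    if (sum(u^2) < 1e-24) {
      warning(sprintf("Y residual exhausted after %d component(s); truncating",
                      a - 1L))
      break
    }
    t_old <- rep(Inf, n)
    converged <- FALSE
    for (it in seq_len(500L)) {
      w <- crossprod(Xw, u) / sum(u^2)
      w <- w / sqrt(sum(w^2))
      t_vec <- Xw %*% w
      q <- crossprod(Yw, t_vec) / sum(t_vec^2)
      u <- Yw %*% q / sum(q^2)
      if (sqrt(sum((t_vec - t_old)^2)) < 1e-10 * max(1, sqrt(sum(t_vec^2)))) {
        converged <- TRUE
        break
      }
      t_old <- t_vec
    }
    if (!converged)
      stopf("NIPALS failed to converge for component %d (500 iterations)", a)
    p_vec <- crossprod(Xw, t_vec) / sum(t_vec^2)
    W[, a] <- w; P[, a] <- p_vec; Q[, a] <- q; Tm[, a] <- t_vec
    Xw <- Xw - tcrossprod(t_vec, p_vec)
    Yw <- Yw - tcrossprod(t_vec, q)
    a_used <- a
  }
  if (a_used == 0L) stopf("no PLS component could be extracted")
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  Q <- Q[, seq_len(a_used), drop = FALSE]
  Tm <- Tm[, seq_len(a_used), drop = FALSE]
  B <- W %*% solve(crossprod(P, W)) %*% t(Q)
  structure(list(n_components = a_used, W = W, P = P, Q = Q, B = B,
                 scores = Tm, classes = colnames(Y0), y_means = y_means,
                 preprocess = pp$params),
            class = "plsda_model")
}

#' Predict classes from a fitted PLS-DA model
#'
#' New rows are transformed with the stored preprocessing parameters; class
#' scores are `X B + Y-means` and the predicted class is the column argmax,
#' with a deterministic tie-break to the alphabetically first class (class
#' columns are stored in alphabetical order and `which.max` takes the first
#' maximum).
#'
#' @param model A `plsda_model`.
#' @param X_new Samples x features matrix with the training feature columns.
#' @return List with `class` (character vector) and `scores` (matrix of
#'   per-class predicted dummy scores).
#' @export
plsda_predict <- function(model, X_new) {
  stopifnot(inherits(model, "plsda_model"))
  Xt <- apply_preprocess(model$preprocess, as.matrix(X_new))
  sc <- Xt %*% model$B
  sc <- sweep(sc, 2, model$y_means, "+")
  colnames(sc) <- model$classes
  cls <- model$classes[apply(sc, 1, which.max)]
  list(class = cls, scores = sc)
}

#' Monte-Carlo cross-validation configuration
#'
#' @param n_iterations Number of random resampling iterations (default 500).
#' @param test_fraction Held-out fraction per class (stratified; default 1/3).
#' @param n_components Number of PLS components (default 2).
#' @param scaling Preprocessing mode.
#' @param seed RNG seed.
#' @return An object of class `mccv_config`.
#' @export
mccv_config <- function(n_iterations = 500L, test_fraction = 1 / 3,
                        n_components = 2L,
                        scaling = c("unit_variance", "pareto", "none"),
                        seed = 1L) {
  scaling <- match.arg(scaling)
  if (!(test_fraction > 0 && test_fraction < 1))
    stopf("test_fraction must be in (0, 1)")
  if (n_iterations < 1) stopf("n_iterations must be >= 1")
  structure(list(n_iterations = as.integer(n_iterations),
                 test_fraction = test_fraction,
                 n_components = as.integer(n_components),
                 scaling = scaling, seed = as.integer(seed)),
            class = "mccv_config")
}

#' Monte-Carlo cross-validated PLS-DA
#'
#' Repeats `n_iterations` times: draw a stratified random train/test split,
#' fit the PLS-DA on the training rows (preprocessing estimated on the
#' training rows only), predict the held-out rows, and pool the predictions
#' into one aggregated confusion matrix (rows = truth, columns = predicted).
#' Fully reproducible from the config seed.
#'
#' @param X Samples x features matrix.
#' @param y Class labels; every class needs >= 2 samples so a stratified
#'   split can leave at least one sample per class in training.
#' @param cfg An [mccv_config].
#' @return List with `confusion` (aggregated counts), `accuracies`
#'   (per-iteration), and `config`.
#' @export
mccv <- function(X, y, cfg = mccv_config()) {
  stopifnot(inherits(cfg, "mccv_config"))
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  sizes <- table(y)
  too_small <- names(sizes)[sizes < 2]
  if (length(too_small))
    stopf("class(es) too small to stratify (need >= 2 samples): %s",
          paste(too_small, collapse = ", "))
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(truth = classes, predicted = classes))
  acc <- numeric(cfg$n_iterations)
  with_seed(cfg$seed, {
    for (i in seq_len(cfg$n_iterations)) {
      test_idx <- integer()
      for (k in classes) {
        idx <- which(y == k)
        n_test <- max(1L, min(length(idx) - 1L,
                              round(length(idx) * cfg$test_fraction)))
        test_idx <- c(test_idx, sample(idx, n_test))
      }
      train_idx <- setdiff(seq_along(y), test_idx)
      fit <- plsda_fit(X[train_idx, , drop = FALSE], y[train_idx],
                       cfg$n_components, cfg$scaling)
      pred <- plsda_predict(fit, X[test_idx, , drop = FALSE])$class
      truth <- y[test_idx]
      for (j in seq_along(test_idx))
        cm[truth[j], pred[j]] <- cm[truth[j], pred[j]] + 1L
      acc[i] <- mean(pred == truth)
    }
  })
  list(confusion = cm, accuracies = acc, config = cfg)
}

#' Collapse a confusion matrix over class sets
#'
#' Pools rows and columns into super-classes, e.g. collapsing the 3-class
#' model over the mutation-carrier set `{SDHx, VHL}`.
#'
#' @param cm Square confusion matrix with identical row/column class names.
#' @param groups Named list mapping super-class name to member classes.
#' @return Collapsed confusion matrix.
#' @export
collapse_confusion <- function(cm, groups) {
  k <- length(groups)
  out <- matrix(0L, k, k, dimnames = list(truth = names(groups),
                                          predicted = names(groups)))
  for (a in names(groups)) for (b in names(groups))
    out[a, b] <- sum(cm[rownames(cm) %in% groups[[a]],
                        colnames(cm) %in% groups[[b]], drop = FALSE])
  out
}

#' Classification performance from a confusion matrix
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' accuracy for a positive class (or class set, e.g. the mutation carriers
#' `{SDHx, VHL}`): a prediction counts as positive when the predicted class
#' belongs to the set. Undefined ratios (zero denominator) are reported as
#' `NA`, never as 0.
#'
#' @param cm Confusion matrix, rows = truth, columns = predicted, with class
#'   names on both dimensions.
#' @param positive Character vector of positive class(es).
#' @return An object of class `performance`: proportions `se`, `sp`, `ppv`,
#'   `npv`, `accuracy`, plus the TP/FP/TN/FN counts.
#' @export
performance <- function(cm, positive) {
  cls <- rownames(cm)
  if (!all(positive %in% cls))
    stopf("positive class(es) not in confusion matrix: %s",
          paste(setdiff(positive, cls), collapse = ", "))
  pos_r <- cls %in% positive
  pos_c <- colnames(cm) %in% positive
  tp <- sum(cm[pos_r, pos_c, drop = FALSE])
  fn <- sum(cm[pos_r, !pos_c, drop = FALSE])
  fp <- sum(cm[!pos_r, pos_c, drop = FALSE])
  tn <- sum(cm[!pos_r, !pos_c, drop = FALSE])
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  structure(list(se = ratio(tp, tp + fn), sp = ratio(tn, tn + fp),
                 ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn),
                 accuracy = ratio(tp + tn, tp + tn + fp + fn),
                 tp = tp, fp = fp, tn = tn, fn = fn,
                 positive = positive),
            class = "performance")
}

#' @export
print.performance <- function(x, ...) {
  pc <- function(v) if (is.na(v)) "NA" else sprintf("%d%%", pct_round(v))
  cat(sprintf("Se %s  Sp %s  PPV %s  NPV %s  accuracy %s (positive: %s)\n",
              pc(x$se), pc(x$sp), pc(x$ppv), pc(x$npv), pc(x$accuracy),
              paste(x$positive, collapse = "+")))
  invisible(x)
}

#' Rounded-percent rendering of a performance object
#'
#' Nearest-integer percentages, halves rounded away from zero.
#'
#' @param x A `performance` object.
#' @return Named numeric vector of integer percents (NA where undefined).
#' @export
performance_percent <- function(x) {
  stopifnot(inherits(x, "performance"))
  v <- c(se = x$se, sp = x$sp, ppv = x$ppv, npv = x$npv,
         accuracy = x$accuracy)
  ifelse(is.na(v), NA_real_, pct_round(v))
}

#' Leave-one-out Q2 component selector
#'
#' Optional helper choosing the number of PLS components by leave-one-out
#' predictive residuals on the dummy response within the training set: the
#' smallest component count whose Q2 is within `tol` of the maximum.
#'
#' @param X Samples x features matrix.
#' @param y Class labels.
#' @param max_components Largest count to consider.
#' @param scaling Preprocessing mode.
#' @param tol Tolerance on Q2 when preferring fewer components.
#' @return List with `n_components` and the `q2` profile.
#' @export
select_ncomp <- function(X, y, max_components = 3L,
                         scaling = "unit_variance", tol = 0.01) {
  X <- as.matrix(X); y <- as.character(y)
  n <- nrow(X)
  Y0 <- class_dummy(y)
  press <- rep(0, max_components)
  tss <- sum(sweep(Y0, 2, colMeans(Y0))^2)
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (length(unique(yi)) < 2) next
    a_fit <- min(max_components, length(unique(yi)), ncol(X))
    fit <- suppressWarnings(plsda_fit(X[-i, , drop = FALSE], yi,
                                      a_fit, scaling))
    # predictions with truncated component counts via the deflation route
    Xt <- apply_preprocess(fit$preprocess, X[i, , drop = FALSE])
    x_res <- Xt
    yhat <- matrix(0, 1, length(fit$classes))
    for (a in seq_len(fit$n_components)) {
      t_a <- x_res %*% fit$W[, a]
      x_res <- x_res - t_a %*% t(fit$P[, a])
      yhat <- yhat + t_a %*% t(fit$Q[, a])
      if (a <= max_components) {
        pred <- yhat + matrix(fit$y_means, 1)
        obs <- Y0[i, fit$classes]
        press[a] <- press[a] + sum((obs - pred)^2)
      }
    }
    if (fit$n_components < max_components)
      for (a in seq(fit$n_components + 1L, max_components))
        press[a] <- press[a] + sum((Y0[i, fit$classes] -
                                      (yhat + matrix(fit$y_means, 1)))^2)
  }
  q2 <- 1 - press / tss
  best <- which(q2 >= max(q2) - tol)[1]
  list(n_components = best, q2 = q2)
}
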