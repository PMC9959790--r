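test_that("sd-scaling matches hand calculations and rejects constants", {
  X <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
  expect_equal(unname(scale_matrix(X)[, 1]), c(1, 2, 3))   # sd = 1
  expect_equal(unname(scale_matrix(X, center = TRUE)[, 1]), c(-1, 0, 1))
  Xs <- scale_matrix(matrix(rnorm(50), 10, 5), center = TRUE)
  expect_equal(unname(apply(Xs, 2, sd)), rep(1, 5))
  Xc <- cbind(a = c(1, 2, 3), flat = c(5, 5, 5))
  expect_error(col_scaler(Xc), "constant column\\(s\\): flat")
})

test_that("PCA explained percentages follow the singular values", {
  u <- c(1, 2, 3); v <- c(2, 1)
  m <- pca_sd(u %o% v, scale = FALSE)          # rank 1
  expect_equal(m$explained_pct[1], 100, tolerance = 1e-9)
  m2 <- pca_sd(diag(2), scale = FALSE)
  expect_equal(m2$explained_pct, c(50, 50))
  set.seed(2)
  X <- matrix(rlnorm(60), 12, 5)
  mf <- pca_sd(X)
  expect_equal(sum(mf$explained_pct), 100, tolerance = 1e-6)
  # scores x loadings' reproduces the scaled matrix at full rank
  Xs <- scale_matrix(X)
  expect_equal(max(abs(Xs - mf$scores %*% t(mf$loadings))), 0,
               tolerance = 1e-8)
  expect_equal(crossprod(mf$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pca_sd(X, n_pc = 9), "exceeds")
})

test_that("the first PLS weight vector is the normalised covariance X'y", {
  set.seed(5)
  X <- matrix(rnorm(12), 4, 3)
  y <- c(1, 1, 0, 0)
  fit <- pls_da(X, y, ncomp = 1, center = TRUE)
  Xs <- scale_matrix(X, center = TRUE)
  w <- drop(crossprod(Xs, y - mean(y)))
  expect_equal(drop(fit$W), w / sqrt(sum(w^2)), tolerance = 1e-10)
})

test_that("a perfect single-variable predictor gives RMSEC 0 at one LV", {
  set.seed(6)
  X <- matrix(rnorm(60), 20, 3)
  y <- rep(c(0, 1), 10)
  # noise columns made exactly orthogonal to y in-sample, so the whole
  # covariance X'y sits on column 2
  for (j in c(1, 3)) X[, j] <- stats::residuals(stats::lm(X[, j] ~ y))
  X[, 2] <- y * 3
  fit <- pls_da(X, y, ncomp = 1, center = TRUE, scale = FALSE)
  expect_lt(sqrt(mean((fitted(fit) - y)^2)), 1e-10)
})

test_that("PLS at full rank equals least squares, for fit and prediction", {
  set.seed(7)
  X <- matrix(rnorm(150), 30, 5)
  y <- as.integer(X[, 1] + 0.5 * X[, 3] + rnorm(30, sd = 0.4) > 0)
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  fit <- pls_da(X, y, ncomp = 5)
  Xs <- scale_matrix(X, center = TRUE)
  ols <- stats::lm.fit(cbind(1, Xs), y)
  expect_lt(max(abs(fitted(fit) - ols$fitted.values)), 1e-8)
  Xnew <- matrix(rnorm(25), 5, 5)
  pr <- predict(fit, Xnew)
  Xns <- scale_matrix(Xnew, attr(Xs, "scaler"))
  expect_lt(max(abs(pr - drop(cbind(1, Xns) %*% ols$coefficients))), 1e-8)
  # consistency and duplication
  expect_equal(predict(fit, X), fitted(fit), tolerance = 1e-12)
  expect_equal(predict(fit, X[c(1, 1), ])[1], predict(fit, X[c(1, 1), ])[2])
  expect_error(predict(fit, Xnew[, 1:3]), "variable mismatch")
  expect_error(pls_da(X, rep(1, 30), 2), "both classes")
})

test_that("raw-scale coefficients reproduce the scaled-space predictions", {
  set.seed(17)
  X <- matrix(rnorm(90), 30, 3)
  y <- rep(c(1, 0), 15)
  fit <- pls_da(X, y, ncomp = 2)
  b <- coef(fit, raw = TRUE)
  expect_equal(drop(cbind(1, X) %*% b), unname(fitted(fit)),
               tolerance = 1e-10)
})

test_that("contiguous blocks have near-equal sizes, larger first", {
  b <- contiguous_blocks(300, 7)
  expect_equal(as.vector(table(b)), c(43, 43, 43, 43, 43, 43, 42))
  expect_true(all(diff(b) >= 0))            # contiguous in row order
  expect_equal(as.vector(table(contiguous_blocks(10, 3))), c(4, 3, 3))
})

test_that("cv_pls matches an explicit per-fold refit loop exactly", {
  set.seed(9)
  X <- matrix(rnorm(150), 30, 5)
  y <- as.integer(X[, 2] - X[, 4] + rnorm(30, sd = 0.5) > 0)
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  cv <- cv_pls(X, y, n_blocks = 7, max_lv = 4)
  # independent brute-force loop
  blocks <- rep(1:7, c(5, 5, 4, 4, 4, 4, 4))
  press <- numeric(4)
  for (b in 1:7) {
    hold <- blocks == b
    fit <- pls_da(X[!hold, ], y[!hold], ncomp = 4)
    for (a in 1:4) {
      yh <- predict(fit, X[hold, , drop = FALSE], ncomp = a)
      press[a] <- press[a] + sum((yh - y[hold])^2)
    }
  }
  expect_equal(cv$rmsecv, sqrt(press / 30), tolerance = 1e-12)
  expect_equal(cv$ncomp, which.min(cv$rmsecv))
  # RMSEC is non-increasing in the number of latent variables
  expect_true(all(diff(cv$rmsec) < 1e-10))
  # Q2 is 1 - PRESS/TSS about the training mean
  expect_equal(cv$q2, 1 - press / sum((y - mean(y))^2), tolerance = 1e-12)
})

test_that("a noiseless linear relation is solved by one latent variable", {
  y <- rep(c(0, 1), 10)
  X <- cbind(2 * y + 1, -y + 4, 3 * y)    # every column affine in y
  cv <- cv_pls(X, y, n_blocks = 4, max_lv = 3)
  expect_lt(cv$rmsecv[1], 1e-8)
  expect_equal(cv$ncomp, 1L)
})

test_that("relabelling the classes flips predictions around one", {
  set.seed(10)
  X <- matrix(rnorm(120), 30, 4)
  y <- rep(c(1, 0), 15)
  cv1 <- cv_pls(X, y, n_blocks = 5, max_lv = 3)
  cv2 <- cv_pls(X, 1 - y, n_blocks = 5, max_lv = 3)
  expect_equal(cv1$rmsecv, cv2$rmsecv, tolerance = 1e-10)
  expect_equal(fitted(cv1$model), 1 - fitted(cv2$model), tolerance = 1e-10)
})

test_that("threshold classification calls ties positive", {
  expect_equal(classify(c(0.39, 0.40, 0.41)), c(0L, 1L, 1L))
  expect_equal(classify(runif(10), threshold = 1.1), rep(0L, 10))
  expect_error(classify(c(0.2, NA)), "non-finite")
})

test_that("confusion counts and class metrics match hand bookkeeping", {
  y <- rep(c(1, 0), c(76, 95))
  pred <- y
  pred[1:9] <- 0                       # 9 false negatives among 76 positives
  pred[77:83] <- 1                     # 7 false positives among 95 negatives
  cm <- confusion(y, pred)
  expect_equal(cm$tp, 67); expect_equal(cm$fn, 9)
  expect_equal(cm$fp, 7); expect_equal(cm$tn, 88)
  expect_equal(cm$tp + cm$fn + cm$fp + cm$tn, length(y))
  m <- class_metrics(cm)
  expect_equal(round(100 * m[["sensitivity"]], 1), 88.2)
  expect_equal(round(m[["specificity"]], 3), 0.926)
  expect_equal(m[["fn_rate"]], 1 - m[["sensitivity"]])
  expect_equal(m[["fp_rate"]], 1 - m[["specificity"]])
  cm2 <- confusion(y, y)
  expect_equal(unname(class_metrics(cm2)), c(1, 1, 0, 0))
  expect_error(confusion(y, pred[-1]), "length mismatch")
})

test_that("the ROC curve matches a hand-counted example and spans the range", {
  yhat <- c(.1, .2, .4, .5, .7, .9)
  y <- c(0, 0, 1, 0, 1, 1)
  r <- roc_curve(y, yhat, thresholds = 0.45)
  expect_equal(r$curve$sensitivity, 2 / 3)
  expect_equal(r$curve$specificity, 2 / 3)
  r2 <- roc_curve(y, yhat)
  expect_true(any(r2$curve$sensitivity == 1))
  expect_true(any(r2$curve$sensitivity == 0))
  expect_true(all(diff(r2$curve$sensitivity) <= 1e-12))  # non-increasing
  # perfectly separated estimates reach sens = spec = 1 somewhere
  rp <- roc_curve(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2))
  expect_true(any(rp$curve$sensitivity == 1 & rp$curve$specificity == 1))
  expect_error(roc_curve(c(1, 1), c(0.1, 0.9)), "both classes")
})
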