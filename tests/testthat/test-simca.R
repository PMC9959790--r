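test_that("a full-rank model reconstructs its training set exactly", {
  set.seed(1)
  X <- matrix(rnorm(40), 10, 4)
  m <- simca(X, ncomp = 4)
  expect_lt(max(m$train$residual), 1e-16)
  # duplicated training rows share their (h, Q) pair
  X2 <- rbind(X, X[1, ])
  m2 <- simca(X2, ncomp = 2)
  expect_equal(m2$train[1, ], m2$train[11, ], ignore_attr = TRUE)
  expect_error(simca(X[1:3, ], ncomp = 4), "at least ncomp \\+ 2")
})

test_that("samples near the class centroid are accepted, far outliers rejected", {
  set.seed(2)
  n <- 80; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  X[, 1:2] <- X[, 1:2] * 4                     # two dominant directions
  m <- simca(X, ncomp = 2)
  centre <- matrix(colMeans(X), 1)
  pc <- predict(m, centre)
  expect_true(pc$accepted)
  expect_lt(pc$leverage, m$h_crit / 2)
  # displace a sample far along a discarded (residual) direction
  far <- centre
  far[1, p] <- far[1, p] + 100 * sd(X[, p])
  pf <- predict(m, far)
  expect_false(pf$accepted)
  expect_gt(pf$residual, 10 * m$q_crit)
  # shrinking the displacement toward the centroid eventually accepts
  steps <- seq(1, 0, length.out = 30)
  acc <- vapply(steps, function(f) {
    xi <- centre; xi[1, p] <- xi[1, p] + f * 100 * sd(X[, p])
    predict(m, xi)$accepted
  }, TRUE)
  expect_false(acc[1]); expect_true(acc[length(acc)])
  expect_error(predict(m, centre[, 1:3, drop = FALSE]), "variable mismatch")
})

test_that("in-class acceptance approximates the nominal 95 percent level", {
  set.seed(3)
  p <- 10
  L <- matrix(rnorm(p * p, sd = 0.3), p) + diag(p)
  Xtr <- matrix(rnorm(400 * p), 400, p) %*% L
  m <- simca(Xtr, ncomp = 3, alpha = 0.05)
  Xnew <- matrix(rnorm(2000 * p), 2000, p) %*% L
  cov <- mean(predict(m, Xnew)$accepted)
  expect_gt(cov, 0.92); expect_lt(cov, 0.98)
})

test_that("variable leverages are orthonormality-consistent", {
  set.seed(4)
  X <- matrix(rnorm(200), 40, 5)
  for (k in c(1, 3)) {
    m <- simca(X, ncomp = k)
    lev <- simca_variable_leverage(m)
    expect_equal(sum(lev), k, tolerance = 1e-10)
    expect_true(all(lev >= 0 & lev <= 1))
  }
  # a variable uncorrelated with the single dominant direction gets a
  # near-zero leverage on one component
  t1 <- rnorm(60)
  Xs <- cbind(t1 * 2, t1 * 2 + rnorm(60, sd = 0.05), rnorm(60, sd = 1))
  m1 <- simca(Xs, ncomp = 1, scale = FALSE)
  lev1 <- simca_variable_leverage(m1)
  expect_lt(lev1[3], 0.05)
  expect_gt(lev1[1] + lev1[2], 0.95)
})

test_that("element-wise PRESS recovers a planted low-rank structure", {
  set.seed(5)
  B <- matrix(rnorm(60 * 2), 60) %*% matrix(rnorm(2 * 7), 2)
  X <- B + matrix(rnorm(60 * 7, sd = 0.05), 60)
  pc <- simca_cv_press(X, max_pc = 5)
  expect_equal(pc$ncomp, 2)
  # near-rank-1 data: one component leaves almost no predictive error
  u <- rnorm(40)
  X1 <- u %o% c(1, 2, 3) + matrix(rnorm(120, sd = 1e-3), 40)
  p1 <- simca_cv_press(X1, max_pc = 2, center = FALSE)
  expect_equal(p1$ncomp, 1)
  expect_lt(p1$press[1] / nrow(X1), 1e-2)
})

test_that("PRESS equals an explicit per-fold refit loop on a small toy", {
  set.seed(6)
  X <- matrix(rnorm(80), 20, 4)
  pc <- simca_cv_press(X, max_pc = 3, n_blocks = 5)
  blocks <- rep(1:5, each = 4)
  press <- numeric(3)
  for (b in 1:5) {
    hold <- blocks == b
    xtr <- X[!hold, ]
    mu <- colMeans(xtr); sds <- apply(xtr, 2, sd)
    Xs <- sweep(sweep(xtr, 2, mu), 2, sds, `/`)
    V <- svd(Xs)$v
    Xh <- sweep(sweep(X[hold, , drop = FALSE], 2, mu), 2, sds, `/`)
    for (k in 1:3) {
      P <- V[, 1:k, drop = FALSE]
      for (j in 1:4) {
        Pj <- P[-j, , drop = FALSE]
        tj <- Xh[, -j, drop = FALSE] %*% Pj %*%
          solve(crossprod(Pj) + diag(1e-12, k))
        press[k] <- press[k] + sum((Xh[, j] - tj %*% P[j, ])^2)
      }
    }
  }
  expect_equal(pc$press, press, tolerance = 1e-9)
})

test_that("the geometric-mean criterion is reported with an out-class set", {
  set.seed(7)
  Xin <- matrix(rnorm(200), 50, 4)
  Xout <- matrix(rnorm(120, mean = 4), 30, 4)
  pc <- simca_cv_press(Xin, max_pc = 3, x_out = Xout)
  expect_length(pc$gmean, 3)
  expect_true(pc$ncomp_gmean %in% 1:3)
  expect_true(all(pc$gmean >= 0 & pc$gmean <= 1))
})
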