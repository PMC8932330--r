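test_that("SMO dual solution matches an independent QP reference", {
  set.seed(42)
  X <- rbind(matrix(rnorm(20, -2), 10, 2), matrix(rnorm(20, 2), 10, 2))
  y <- rep(c(-1, 1), each = 10)
  C <- 10; sig <- 2
  m <- train_binary_svm(X, y, C = C, sigma = sig, tol = 1e-8)
  expect_equal(mean(sign(svm_decision(m, X)) == y), 1)
  # reference: interior-point QP on the same dual
  K <- exp(-as.matrix(dist(X))^2 / sig^2)
  H <- (y %*% t(y)) * K
  sol <- kernlab::ipop(c = rep(-1, 20), H = H, A = matrix(y, 1), b = 0,
                       l = rep(0, 20), u = rep(C, 20), r = 0, sigf = 10)
  al <- kernlab::primal(sol)
  free <- which(al > 1e-6 & al < C - 1e-6)
  b_ref <- mean(y[free] - (K %*% (al * y))[free])
  dec_ref <- as.numeric(K %*% (al * y) + b_ref)
  expect_lt(max(abs(dec_ref - svm_decision(m, X))), 1e-4)
})

test_that("binary SVM solves the XOR pattern and tolerates label conflicts", {
  Xx <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  yx <- c(-1, -1, 1, 1)
  mx <- train_binary_svm(Xx, yx, C = 100, sigma = 0.7)
  expect_equal(sign(svm_decision(mx, Xx)), yx)
  # duplicated point with conflicting labels: soft margin must still converge
  Xc <- rbind(Xx, c(0, 0))
  yc <- c(yx, 1)
  mc <- train_binary_svm(Xc, yc, C = 1, sigma = 0.7)
  expect_true(all(is.finite(svm_decision(mc, Xc))))
})

test_that("every trained sub-model satisfies dual feasibility", {
  blobs <- feature_blobs(15, sep = 2.5, seed = 5)
  fit <- train_ovo_svm(blobs$X, blobs$y, C = 10, sigma = 3)
  expect_length(fit$models, 3)
  for (m in fit$models) {
    expect_true(all(m$alpha >= -1e-9))
    expect_true(all(m$alpha <= m$C + 1e-9))
    expect_lt(abs(sum(m$alpha * m$y)), 1e-6)
  }
})

test_that("a missing class aborts training with a named error", {
  blobs <- feature_blobs(10, seed = 6)
  keep <- blobs$y != 0
  expect_error(train_ovo_svm(blobs$X[keep, ], blobs$y[keep]), regexp = "0",
               class = "fatiguefuse_invalid_parameter")
})

test_that("deep-interior points are classified as their class by all voters", {
  blobs <- feature_blobs(15, sep = 4, seed = 7)
  fit <- train_ovo_svm(blobs$X, blobs$y, C = 10, sigma = 5)
  pred <- predict(fit, blobs$X)
  expect_gt(mean(pred == blobs$y), 0.95)
  # the class-1 centroid must win every sub-model involving class 1
  ctr <- matrix(colMeans(blobs$X[blobs$y == 1, ]), 1)
  for (m in fit$models) {
    if (!1 %in% m$pair) next
    dec <- svm_decision(m, ctr)
    expect_true((max(m$pair) == 1 && dec > 0) || (min(m$pair) == 1 && dec < 0))
  }
  expect_equal(predict(fit, ctr), 1)
})

test_that("prediction is invariant to support-vector ordering", {
  blobs <- feature_blobs(10, sep = 2, seed = 8)
  fit <- train_ovo_svm(blobs$X, blobs$y, C = 5, sigma = 3)
  fit2 <- fit
  for (i in seq_along(fit2$models)) {
    perm <- rev(seq_len(nrow(fit2$models[[i]]$sv)))
    fit2$models[[i]]$sv <- fit2$models[[i]]$sv[perm, , drop = FALSE]
    fit2$models[[i]]$coef <- fit2$models[[i]]$coef[perm]
  }
  probe <- matrix(rnorm(55), 5, 11)
  expect_equal(predict(fit2, probe), predict(fit, probe))
})

test_that("identity fusion reproduces the plain SVM prediction-for-prediction", {
  blobs <- feature_blobs(12, sep = 2, seed = 9)
  scaler <- fatiguefuse:::fit_scaler(blobs$X)
  Xs <- fatiguefuse:::apply_scaler(blobs$X, scaler)
  expect_identical(fuse(Xs, rep(1, 11)), Xs)
  plain <- train_ovo_svm(Xs, blobs$y, C = 10, sigma = sqrt(11))
  fused <- train_ovo_svm(fuse(Xs, rep(1, 11)), blobs$y, C = 10, sigma = sqrt(11))
  probe <- matrix(rnorm(110), 10, 11)
  expect_identical(predict(fused, probe), predict(plain, probe))
  # zero weight annihilates its feature
  expect_true(all(fuse(Xs, c(0, rep(1, 10)))[, 1] == 0))
  set.seed(1)
  d <- runif(11); F <- matrix(rnorm(33), 3, 11)
  expect_equal(fuse(F, d), F * rep(d, each = 3), tolerance = 1e-15)
  expect_error(fuse(F, d[1:5]), class = "fatiguefuse_invalid_parameter")
})
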