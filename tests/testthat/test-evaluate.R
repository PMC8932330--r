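# classifier that applies a fixed labeling rule without learning, so the
# true labels are recoverable on any split
rule_clf <- function(rule) {
  list(name = "rule", fit = function(X, y, split_seed = NULL) NULL,
       predict = function(model, X) rule(X))
}

test_that("recognition rate counts correct identifications", {
  expect_equal(recognition_rate(c(1, 0, -1, 1), c(1, 0, -1, 0)), 0.75)
  expect_equal(recognition_rate(c(1, 1), c(1, 1)), 1.0)
  expect_error(recognition_rate(numeric(0), numeric(0)),
               class = "fatiguefuse_invalid_parameter")
  expect_error(recognition_rate(1, c(1, 0)), class = "fatiguefuse_invalid_parameter")
})

test_that("per-class rates agree with the confusion matrix", {
  pred <- c(-1, -1, 0, 1, 1, 0)
  truth <- c(-1, 0, 0, 1, -1, 1)
  cr <- fatiguefuse:::class_rates(pred, truth)
  expect_equal(sum(cr$confusion), 6)
  expect_equal(as.numeric(diag(cr$confusion) / rowSums(cr$confusion)),
               cr$per_class)
  expect_equal(mean(pred == truth), sum(diag(cr$confusion)) / sum(cr$confusion))
})

test_that("MCCV with an oracle rule scores perfectly and reproducibly", {
  blobs <- feature_blobs(10, sep = 50, sd = 0.1, seed = 20)
  oracle <- rule_clf(function(X) c(-1, 0, 1)[cut(X[, 1], c(-Inf, -25, 25, Inf))])
  rep1 <- mccv(blobs$X, blobs$y, oracle, n_rep = 5, seed = 4)
  expect_equal(rep1$mean_rate, 1.0)
  expect_equal(unname(rep1$per_class_rate), c(1, 1, 1))
  rep2 <- mccv(blobs$X, blobs$y, oracle, n_rep = 5, seed = 4)
  expect_identical(rep1$rep_rates, rep2$rep_rates)
  expect_identical(rep1$confusion, rep2$confusion)
})

test_that("a constant classifier on balanced data scores exactly chance", {
  blobs <- feature_blobs(10, seed = 21)
  const <- rule_clf(function(X) rep(0, nrow(X)))
  rep <- mccv(blobs$X, blobs$y, const, n_rep = 4, test_fraction = 0.3, seed = 5)
  expect_equal(rep$mean_rate, 1 / 3, tolerance = 1e-12)
  expect_equal(unname(rep$per_class_rate), c(0, 1, 0))
})

test_that("confusion totals equal the number of test predictions", {
  blobs <- feature_blobs(10, seed = 22)
  rep <- mccv(blobs$X, blobs$y, clf_knn(k = 3), n_rep = 6,
              test_fraction = 0.3, seed = 6)
  expect_equal(sum(rep$confusion), 6 * 3 * 3)  # 3 test samples per class
  expect_true(all(rep$rep_rates >= 0 & rep$rep_rates <= 1))
  expect_equal(rep$mean_rate, mean(rep$rep_rates))
})

test_that("degenerate splits are rejected", {
  blobs <- feature_blobs(4, seed = 23)
  # a class with a single sample cannot be split on both sides
  expect_error(mccv(blobs$X[c(1:4, 5:8, 9), ], blobs$y[c(1:4, 5:8, 9)],
                    clf_knn(), n_rep = 2, test_fraction = 0.5, seed = 1),
               class = "fatiguefuse_invalid_parameter")
})

test_that("KNN with k = 1 memorizes its training set", {
  blobs <- feature_blobs(8, seed = 24)
  f <- clf_knn(k = 1)
  m <- f$fit(blobs$X, blobs$y)
  expect_equal(recognition_rate(f$predict(m, blobs$X), blobs$y), 1.0)
})

test_that("LDA separates well-separated Gaussian blobs", {
  blobs <- feature_blobs(20, sep = 4, seed = 25)
  rep <- mccv(blobs$X, blobs$y, clf_lda(), n_rep = 20, seed = 7)
  expect_gte(rep$mean_rate, 0.95)
})

test_that("all baselines run through the identical MCCV interface", {
  blobs <- feature_blobs(12, sep = 3, seed = 26)
  for (f in list(clf_bpnn(size = 4, maxit = 100), clf_knn(), clf_lda(),
                 clf_svm())) {
    rep <- mccv(blobs$X, blobs$y, f, n_rep = 3, seed = 8)
    expect_s3_class(rep, "evaluation_report")
    expect_true(rep$mean_rate >= 0 && rep$mean_rate <= 1)
    expect_gt(rep$mean_rate, 0.5)  # blobs are easy; every baseline beats chance
  }
})

test_that("modality comparison emits the 3 x 4 rate table on shared splits", {
  blobs <- feature_blobs(12, sep = 3, seed = 27)
  cmp <- compare_modalities(blobs$X, blobs$y,
                            fused_classifier = clf_svm(),
                            single_classifier_fn = function(cols)
                              clf_svm(columns = cols),
                            n_rep = 4, seed = 9)
  expect_equal(nrow(cmp$table), 3)
  expect_identical(cmp$table$modality, c("ecg", "semg", "fused"))
  expect_identical(names(cmp$table), c("modality", "relaxed", "transition",
                                       "tired", "mean"))
  expect_true(all(unlist(cmp$table[, -1]) >= 0 & unlist(cmp$table[, -1]) <= 1))
  # paired protocol: all three reports share split seeds and test counts
  expect_identical(sum(cmp$reports$ecg$confusion), sum(cmp$reports$fused$confusion))
})
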