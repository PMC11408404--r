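test_that("ANOVA-F filter scores match the independent one-way ANOVA oracle", {
  set.seed(12)
  x <- cbind(a = rnorm(60), b = rnorm(60), c = rnorm(60))
  y <- rep(c(0, 1), each = 30)
  x[, "b"] <- x[, "b"] + y          # one separating feature
  f <- filter_scores(x, y)
  for (j in 1:3) {
    oracle <- stats::oneway.test(x[, j] ~ factor(y), var.equal = TRUE)$statistic
    expect_equal(unname(f[j]), unname(oracle), tolerance = 1e-10)
  }
  expect_gt(f["b"], max(f[c("a", "c")]))

  const <- cbind(k = rep(2, 60), x)
  expect_identical(unname(filter_scores(const, y)["k"]), 0)

  jittered <- cbind(lab = y + rnorm(60, 0, 1e-3), x)
  expect_identical(which.max(filter_scores(jittered, y)), c(lab = 1L))
})

test_that("top-k selection is deterministic with lower-index tie-breaks", {
  s <- c(0.1, 5, 3)
  expect_identical(select_top_k(s, 2), c(2L, 3L))
  expect_identical(select_top_k(c(1, 1, 1), 2), c(1L, 2L))
  expect_identical(select_top_k(s, 3), c(2L, 3L, 1L))
  expect_error(select_top_k(s, 0), "k")
  expect_error(select_top_k(s, 4), "k")
})

test_that("all five classifiers separate the Gaussian-blob fixture", {
  blobs <- make_blobs(n = 200)
  sp <- split_dataset(seq_along(blobs$y), blobs$y, seed = 3)
  for (alg in c("knn", "svm", "dt", "nb", "etc")) {
    m <- spindle_classifier(blobs$x[sp$train_idx, ], blobs$y[sp$train_idx],
                            algorithm = alg, seed = 5)
    pred <- predict(m, blobs$x[sp$test_idx, ])
    acc <- mean(pred == blobs$y[sp$test_idx])
    expect_gt(acc, 0.95)
    sc <- predict(m, blobs$x[sp$test_idx, ], type = "score")
    expect_true(all(sc >= 0 & sc <= 1))
  }
  # KNN on the fully separable blobs reaches test accuracy 1.0
  m <- spindle_classifier(blobs$x[sp$train_idx, ], blobs$y[sp$train_idx],
                          algorithm = "knn", seed = 5)
  expect_equal(mean(predict(m, blobs$x[sp$test_idx, ]) ==
                      blobs$y[sp$test_idx]), 1.0)
})

test_that("KNN honours its neighborhood contract and agrees with an independent KNN", {
  blobs <- make_blobs(n = 100, seed = 77)
  m1 <- spindle_classifier(blobs$x, blobs$y, algorithm = "knn",
                           hyperparameters = list(k = 1))
  expect_identical(as.numeric(predict(m1, blobs$x)), as.numeric(blobs$y))

  m5 <- spindle_classifier(blobs$x, blobs$y, algorithm = "knn")
  z <- scale(blobs$x)
  oracle <- as.integer(as.character(
    class::knn(z, z, factor(blobs$y), k = 5)))
  expect_equal(as.numeric(predict(m5, blobs$x)), as.numeric(oracle))
})

test_that("naive Bayes recovers the generating class means", {
  set.seed(31)
  n <- 2000
  mu <- c(0, 2.5)
  x <- matrix(c(rnorm(n / 2, mu[1]), rnorm(n / 2, mu[2])), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- rep(c(0, 1), each = n / 2)
  m <- spindle_classifier(x, y, algorithm = "nb")
  # de-standardize the fitted per-class means
  fitted_means <- m$fit$tables$f[, 1] * m$scale + m$center
  se <- 1 / sqrt(n / 2)
  expect_lt(abs(fitted_means[1] - mu[1]), 3 * se)
  expect_lt(abs(fitted_means[2] - mu[2]), 3 * se)
})

test_that("training is deterministic and leak-free; errors are informative", {
  blobs <- make_blobs(n = 100, seed = 13)
  for (alg in c("dt", "etc")) {
    a <- spindle_classifier(blobs$x, blobs$y, algorithm = alg, seed = 9)
    b <- spindle_classifier(blobs$x, blobs$y, algorithm = alg, seed = 9)
    expect_identical(predict(a, blobs$x, type = "score"),
                     predict(b, blobs$x, type = "score"))
  }
  m <- spindle_classifier(blobs$x, blobs$y, algorithm = "svm")
  expect_equal(unname(m$center), unname(colMeans(blobs$x)))
  expect_equal(unname(m$scale), unname(apply(blobs$x, 2, sd)))

  expect_error(spindle_classifier(blobs$x, blobs$y, algorithm = "mlp"),
               "knn, svm, dt, nb, etc")
  expect_error(spindle_classifier(blobs$x, rep(1, length(blobs$y)),
                                  algorithm = "knn"), "class")
  bad <- blobs$x; colnames(bad) <- c("f1", "zz")
  expect_error(predict(m, bad), "f2")
})
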