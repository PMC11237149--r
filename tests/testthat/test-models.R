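test_that("PCA matches an independent eigendecomposition and reconstructs the data", {
  set.seed(10)
  X <- matrix(rnorm(10 * 50), 10, 50)
  m <- pca_fit(X)
  # explained variance against brute-force eigenvalues of the covariance
  ev <- eigen(cov(X), symmetric = TRUE)$values
  ev <- ev[ev > 1e-12]
  expect_equal(m$explained_pct, 100 * ev / sum(ev), tolerance = 1e-8)
  # orthonormal loadings
  expect_equal(crossprod(m$loadings), diag(ncol(m$loadings)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # scores = centred data x loadings, and full-rank reconstruction
  Xc <- sweep(X, 2, colMeans(X), "-")
  expect_equal(m$scores, Xc %*% m$loadings, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(m$scores %*% t(m$loadings), Xc, tolerance = 1e-8,
               ignore_attr = TRUE)
  # sign convention: largest-|value| loading entry positive
  for (j in seq_len(ncol(m$loadings))) {
    expect_gt(m$loadings[which.max(abs(m$loadings[, j])), j], 0)
  }
  # agreement with prcomp
  pr <- prcomp(X)
  expect_equal(m$explained_pct,
               (100 * pr$sdev^2 / sum(pr$sdev^2))[seq_along(m$explained_pct)],
               tolerance = 1e-9)
})

test_that("PCA handles rank-1 and degenerate inputs", {
  v <- sin(seq_len(40))
  X1 <- outer(c(1, 2, 3, 5), v) + 2
  m1 <- pca_fit(X1)
  expect_equal(m1$explained_pct[1], 100, tolerance = 1e-9)
  expect_error(pca_fit(matrix(3, 5, 10)), "zero variance")
  expect_error(pca_fit(matrix(1, 1, 10)), "at least 2")
})

test_that("component selection takes the smallest k reaching the threshold", {
  stub <- function(expl) structure(list(explained_pct = expl),
                                   class = "pca_model")
  expect_equal(select_components(stub(c(93, 5, 1, 1)), 99), 3L)
  expect_equal(select_components(stub(100), 99), 1L)
  expect_equal(select_components(stub(c(60, 40)), 100), 2L)
  expect_equal(select_components(stub(c(99.5, 0.5)), 99), 1L)
  expect_error(select_components(stub(100), 0), "threshold")
})

test_that("Hotelling T2 equals the Mahalanobis distance in score space", {
  set.seed(11)
  X <- matrix(rnorm(20 * 8), 20, 8)
  # a row equal to the mean of the others is the overall column mean,
  # so its T2 must be 0
  X[20, ] <- colSums(X[1:19, ]) / 19
  m <- pca_fit(X)
  k <- 4
  ht <- hotelling_t2(m, k, alpha = 0.05)
  sc <- m$scores[, 1:k]
  oracle <- mahalanobis(sc, center = rep(0, k), cov = diag(apply(sc, 2, var)))
  expect_equal(ht$t2, oracle, tolerance = 1e-9)
  expect_lt(ht$t2[20], 1e-16)
  expect_equal(ht$limit,
               k * (20 - 1) / (20 - k) * qf(0.95, k, 20 - k))
  # alpha -> 1: limit -> 0, everything non-central flagged
  ht1 <- hotelling_t2(m, k, alpha = 1 - 1e-12)
  expect_lt(ht1$limit, 1e-3)
  expect_true(all(ht1$flagged[-20]))
  expect_error(hotelling_t2(m, 25), "n > k")
})

test_that("LDA separates well-separated classes and collapses to priors under the null", {
  set.seed(20)
  x <- matrix(c(rnorm(20, -5), rnorm(20, 5)), ncol = 1)
  y <- rep(c("a", "b"), each = 20)
  correct <- vapply(seq_along(y), function(i) {
    m <- lda_fit(x[-i, , drop = FALSE], y[-i])
    lda_predict(m, x[i, , drop = FALSE]) == y[i]
  }, logical(1))
  expect_true(all(correct))  # 10-sd separation: LOO is perfect

  # identical distributions: accuracy tracks the majority fraction
  set.seed(21)
  acc <- replicate(50, {
    xn <- matrix(rnorm(40), ncol = 1)
    yn <- rep(c("a", "b"), times = c(30, 10))
    m <- lda_fit(xn, yn)
    mean(lda_predict(m, xn) == yn)
  })
  # resubstitution accuracy of a null model with empirical priors stays
  # inside the exact binomial 99% band around the 75% majority rate
  total_correct <- sum(acc * 40)
  expect_gte(total_correct, qbinom(0.005, 50 * 40, 0.75))
  expect_lte(total_correct, qbinom(0.995, 50 * 40, 0.75))
})

test_that("LDA tie-breaks to the first class in sorted order and matches MASS", {
  skip_if_not_installed("MASS")
  x <- matrix(c(-2, -1, 1, 2), ncol = 1)
  y <- c("b_class", "b_class", "a_class", "a_class")
  m <- lda_fit(x, y)
  # 0 is exactly equidistant with equal priors: sorted-first class wins
  expect_equal(lda_predict(m, matrix(0)), "a_class")

  set.seed(22)
  X <- rbind(matrix(rnorm(80, 0), 40), matrix(rnorm(80, 1.2), 40))
  y2 <- rep(c("a", "b"), each = 40)
  Xt <- matrix(rnorm(60, 0.6), 30)
  expect_equal(lda_predict(lda_fit(X, y2), Xt),
               as.character(predict(MASS::lda(X, y2), Xt)$class))
  expect_equal(qda_predict(qda_fit(X, y2), Xt),
               as.character(predict(MASS::qda(X, y2), Xt)$class))
})

test_that("QDA uses per-class covariances where LDA cannot", {
  # exactly equal class covariances (class b is a shifted copy of class
  # a): QDA and LDA agree on every test point
  set.seed(23)
  Xa <- matrix(rnorm(100), 50)
  X <- rbind(Xa, sweep(Xa, 2, c(2, -1), "+"))
  y <- rep(c("a", "b"), each = 50)
  Xt <- matrix(rnorm(200, 0.5), 100)
  expect_equal(qda_predict(qda_fit(X, y), Xt),
               lda_predict(lda_fit(X, y), Xt))

  # 1-D N(0,1) vs N(0,100): a point at 50 belongs to the wide class
  set.seed(24)
  xs <- matrix(c(rnorm(50, 0, 1), rnorm(50, 0, 10)), ncol = 1)
  ys <- rep(c("narrow", "wide"), each = 50)
  qm <- qda_fit(xs, ys, priors = "uniform")
  expect_equal(qda_predict(qm, matrix(50)), "wide")
  # at a class mean, the smaller-determinant class wins at equal priors
  expect_equal(qda_predict(qm, matrix(0)), "narrow")

  # error names the offending class
  expect_error(check_err <- qda_fit(matrix(c(1, 1, 2, 3), ncol = 1),
                                    c("a", "a", "b", "b")),
               NA)  # constant class is rescued by the ridge
})

test_that("discriminant predictions are invariant under affine rescaling of scores", {
  set.seed(25)
  X <- rbind(matrix(rnorm(90, -1), 30), matrix(rnorm(90, 1), 30))
  y <- rep(c("a", "b"), each = 30)
  Xt <- matrix(rnorm(45), 15)
  A <- matrix(c(2, 0.5, -0.3, 1.5, 0.2, 0, 0.1, -0.4, 3), 3, 3)
  shift <- c(5, -2, 1)
  tr <- function(M) sweep(M %*% A, 2, shift, "+")
  expect_equal(lda_predict(lda_fit(tr(X), y), tr(Xt)),
               lda_predict(lda_fit(X, y), Xt))
  expect_equal(qda_predict(qda_fit(tr(X), y), tr(Xt)),
               qda_predict(qda_fit(X, y), Xt))
})

test_that("SVM recovers the analytic maximum-margin separator", {
  X <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  y <- c("A", "A", "B", "B")
  m <- svm_fit(X, y, kernel = "linear", C = 100, scale = FALSE)
  expect_equal(svm_predict(m, X), y)
  mach <- m$machines[[1]]
  w <- colSums(mach$coef * mach$X)
  # maximum-margin separator: x1 = 0, geometric margin 1 => |w| = 1
  expect_equal(unname(w), c(-1, 0), tolerance = 1e-3)
  expect_equal(mach$b, 0, tolerance = 1e-3)
  # margin points score exactly +-1
  f <- c(tcrossprod(X, t(w)) + mach$b)
  expect_equal(abs(f), rep(1, 4), tolerance = 1e-3)
})

test_that("SVM solves XOR with the RBF kernel and reports calibration stats", {
  X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c("healthy", "healthy", "IBD", "IBD")
  m <- svm_fit(X, y, kernel = "rbf", C = 100, gamma = 1, scale = FALSE)
  expect_equal(svm_predict(m, X), y)
  st <- svm_regression_stats(m, X, y)
  expect_equal(st$r2, 100)
  expect_equal(st$rmsec, 0)
})

test_that("SVM one-vs-one multiclass is deterministic and agrees with e1071 on separated data", {
  skip_if_not_installed("e1071")
  set.seed(26)
  X <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 6), 20),
             matrix(rnorm(40, -6), 20))
  y <- rep(c("healthy", "UC", "CD"), each = 20)
  m1 <- svm_fit(X, y, "linear", C = 1, scale = FALSE)
  m2 <- svm_fit(X, y, "linear", C = 1, scale = FALSE)
  Xt <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 6), 10),
              matrix(rnorm(20, -6), 10))
  expect_identical(svm_predict(m1, Xt), svm_predict(m2, Xt))
  ref <- e1071::svm(X, factor(y), kernel = "linear", cost = 1, scale = FALSE)
  expect_equal(svm_predict(m1, Xt), as.character(predict(ref, Xt)))
  expect_error(svm_fit(X, y, C = -1), "C must be")
})

test_that("class codes follow the diagnostic conventions", {
  expect_mapequal(class_codes(c("IBD", "healthy")), c(healthy = 0, IBD = 1))
  expect_mapequal(class_codes(c("UC", "CD", "healthy")),
                  c(CD = 2, healthy = 0, UC = 1))
  expect_equal(unname(class_codes(c("x", "y"))), c(0, 1))
})

test_that("models serialize to JSON", {
  set.seed(27)
  X <- rbind(matrix(rnorm(20, -2), 10), matrix(rnorm(20, 2), 10))
  y <- rep(c("a", "b"), each = 10)
  p <- withr::local_tempfile(fileext = ".json")
  write_model_json(lda_fit(X, y), p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$type, "lda_model")
  expect_equal(unlist(back$means[[1]]), colMeans(X[1:10, , drop = FALSE]),
               tolerance = 1e-9, ignore_attr = TRUE)
  write_model_json(pca_fit(X), p)
  expect_equal(jsonlite::read_json(p)$type, "pca_model")
})
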