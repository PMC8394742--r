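# One-class scorers: exact oracles, closed forms, orientation and
# determinism.

test_that("OC-KNN score equals the brute-force k-th smallest distance", {
  set.seed(2)
  train <- matrix(rnorm(200 * 10), 200, 10)
  query <- matrix(rnorm(30 * 10), 30, 10)
  mink <- function(a, b, p) sum(abs(a - b)^p)^(1 / p)
  brute <- function(metric, k) {
    apply(query, 1, function(q) {
      d <- apply(train, 1, function(t) switch(metric,
        euclidean = sqrt(sum((q - t)^2)),
        minkowski = mink(q, t, 3),
        chebychev = max(abs(q - t)),
        cosine = 1 - sum(q * t) / (sqrt(sum(q^2)) * sqrt(sum(t^2)))))
      sort(d)[k]
    })
  }
  for (metric in c("euclidean", "minkowski", "chebychev", "cosine")) {
    for (k in c(1L, 5L, 50L)) {
      m <- train_ocknn(train, metric, k)
      expect_equal(occ_score(m, query), brute(metric, k), tolerance = 1e-10,
                   label = paste(metric, k))
    }
  }
})

test_that("OC-KNN handles the 1-D textbook cases", {
  train <- matrix(c(0, 1, 2), ncol = 1)
  expect_equal(occ_score(train_ocknn(train, "euclidean", 1), matrix(5)), 3)
  expect_equal(occ_score(train_ocknn(train, "euclidean", 3), matrix(5)), 5)
  expect_equal(occ_score(train_ocknn(train, "euclidean", 1), matrix(1)), 0)
  expect_error(train_ocknn(train, "euclidean", 4), "k must lie")
})

test_that("1-component GMM matches the closed-form Gaussian NLL", {
  x <- matrix(c(-1, 1), ncol = 1)
  m <- train_gmm(x, components = 1L, seed = 1)
  expect_equal(m$fit$mean[1, 1], 0, tolerance = 1e-9)
  expect_equal(m$fit$variance[1, 1], 1, tolerance = 1e-9)  # biased MLE
  expect_equal(occ_score(m, matrix(0)), 0.5 * log(2 * pi), tolerance = 1e-6)

  # multivariate spot check against the closed-form diagonal Gaussian
  set.seed(6)
  y <- matrix(rnorm(400), 100, 4)
  m2 <- train_gmm(y, components = 1L, seed = 1)
  mu <- colMeans(y); v <- colMeans(sweep(y, 2, mu)^2)
  q <- matrix(rnorm(8), 2, 4)
  nll <- vapply(1:2, function(i)
    0.5 * sum(log(2 * pi * v)) + 0.5 * sum((q[i, ] - mu)^2 / v), 0)
  expect_equal(occ_score(m2, q), nll, tolerance = 1e-6)
})

test_that("GMM EM log-likelihood is non-decreasing per iteration", {
  set.seed(10)
  x <- rbind(matrix(rnorm(150), 50, 3),
             matrix(rnorm(150, mean = 4), 50, 3))
  for (k in c(2L, 3L)) {
    m <- train_gmm(x, components = k, seed = 7)
    tr <- m$fit$loglik_trace
    expect_gt(length(tr), 1L)
    expect_true(all(diff(tr) > -1e-8))
  }
})

test_that("GMM scores are translation-consistent and seed-deterministic", {
  set.seed(12)
  x <- matrix(rnorm(300), 100, 3)
  q <- matrix(rnorm(15), 5, 3)
  s1 <- occ_score(train_gmm(x, 3, seed = 2), q)
  s2 <- occ_score(train_gmm(x + 5, 3, seed = 2), q + 5)
  expect_equal(s1, s2, tolerance = 1e-4)
  s3 <- occ_score(train_gmm(x, 3, seed = 2), q)
  expect_identical(s1, s3)
})

test_that("Parzen scorer evaluates its window function exactly at zero distance", {
  m <- train_ppnn(matrix(c(0, 0, 0), 1, 3), bandwidth = 1)
  # likelihood = f(0) = e^-1; anomaly score is the negated likelihood
  expect_equal(-occ_score(m, matrix(0, 1, 3)), exp(-1), tolerance = 1e-12)

  # likelihood decays monotonically with distance from the lone prototype
  d <- seq(0, 5, by = 0.5)
  lik <- -occ_score(m, cbind(d, 0, 0))
  expect_true(all(diff(lik) < 0))
  expect_error(train_ppnn(matrix(0, 1, 3), bandwidth = 0), "positive")
})

test_that("likelihood-type scorers rank a far outlier above training data", {
  x <- gaussian_cloud(n = 80, p = 5, seed = 33)
  out <- matrix(10, 1, 5)
  for (kind in c("ppnn", "ocsvm")) {
    m <- switch(kind, ppnn = train_ppnn(x), ocsvm = train_ocsvm(x))
    expect_gt(occ_score(m, out), median(occ_score(m, x)), label = kind)
  }
})

test_that("autoencoder reconstructs inliers and flags a 10-sd outlier", {
  x <- gaussian_cloud(n = 60, p = 6, seed = 44)
  m <- train_autoencoder(x, hidden = 6, seed = 1, epochs = 400)
  s_train <- occ_score(m, x)
  s_out <- occ_score(m, matrix(10, 1, 6))
  expect_gt(s_out, quantile(s_train, 0.95))

  m2 <- train_autoencoder(x, hidden = 6, seed = 1, epochs = 400)
  expect_identical(occ_score(m2, x), s_train)  # seed determinism

  const <- matrix(0.3, 50, 4)  # identical input repeated: reconstructible
  mc <- train_autoencoder(const, hidden = 4, seed = 1, epochs = 400)
  expect_lt(mean(occ_score(mc, const)), 1e-3)
})

test_that("OC-SVM flags a distant outlier (margin-respecting kernels)", {
  x <- gaussian_cloud(n = 60, p = 4, seed = 55)
  out <- matrix(9, 1, 4)
  for (kernel in c("linear", "medium_gaussian")) {
    m <- train_ocsvm(x, kernel)
    expect_gt(occ_score(m, out), max(occ_score(m, x)) - 1e-9, label = kernel)
  }
})

test_that("OC-SVM boundary support vectors score approximately zero", {
  x <- gaussian_cloud(n = 60, p = 4, seed = 55)
  for (kernel in c("linear", "quadratic", "cubic", "medium_gaussian")) {
    m <- train_ocsvm(x, kernel)
    ub <- 1 / (0.05 * nrow(x))  # alpha upper bound in the nu formulation
    co <- as.numeric(m$fit$coefs)
    free <- which(co > 1e-8 & co < ub - 1e-8)
    expect_gt(length(free), 0L, label = kernel)
    boundary <- x[m$fit$index[free], , drop = FALSE]
    expect_lt(max(abs(occ_score(m, boundary))), 1e-3, label = kernel)
  }
})

test_that("RBF OC-SVM scores are invariant to joint rotation", {
  set.seed(66)
  x <- matrix(rnorm(240), 80, 3)
  q <- matrix(rnorm(30), 10, 3)
  s0 <- occ_score(train_ocsvm(x, "medium_gaussian"), q)
  r <- random_rotation(seed = 3)
  s1 <- occ_score(train_ocsvm(x %*% r, "medium_gaussian"), q %*% r)
  expect_equal(s0, s1, tolerance = 1e-6)
})

test_that("every model kind separates inliers from 3-sigma-shifted outliers", {
  set.seed(77)
  x <- gaussian_cloud(n = 80, p = 5, seed = 77)
  held_in <- matrix(rnorm(100), 20, 5)
  held_out <- matrix(rnorm(100), 20, 5) + 3
  params <- list(autoencoder = list(hidden = 6), gmm = list(components = 3),
                 ppnn = list(), ocknn = list(metric = "euclidean", k = 5),
                 ocsvm = list(kernel = "medium_gaussian"))
  for (kind in names(params)) {
    m <- occ_train(kind, x, params[[kind]], seed = 1)
    expect_gt(mean(occ_score(m, held_out)), mean(occ_score(m, held_in)),
              label = kind)
  }
})

test_that("scoring contract: empty input, purity, and dimension checks", {
  x <- gaussian_cloud(n = 30, p = 4, seed = 88)
  m <- train_ocknn(x, "euclidean", 5)
  expect_identical(occ_score(m, matrix(0, 0, 4)), numeric(0))
  q <- matrix(rnorm(20), 5, 4)
  expect_identical(occ_score(m, q), occ_score(m, q))
  expect_error(occ_score(m, matrix(0, 2, 3)), "trained on")
})

test_that("hyperparameter grids enumerate the study's search space", {
  expect_equal(hyper_grid("autoencoder")$hidden, c(6L, 10L, 12L, 15L))
  expect_equal(hyper_grid("gmm")$components, c(3L, 5L, 7L))
  g <- hyper_grid("ocknn")
  expect_equal(nrow(g), 12L)
  expect_setequal(unique(g$metric),
                  c("euclidean", "minkowski", "chebychev", "cosine"))
  expect_setequal(unique(g$k), c(5L, 10L, 50L))
  expect_equal(hyper_grid("ocsvm")$kernel,
               c("linear", "cubic", "quadratic", "medium_gaussian"))
})
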