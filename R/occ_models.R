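# One-class scorers.
#
# Every model is trained on ADL feature rows only and exposes a single
# anomaly score through occ_score(): larger = more anomalous, whatever the
# model's natural score direction. Likelihood-type scores (Parzen, OC-SVM)
# are negated to share this orientation, so one ROC sweep serves all five.

OCC_KINDS <- c("autoencoder", "gmm", "ppnn", "ocknn", "ocsvm")

new_occ_model <- function(kind, fit, p, params) {
  structure(list(kind = kind, fit = fit, p = p, params = params),
            class = c(paste0("occ_", kind), "occ_model"))
}

#' @export
print.occ_model <- function(x, ...) {
  ps <- paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  cat(sprintf("<occ_model %s> %d features%s\n", x$kind, x$p,
              if (nzchar(ps)) paste0(" (", ps, ")") else ""))
  invisible(x)
}

#' Hyperparameter grid for one model kind
#'
#' The grids mirror the study's search space: autoencoder hidden sizes
#' 6/10/12/15; GMM 3/5/7 diagonal components; a single Parzen configuration;
#' OC-KNN over four distances x three neighbour counts; OC-SVM over four
#' kernels. Enumeration order is fixed so tie-breaking is deterministic.
#'
#' @param kind One of `"autoencoder"`, `"gmm"`, `"ppnn"`, `"ocknn"`,
#'   `"ocsvm"`.
#' @return A `data.frame`, one row per hyperparameter combination.
#' @export
hyper_grid <- function(kind) {
  kind <- match.arg(kind, OCC_KINDS)
  switch(kind,
         autoencoder = data.frame(hidden = c(6L, 10L, 12L, 15L)),
         gmm = data.frame(components = c(3L, 5L, 7L)),
         ppnn = data.frame(bandwidth_rule = "median", stringsAsFactors = FALSE),
         ocknn = expand.grid(metric = c("euclidean", "minkowski",
                                        "chebychev", "cosine"),
                             k = c(5L, 10L, 50L),
                             KEEP.OUT.ATTRS = FALSE,
                             stringsAsFactors = FALSE),
         ocsvm = data.frame(kernel = c("linear", "cubic", "quadratic",
                                       "medium_gaussian"),
                            stringsAsFactors = FALSE))
}

check_train_matrix <- function(x, min_rows = 1L) {
  x <- as.matrix(x)
  if (!is.numeric(x) || !all(is.finite(x)))
    stop("training matrix must be finite and numeric")
  if (nrow(x) < min_rows)
    stop("training matrix needs at least ", min_rows, " rows")
  x
}

## ---- autoencoder -----------------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

# Min-max scaling to [0,1] per column (training ranges stored): the logistic
# decoder can only emit (0,1), so reconstruction happens in scaled space.
ae_scale <- function(x, lo, span) sweep(sweep(x, 2L, lo, "-"), 2L, span, "/")

#' Train a sparse autoencoder anomaly scorer
#'
#' Single hidden layer with logistic-sigmoid encoder and decoder, trained
#' full-batch with Adam for at most `epochs` epochs on the loss
#' MSE + 0.001 * L2(weights) + 1 * KL-sparsity (target mean hidden
#' activation 0.05). Inputs are min-max scaled to \[0, 1\] internally.
#' The anomaly score of a row is its mean squared reconstruction error in
#' scaled space.
#'
#' @param x Training matrix (rows = ADL feature vectors).
#' @param hidden Number of hidden neurons.
#' @param seed Integer seed for the weight initialization.
#' @param epochs Maximum number of full-batch epochs.
#' @param lr Adam learning rate.
#' @param sparsity_target Target mean hidden activation for the KL penalty.
#' @param l2 L2 regularization coefficient.
#' @param sparsity_coef Sparsity regularization coefficient.
#' @return An `occ_model`.
#' @export
train_autoencoder <- function(x, hidden = 10L, seed = 1L, epochs = 1000L,
                              lr = 0.05, sparsity_target = 0.05,
                              l2 = 0.001, sparsity_coef = 1) {
  x <- check_train_matrix(x, min_rows = 2L)
  p <- ncol(x)
  lo <- apply(x, 2L, min)
  span <- apply(x, 2L, max) - lo
  span[span < 1e-12] <- 1
  xs <- ae_scale(x, lo, span)
  n <- nrow(xs)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  W1 <- matrix(stats::runif(p * hidden, -0.5, 0.5), p, hidden) / sqrt(p)
  b1 <- numeric(hidden)
  W2 <- matrix(stats::runif(hidden * p, -0.5, 0.5), hidden, p) / sqrt(hidden)
  b2 <- numeric(p)

  mW1 <- vW1 <- W1 * 0; mW2 <- vW2 <- W2 * 0
  mb1 <- vb1 <- b1 * 0; mb2 <- vb2 <- b2 * 0
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  rho <- sparsity_target

  adam <- function(m, v, g, t) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    list(m = m, v = v,
         step = lr * (m / (1 - beta1^t)) / (sqrt(v / (1 - beta2^t)) + eps))
  }

  for (t in seq_len(epochs)) {
    H <- sigmoid(sweep(xs %*% W1, 2L, b1, "+"))
    Y <- sigmoid(sweep(H %*% W2, 2L, b2, "+"))
    # dLoss/dY for MSE averaged over n*p entries
    dY <- 2 * (Y - xs) / (n * p) * Y * (1 - Y)
    rho_hat <- pmin(pmax(colMeans(H), 1e-8), 1 - 1e-8)
    dsparse <- sparsity_coef * (-rho / rho_hat + (1 - rho) / (1 - rho_hat)) / n
    dH <- (dY %*% t(W2) + matrix(dsparse, n, hidden, byrow = TRUE)) *
      H * (1 - H)
    gW2 <- t(H) %*% dY + l2 * W2
    gb2 <- colSums(dY)
    gW1 <- t(xs) %*% dH + l2 * W1
    gb1 <- colSums(dH)
    u <- adam(mW1, vW1, gW1, t); mW1 <- u$m; vW1 <- u$v; W1 <- W1 - u$step
    u <- adam(mb1, vb1, gb1, t); mb1 <- u$m; vb1 <- u$v; b1 <- b1 - u$step
    u <- adam(mW2, vW2, gW2, t); mW2 <- u$m; vW2 <- u$v; W2 <- W2 - u$step
    u <- adam(mb2, vb2, gb2, t); mb2 <- u$m; vb2 <- u$v; b2 <- b2 - u$step
  }
  fit <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, lo = lo, span = span)
  new_occ_model("autoencoder", fit, p,
                list(hidden = hidden, seed = seed, epochs = epochs))
}

## ---- diagonal Gaussian mixture --------------------------------------------

# k-means++ seeding followed by Lloyd assignment, for the EM initialization.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  if (k > 1L) for (j in 2:k) {
    d2 <- apply(x, 1L, function(r)
      min(colSums((t(centers[seq_len(j - 1L), , drop = FALSE]) - r)^2)))
    if (sum(d2) <= 0) {
      centers[j, ] <- x[sample.int(n, 1L), ]
    } else {
      centers[j, ] <- x[sample.int(n, 1L, prob = d2), ]
    }
  }
  centers
}

gmm_log_density <- function(x, fit) {
  n <- nrow(x)
  k <- length(fit$weight)
  logcomp <- matrix(0, n, k)
  for (j in seq_len(k)) {
    v <- fit$variance[j, ]
    logcomp[, j] <- log(fit$weight[j]) -
      0.5 * sum(log(2 * pi * v)) -
      0.5 * rowSums(sweep(sweep(x, 2L, fit$mean[j, ], "-")^2, 2L, v, "/"))
  }
  mx <- apply(logcomp, 1L, max)
  mx + log(rowSums(exp(logcomp - mx)))
}

#' Train a diagonal-covariance Gaussian mixture scorer
#'
#' EM with k-means++ initialization, a 1e-6 variance floor, convergence
#' tolerance 1e-6 on the mean log-likelihood, and at most 500 iterations.
#' The anomaly score is the negative log-likelihood of a row under the
#' fitted mixture.
#'
#' @param x Training matrix.
#' @param components Number of mixture components.
#' @param seed Integer seed (initialization).
#' @param max_iter,tol EM stopping controls.
#' @return An `occ_model`; `fit$loglik_trace` records the mean
#'   log-likelihood after every EM iteration.
#' @export
train_gmm <- function(x, components = 3L, seed = 1L, max_iter = 500L,
                      tol = 1e-6) {
  if (components < 1L) stop("components must be >= 1")
  x <- check_train_matrix(x, min_rows = components)
  n <- nrow(x); p <- ncol(x)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  centers <- kmeanspp_centers(x, components)
  assign_idx <- apply(x, 1L, function(r)
    which.min(colSums((t(centers) - r)^2)))
  fit <- list(weight = as.numeric(tabulate(assign_idx, components) + 1) /
                (n + components),
              mean = centers,
              variance = matrix(pmax(rep(apply(x, 2L, stats::var), each = components),
                                     1e-6), components, p, byrow = FALSE))
  fit$variance[!is.finite(fit$variance)] <- 1
  trace <- numeric(0)
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    # E step
    logcomp <- matrix(0, n, components)
    for (j in seq_len(components)) {
      v <- fit$variance[j, ]
      logcomp[, j] <- log(fit$weight[j]) - 0.5 * sum(log(2 * pi * v)) -
        0.5 * rowSums(sweep(sweep(x, 2L, fit$mean[j, ], "-")^2, 2L, v, "/"))
    }
    mx <- apply(logcomp, 1L, max)
    ll_rows <- mx + log(rowSums(exp(logcomp - mx)))
    ll <- mean(ll_rows)
    trace <- c(trace, ll)
    resp <- exp(logcomp - ll_rows)
    # M step
    nk <- colSums(resp)
    fit$weight <- nk / n
    for (j in seq_len(components)) {
      mu <- colSums(resp[, j] * x) / nk[j]
      fit$mean[j, ] <- mu
      fit$variance[j, ] <- pmax(
        colSums(resp[, j] * sweep(x, 2L, mu, "-")^2) / nk[j], 1e-6)
    }
    if (is.finite(prev) && abs(ll - prev) < tol) break
    prev <- ll
  }
  fit$loglik_trace <- trace
  new_occ_model("gmm", fit, p, list(components = components, seed = seed))
}

## ---- Parzen probabilistic scorer ------------------------------------------

#' Train a Parzen-window probabilistic scorer
#'
#' Kernel density style likelihood with window function
#' \eqn{f(u) = e^{u - 1}}: likelihood(x) = mean over training rows of
#' \eqn{f(-\|x - x_j\|^2 / (2\sigma^2))}. The default bandwidth is the
#' median pairwise training distance divided by \eqn{\sqrt 2}. Anomaly
#' score = negated likelihood (shared orientation).
#'
#' @param x Training matrix.
#' @param bandwidth Either the string `"median"` (default rule) or a
#'   positive number.
#' @return An `occ_model`.
#' @export
train_ppnn <- function(x, bandwidth = "median") {
  x <- check_train_matrix(x, min_rows = 1L)
  if (identical(bandwidth, "median")) {
    if (nrow(x) > 1L) {
      sigma <- stats::median(stats::dist(x)) / sqrt(2)
    } else sigma <- 1
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  } else {
    sigma <- as.numeric(bandwidth)
    if (!is.finite(sigma) || sigma <= 0) stop("bandwidth must be positive")
  }
  new_occ_model("ppnn", list(train = x, sigma = sigma), ncol(x),
                list(bandwidth = sigma))
}

## ---- k-th nearest-neighbour distance ---------------------------------------

pairwise_distance <- function(a, b, metric, minkowski_p = 3) {
  switch(metric,
         euclidean = {
           d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
           sqrt(pmax(d2, 0))
         },
         minkowski = {
           d <- matrix(0, nrow(a), nrow(b))
           for (j in seq_len(ncol(a)))
             d <- d + abs(outer(a[, j], b[, j], "-"))^minkowski_p
           d^(1 / minkowski_p)
         },
         chebychev = {
           d <- matrix(0, nrow(a), nrow(b))
           for (j in seq_len(ncol(a)))
             d <- pmax(d, abs(outer(a[, j], b[, j], "-")))
           d
         },
         cosine = {
           na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
           na[na < 1e-300] <- 1e-300; nb[nb < 1e-300] <- 1e-300
           1 - (a %*% t(b)) / outer(na, nb)
         },
         stop("unknown metric: ", metric))
}

#' Train a one-class k-nearest-neighbour distance scorer
#'
#' The anomaly score of a query is the distance to its k-th nearest
#' training row. Minkowski uses exponent 3 (so it is distinct from the
#' separately listed Euclidean); cosine distance is 1 minus the cosine
#' similarity.
#'
#' @param x Training matrix.
#' @param metric `"euclidean"`, `"minkowski"`, `"chebychev"`, or `"cosine"`.
#' @param k Neighbour rank used as the score.
#' @return An `occ_model`.
#' @export
train_ocknn <- function(x, metric = "euclidean", k = 5L) {
  metric <- match.arg(metric, c("euclidean", "minkowski", "chebychev",
                                "cosine"))
  x <- check_train_matrix(x, min_rows = 1L)
  if (k < 1L || k > nrow(x))
    stop("k must lie in [1, number of training rows]")
  new_occ_model("ocknn", list(train = x, metric = metric, k = as.integer(k)),
                ncol(x), list(metric = metric, k = k))
}

## ---- one-class SVM ---------------------------------------------------------

#' Train a one-class support vector machine scorer
#'
#' nu-formulation (nu = 0.05) via \code{e1071::svm}. Kernels follow the
#' naming of the study's toolbox: `linear`; `quadratic`/`cubic` are
#' polynomial kernels of degree 2/3 (gamma 1, offset 1); `medium_gaussian`
#' is an RBF with kernel scale \eqn{\sqrt P} for P features (gamma = 1/P).
#' The anomaly score is the negated decision value, so the fitted boundary
#' sits at score 0.
#'
#' @param x Training matrix (already normalized; no internal rescaling).
#' @param kernel One of `"linear"`, `"quadratic"`, `"cubic"`,
#'   `"medium_gaussian"`.
#' @param nu Expected outlier fraction of the training set.
#' @return An `occ_model`.
#' @export
train_ocsvm <- function(x, kernel = "medium_gaussian", nu = 0.05) {
  kernel <- match.arg(kernel, c("linear", "quadratic", "cubic",
                                "medium_gaussian"))
  x <- check_train_matrix(x, min_rows = 2L)
  p <- ncol(x)
  args <- switch(kernel,
                 linear = list(kernel = "linear"),
                 quadratic = list(kernel = "polynomial", degree = 2L,
                                  gamma = 1, coef0 = 1),
                 cubic = list(kernel = "polynomial", degree = 3L,
                              gamma = 1, coef0 = 1),
                 medium_gaussian = list(kernel = "radial", gamma = 1 / p))
  fit <- do.call(e1071::svm,
                 c(list(x = x, y = NULL, type = "one-classification",
                        nu = nu, scale = FALSE), args))
  new_occ_model("ocsvm", fit, p, list(kernel = kernel, nu = nu))
}

## ---- unified scoring -------------------------------------------------------

#' Score rows with a trained one-class model
#'
#' A single orientation for all five model kinds: larger = more anomalous.
#' Reconstruction error (autoencoder), negative log-likelihood (GMM), and
#' k-th neighbour distance (OC-KNN) are already anomaly-directed; the
#' Parzen likelihood and the OC-SVM decision value are negated.
#'
#' @param model An `occ_model`.
#' @param x Matrix (or data.frame) whose columns match the training matrix.
#' @return Numeric vector of anomaly scores (length `nrow(x)`).
#' @export
occ_score <- function(model, x) {
  stopifnot(inherits(model, "occ_model"))
  x <- as.matrix(x)
  if (nrow(x) == 0L) return(numeric(0))
  if (ncol(x) != model$p)
    stop("query has ", ncol(x), " columns but the model was trained on ",
         model$p)
  if (!all(is.finite(x))) stop("query matrix must be finite")
  f <- model$fit
  switch(model$kind,
         autoencoder = {
           xs <- ae_scale(x, f$lo, f$span)
           H <- sigmoid(sweep(xs %*% f$W1, 2L, f$b1, "+"))
           Y <- sigmoid(sweep(H %*% f$W2, 2L, f$b2, "+"))
           rowMeans((Y - xs)^2)
         },
         gmm = -gmm_log_density(x, f),
         ppnn = {
           d2 <- outer(rowSums(x^2), rowSums(f$train^2), "+") -
             2 * x %*% t(f$train)
           lik <- rowMeans(exp(-pmax(d2, 0) / (2 * f$sigma^2) - 1))
           -lik
         },
         ocknn = {
           d <- pairwise_distance(x, f$train, f$metric)
           apply(d, 1L, function(r) sort(r, partial = f$k)[f$k])
         },
         ocsvm = {
           pr <- stats::predict(f, x, decision.values = TRUE)
           -as.numeric(attr(pr, "decision.values"))
         },
         stop("unknown model kind"))
}

#' Train a one-class model by kind
#'
#' Thin dispatcher over the five `train_*` functions, used by the grid
#' search. `params` is one row of [hyper_grid()] (as a list).
#'
#' @param kind Model kind (see [hyper_grid()]).
#' @param x Training matrix.
#' @param params Named list of hyperparameters for that kind.
#' @param seed Integer seed forwarded to stochastic trainers.
#' @return An `occ_model`.
#' @export
occ_train <- function(kind, x, params = list(), seed = 1L) {
  kind <- match.arg(kind, OCC_KINDS)
  switch(kind,
         autoencoder = train_autoencoder(x, hidden = params$hidden %||% 10L,
                                         seed = seed),
         gmm = train_gmm(x, components = params$components %||% 3L,
                         seed = seed),
         ppnn = train_ppnn(x, bandwidth = params$bandwidth_rule %||% "median"),
         ocknn = train_ocknn(x, metric = params$metric %||% "euclidean",
                             k = params$k %||% 5L),
         ocsvm = train_ocsvm(x, kernel = params$kernel %||% "medium_gaussian"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
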