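# Peak-centered feature extraction.
#
# All features derive from a 2 s observation window centered on the sample
# where the signal magnitude vector (SMV) attains its global maximum; the
# rest of the trace is discarded. The twelve candidate statistics are labeled
# A through L; the seven-feature subset BCDFGIK and the full set are the two
# presets the experiments use.

FEATURE_IDS <- c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K", "L")

#' Signal magnitude vector
#'
#' Euclidean norm of the triaxial acceleration, per sample:
#' \eqn{SMV_i = \sqrt{A_{x,i}^2 + A_{y,i}^2 + A_{z,i}^2}}.
#'
#' @param x Numeric length-3 vector or an N x 3 matrix (in g).
#' @return Scalar or length-N vector of magnitudes in g.
#' @export
smv <- function(x) {
  if (is.matrix(x)) sqrt(rowSums(x^2)) else sqrt(sum(x^2))
}

#' Resolve a feature-set specification
#'
#' Accepts the preset names `"BCDFGIK"` and `"ABCDEFGHIJKL"` (alias
#' `"ALL12"`), or any custom string/vector of unique IDs drawn from A-L.
#'
#' @param spec Preset name, ID string (e.g. `"ACG"`), or character vector.
#' @return Ordered character vector of feature IDs.
#' @export
feature_set <- function(spec = "BCDFGIK") {
  if (length(spec) == 1L) {
    if (toupper(spec) == "ALL12") spec <- "ABCDEFGHIJKL"
    spec <- strsplit(spec, "")[[1L]]
  }
  spec <- toupper(spec)
  if (anyDuplicated(spec)) stop("feature IDs must be unique")
  bad <- setdiff(spec, FEATURE_IDS)
  if (length(bad)) stop("unknown feature ID(s): ", paste(bad, collapse = ", "))
  spec
}

#' Extract the peak-centered observation window
#'
#' Finds the index of the global SMV maximum (first occurrence on ties) and
#' cuts `N_W = round(fs * t_w)` consecutive samples centered on it
#' (\eqn{\pm t_w/2} around the peak). Windows that would overflow a trace
#' edge are shifted to fit entirely inside the trace; traces shorter than
#' `N_W` are edge-replicated to the full window length.
#'
#' @param trace A [fall_trace()].
#' @param t_w Window duration in seconds (default 2).
#' @return A list of class `obs_window` with fields `samples` (`N_W` x 3),
#'   `fs`, `n_w`, and `peak_index` (index of the peak in the original trace).
#' @export
extract_window <- function(trace, t_w = 2) {
  stopifnot(inherits(trace, "fall_trace"))
  x <- trace$samples
  n <- nrow(x)
  if (n < 1L) stop("empty trace")
  n_w <- max(2L, as.integer(round(trace$fs * t_w)))
  i_o <- which.max(smv(x))
  if (n < n_w) {
    pad_tail <- n_w - n
    x <- rbind(x, x[rep(n, pad_tail), , drop = FALSE])
    start <- 1L
  } else {
    start <- i_o - n_w %/% 2L
    start <- min(max(start, 1L), n - n_w + 1L)
  }
  structure(list(samples = x[start:(start + n_w - 1L), , drop = FALSE],
                 fs = trace$fs, n_w = n_w, peak_index = i_o),
            class = "obs_window")
}

sample_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 < 1e-24) return(0)
  mean((x - m)^3) / s2^1.5
}

# Mean of the biased normalized autocorrelation of the mean-removed SMV over
# all positive lags; 0 for zero-variance windows.
mean_autocorrelation <- function(x) {
  n <- length(x)
  if (stats::var(x) < 1e-24) return(0)
  r <- stats::acf(x, lag.max = n - 1L, plot = FALSE, demean = TRUE)$acf[, 1L, 1L]
  mean(r[-1L])
}

#' Compute the windowed feature statistics
#'
#' For the window samples \eqn{a_i} and their magnitudes \eqn{SMV_i}:
#' \describe{
#'   \item{A}{mean SMV (g)}
#'   \item{B}{maximum variation of the acceleration vector,
#'     \eqn{\max_i \|a_{i+1} - a_i\|_2} (g)}
#'   \item{C}{sample standard deviation of SMV (g, denominator `N_W - 1`)}
#'   \item{D}{mean rotation angle between consecutive acceleration vectors
#'     (radians; zero-norm pairs contribute 0)}
#'   \item{E}{mean absolute first difference of SMV (g)}
#'   \item{F}{mean magnitude of the component parallel to the floor plane,
#'     with gravity estimated as the normalized window-mean vector (g)}
#'   \item{G}{maximum SMV (g) -- the impact peak}
#'   \item{H}{minimum SMV (g) -- the free-fall valley}
#'   \item{I}{sample skewness g1 of SMV (0 for constant windows)}
#'   \item{J}{signal magnitude area: mean of |Ax|+|Ay|+|Az| (g)}
#'   \item{K}{energy, \eqn{\sum_i SMV_i^2} (g^2 samples)}
#'   \item{L}{mean autocorrelation of the mean-removed SMV over all positive
#'     lags (0 for constant windows)}
#' }
#'
#' @param window An `obs_window` from [extract_window()].
#' @param spec Feature IDs (see [feature_set()]).
#' @return Named numeric vector, one value per requested feature, in spec
#'   order.
#' @export
compute_features <- function(window, spec = feature_set("ABCDEFGHIJKL")) {
  spec <- feature_set(spec)
  x <- window$samples
  n <- nrow(x)
  if (n < 2L) stop("window must contain at least 2 samples")
  s <- smv(x)
  d <- x[-1L, , drop = FALSE] - x[-n, , drop = FALSE]

  vals <- c()
  for (id in spec) {
    v <- switch(
      id,
      A = mean(s),
      B = max(sqrt(rowSums(d^2))),
      C = stats::sd(s),
      D = {
        n1 <- s[-n]; n2 <- s[-1L]
        dot <- rowSums(x[-n, , drop = FALSE] * x[-1L, , drop = FALSE])
        ok <- n1 > 1e-12 & n2 > 1e-12
        ang <- numeric(n - 1L)
        ang[ok] <- acos(pmin(1, pmax(-1, dot[ok] / (n1[ok] * n2[ok]))))
        mean(ang)
      },
      E = mean(abs(diff(s))),
      F = {
        g <- colMeans(x)
        gn <- sqrt(sum(g^2))
        if (gn < 1e-12) {
          mean(s)
        } else {
          ghat <- g / gn
          par <- x - (x %*% ghat) %*% t(ghat)
          mean(sqrt(rowSums(par^2)))
        }
      },
      G = max(s),
      H = min(s),
      I = sample_skewness(s),
      J = mean(rowSums(abs(x))),
      K = sum(s^2),
      L = mean_autocorrelation(s))
    vals <- c(vals, v)
  }
  names(vals) <- spec
  vals
}

#' Build a feature matrix for a whole manifest
#'
#' Reads every trace, extracts its peak window, and computes the requested
#' features. Metadata columns (`trace_id`, `label`, `category`) precede the
#' feature columns, which follow spec order.
#'
#' @param manifest A `fall_manifest`.
#' @param spec Feature IDs (see [feature_set()]).
#' @param traces Optional pre-read named list of traces (avoids re-reading).
#' @return A `data.frame` with one row per trace.
#' @export
feature_matrix <- function(manifest, spec = feature_set("ABCDEFGHIJKL"),
                           traces = NULL) {
  spec <- feature_set(spec)
  if (is.null(traces)) traces <- read_traces(manifest)
  feats <- t(vapply(manifest$trace_id, function(id) {
    compute_features(extract_window(traces[[id]]), spec)
  }, numeric(length(spec))))
  out <- data.frame(trace_id = manifest$trace_id, label = manifest$label,
                    category = manifest$category, stringsAsFactors = FALSE)
  out[, spec] <- feats
  out
}

#' Fit a per-column z-score normalizer
#'
#' Means and standard deviations are learned from the training matrix only
#' and later applied to held-out rows, so no test-set information leaks into
#' the scaling. Columns whose standard deviation falls below 1e-12 are
#' treated as constant (sd set to 1, centering only).
#'
#' @param x Numeric matrix or all-numeric data.frame of training rows.
#' @return An object of class `znorm` with `mean` and `sd` vectors.
#' @export
fit_normalizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("cannot fit a normalizer on an empty matrix")
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  structure(list(mean = mu, sd = sd), class = "znorm")
}

#' Apply a fitted z-score normalizer
#'
#' @param normalizer A `znorm` from [fit_normalizer()].
#' @param x Matrix/data.frame with the same columns as the training matrix.
#' @return Matrix of z-scored values.
#' @export
apply_normalizer <- function(normalizer, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(normalizer$mean))
    stop("column count does not match the fitted normalizer")
  sweep(sweep(x, 2L, normalizer$mean, "-"), 2L, normalizer$sd, "/")
}
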