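# Shared fixtures, built in code. The small configuration keeps unit tests
# fast; the default configuration (the study conditions) is reserved for the
# acceptance suite.

small_config <- function(seed = 1, ...) {
  args <- list(fs = 50, duration = 8, n_subjects = 3,
               n_basic = 8, n_standard = 8, n_sporting = 8, n_falls = 10,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(generator_config, args)
}

digest_file <- function(p) paste(readLines(p), collapse = "\n")

# Lazily generated small dataset (seed 1), cached for the whole test run.
.fixture_env <- new.env(parent = emptyenv())

small_dataset <- function() {
  if (is.null(.fixture_env$manifest)) {
    dir <- file.path(tempdir(), "occfall_small_fixture")
    .fixture_env$manifest <- generate_dataset(small_config(), dir)
    .fixture_env$feats <- feature_matrix(.fixture_env$manifest)
  }
  list(manifest = .fixture_env$manifest, feats = .fixture_env$feats)
}

# Seeded Gaussian cloud with optional far outliers appended, for the model
# separation properties.
gaussian_cloud <- function(n = 60, p = 5, seed = 42, n_out = 0, shift = 8) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  if (n_out > 0) {
    out <- matrix(rnorm(n_out * p), n_out, p) + shift
    x <- rbind(x, out)
  }
  x
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

write_tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
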