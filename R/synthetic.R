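# Synthetic triaxial accelerometer traces for ADLs and falls.
#
# The generator emulates the structure the downstream analysis assumes:
# gravity (1 g along a per-subject orientation), an activity component whose
# intensity grows from the basic to the sporting category, white Gaussian
# sensor noise, and falls built from four consecutive phases (pre-fall
# activity, free-fall dip, half-sine impact spike, post-impact rest).

#' Configuration for the synthetic trace generator
#'
#' Defaults describe the study conditions: 100 Hz sampling (inside the
#' 18-238 Hz span of public fall repositories), 15 s traces, 0.03 g sensor
#' noise, 20 traces per ADL category and 30 falls spread over 5 subjects.
#' Fall-phase parameter ranges are chosen so that the free-fall valley and
#' impact peak land inside the ranges the corresponding features are meant
#' to capture: a free-fall floor of 0.1-0.4 g over 0.2-0.6 s and an impact
#' peak of 3-6 g lasting at most 0.5 s.
#'
#' @param fs Sampling rate in Hz.
#' @param duration Trace duration in seconds.
#' @param noise_sd Per-axis white-noise standard deviation in g.
#' @param n_subjects Number of synthetic subjects.
#' @param n_basic,n_standard,n_sporting ADL trace counts per category.
#' @param n_falls Fall trace count.
#' @param seed Integer seed making [generate_dataset()] deterministic.
#' @param freefall_floor Range (g) of the free-fall SMV floor.
#' @param freefall_duration Range (s) of the free-fall phase, within
#'   \[0.2, 0.6\].
#' @param impact_peak Range (g) of the impact SMV peak.
#' @param impact_duration Range (s) of the impact spike; upper bound must
#'   not exceed 0.5 s.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(fs = 100, duration = 15, noise_sd = 0.03,
                             n_subjects = 5,
                             n_basic = 20, n_standard = 20, n_sporting = 20,
                             n_falls = 30, seed = 1,
                             freefall_floor = c(0.1, 0.4),
                             freefall_duration = c(0.2, 0.6),
                             impact_peak = c(3, 6),
                             impact_duration = c(0.1, 0.5)) {
  stopifnot(fs > 0, duration > 0, noise_sd >= 0, n_subjects >= 1)
  for (r in list(freefall_floor, freefall_duration, impact_peak,
                 impact_duration)) {
    if (length(r) != 2L || r[1L] > r[2L])
      stop("parameter ranges must be length-2 with lo <= hi")
  }
  if (impact_duration[2L] > 0.5)
    stop("impact duration upper bound must not exceed 0.5 s")
  if (freefall_duration[1L] < 0.2 || freefall_duration[2L] > 0.6)
    stop("free-fall duration range must lie within [0.2, 0.6] s")
  structure(list(fs = fs, duration = duration, noise_sd = noise_sd,
                 n_subjects = n_subjects, n_basic = n_basic,
                 n_standard = n_standard, n_sporting = n_sporting,
                 n_falls = n_falls, seed = as.integer(seed),
                 freefall_floor = freefall_floor,
                 freefall_duration = freefall_duration,
                 impact_peak = impact_peak,
                 impact_duration = impact_duration),
            class = "generator_config")
}

runif1 <- function(lo, hi) stats::runif(1L, lo, hi)

random_unit_vector <- function() {
  v <- stats::rnorm(3L)
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(0, 0, 1) else v / n
}

# Spherical linear interpolation between unit vectors, t in [0, 1].
slerp <- function(u, v, t) {
  d <- max(-1, min(1, sum(u * v)))
  omega <- acos(d)
  if (omega < 1e-8) return(matrix(rep(u, each = length(t)), ncol = 3L))
  (sin((1 - t) * omega) %o% u + sin(t * omega) %o% v) / sin(omega)
}

# Subject model: a resting orientation and a multiplicative movement
# amplitude drawn once per subject (range 0.8-1.2).
draw_subject <- function(id) {
  list(subject_id = id,
       orientation = random_unit_vector(),
       amplitude = runif1(0.8, 1.2))
}

add_noise <- function(x, sd) {
  if (sd <= 0) return(x)
  x + matrix(stats::rnorm(length(x), sd = sd), ncol = 3L)
}

#' Generate one synthetic ADL trace
#'
#' The signal is gravity (1 g along the subject orientation) plus a
#' category-dependent activity component plus white noise. Basic movements
#' are band-limited fluctuations of 0.02-0.08 g with at most one smooth
#' posture transition; standard movements add a periodic component
#' (fundamental 1.5-2.5 Hz, amplitude 0.2-0.5 g, one harmonic); sporting
#' movements are faster (2.5-3.5 Hz) and stronger (0.8-2.0 g) with sporadic
#' spikes up to 4 g. Consumes the session RNG stream; seed via `set.seed()`
#' or use [generate_dataset()].
#'
#' @param category `"basic"`, `"standard"` or `"sporting"`.
#' @param config A [generator_config()].
#' @param subject Optional subject model (orientation + amplitude factor);
#'   drawn fresh when `NULL`.
#' @param trace_id Identifier for the resulting trace.
#' @return A [fall_trace()] labeled `ADL`.
#' @export
generate_adl <- function(category, config = generator_config(),
                         subject = NULL, trace_id = "adl") {
  category <- match.arg(category, c("basic", "standard", "sporting"))
  if (is.null(subject)) subject <- draw_subject("s1")
  n <- max(2L, round(config$fs * config$duration))
  t <- (seq_len(n) - 1L) / config$fs
  grav <- matrix(rep(subject$orientation, each = n), ncol = 3L)

  act <- matrix(0, n, 3L)
  if (category == "basic") {
    amp <- runif1(0.02, 0.08) * subject$amplitude
    dir <- random_unit_vector()
    # band-limited fluctuation: two slow sinusoids below 1 Hz
    f1 <- runif1(0.2, 0.6); f2 <- runif1(0.6, 1.0)
    wave <- amp * (0.7 * sin(2 * pi * f1 * t + runif1(0, 2 * pi)) +
                     0.3 * sin(2 * pi * f2 * t + runif1(0, 2 * pi)))
    act <- wave %o% dir
    if (stats::runif(1L) < 0.5 && config$duration > 3) {
      # one smooth posture transition: rotate gravity over ~1.5 s and add a
      # small bump so SMV briefly departs from 1 g (bounded by 1.3 g)
      t0 <- runif1(0.2, config$duration - 2)
      idx <- which(t >= t0 & t <= t0 + 1.5)
      if (length(idx) > 1L) {
        target <- random_unit_vector()
        frac <- (t[idx] - t0) / 1.5
        grav[idx, ] <- slerp(subject$orientation, target, frac)
        if (max(idx) < n)
          grav[(max(idx) + 1L):n, ] <-
            matrix(rep(target, each = n - max(idx)), ncol = 3L)
        bump <- runif1(0.05, 0.2) * sin(pi * frac)
        grav[idx, ] <- grav[idx, ] * (1 + bump)
      }
    }
  } else {
    if (category == "standard") {
      f0 <- runif1(1.5, 2.5); amp <- runif1(0.2, 0.5) * subject$amplitude
    } else {
      f0 <- runif1(2.5, 3.5); amp <- runif1(0.8, 2.0) * subject$amplitude
    }
    dir <- random_unit_vector()
    ph <- runif1(0, 2 * pi)
    wave <- amp * (sin(2 * pi * f0 * t + ph) +
                     0.5 * sin(2 * pi * 2 * f0 * t + 2 * ph))
    act <- wave %o% dir
    if (category == "sporting") {
      n_spikes <- stats::rpois(1L, lambda = max(1, config$duration / 5))
      for (k in seq_len(n_spikes)) {
        c0 <- sample.int(n, 1L)
        w <- max(2L, round(0.05 * config$fs))
        idx <- c0:min(n, c0 + w)
        spike <- runif1(1.0, 4.0) * sin(pi * seq(0, 1, length.out = length(idx)))
        act[idx, ] <- act[idx, ] + spike %o% random_unit_vector()
      }
    }
  }
  x <- add_noise(grav + act, config$noise_sd)
  fall_trace(trace_id, x, fs = config$fs, label = "ADL",
             activity_type = paste0(category, "_synthetic"),
             category = category, subject_id = subject$subject_id)
}

#' Generate one synthetic fall trace
#'
#' Four consecutive phases: (1) a basic-activity pre-fall segment; (2) a
#' free-fall dip where the SMV decays from 1 g to a floor drawn from the
#' configured range; (3) a half-sine impact spike whose peak (3-6 g by
#' default, <= 0.5 s) is the global SMV maximum; (4) rest at a new, lying
#' orientation with reduced noise. With `noise_sd = 0` the SMV maximum
#' equals the drawn peak exactly and the free-fall minimum equals the drawn
#' floor.
#'
#' @inheritParams generate_adl
#' @return A [fall_trace()] labeled `FALL`, with attributes
#'   `impact_peak`, `freefall_floor`, and the phase sample ranges.
#' @export
generate_fall <- function(config = generator_config(), subject = NULL,
                          trace_id = "fall") {
  if (is.null(subject)) subject <- draw_subject("s1")
  fs <- config$fs
  n <- max(2L, round(fs * config$duration))
  ff_dur <- runif1(config$freefall_duration[1L], config$freefall_duration[2L])
  imp_dur <- runif1(config$impact_duration[1L], config$impact_duration[2L])
  n_ff <- max(2L, round(fs * ff_dur))
  n_imp <- max(3L, round(fs * imp_dur))
  if (n_imp %% 2L == 0L) n_imp <- n_imp + 1L  # odd: a sample sits on the peak
  n_rest_min <- max(2L, round(fs * 0.5))
  n_pre <- n - n_ff - n_imp - n_rest_min
  if (n_pre < max(2L, round(fs * 0.5)))
    stop("trace duration too short to contain pre-fall, free-fall, ",
         "impact and rest phases at fs = ", fs)

  floor_g <- runif1(config$freefall_floor[1L], config$freefall_floor[2L])
  peak_g <- runif1(config$impact_peak[1L], config$impact_peak[2L])
  orient <- subject$orientation
  t_pre <- (seq_len(n_pre) - 1L) / fs

  # phase 1: quiet ADL-like segment (keeps its own SMV well below the peak)
  amp <- runif1(0.02, 0.08) * subject$amplitude
  dir <- random_unit_vector()
  wave <- amp * sin(2 * pi * runif1(0.3, 0.9) * t_pre + runif1(0, 2 * pi))
  pre <- matrix(rep(orient, each = n_pre), ncol = 3L) + wave %o% dir

  # phase 2: SMV decays from 1 g to the floor along the falling orientation
  decay <- seq(1, floor_g, length.out = n_ff)
  ff <- decay %o% orient

  # phase 3: half-sine SMV spike along an impact direction; starts and ends
  # at the floor level so the profile is continuous with the free-fall dip
  imp_dir <- random_unit_vector()
  prof <- floor_g + (peak_g - floor_g) * sin(pi * seq(0, 1, length.out = n_imp))
  imp <- prof %o% imp_dir

  # phase 4: rest at a new (lying) orientation
  n_rest <- n - n_pre - n_ff - n_imp
  rest_orient <- random_unit_vector()
  rest <- matrix(rep(rest_orient, each = n_rest), ncol = 3L)

  x <- rbind(add_noise(pre, config$noise_sd),
             add_noise(ff, config$noise_sd / 3),
             imp,
             add_noise(rest, config$noise_sd / 3))
  tr <- fall_trace(trace_id, x, fs = fs, label = "FALL",
                   activity_type = "fall_synthetic", category = "none",
                   subject_id = subject$subject_id)
  attr(tr, "impact_peak") <- peak_g
  attr(tr, "freefall_floor") <- floor_g
  attr(tr, "phase_ranges") <- list(
    pre = c(1L, n_pre), freefall = c(n_pre + 1L, n_pre + n_ff),
    impact = c(n_pre + n_ff + 1L, n_pre + n_ff + n_imp),
    rest = c(n_pre + n_ff + n_imp + 1L, n))
  tr
}

#' Generate a labeled synthetic dataset on disk
#'
#' Draws subject models once, generates the configured number of ADL traces
#' per category and falls, writes each trace as a CSV and a manifest
#' indexing them. Deterministic: the same configuration (including seed)
#' yields byte-identical files.
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest (also written to `out_dir/manifest.csv`).
#' @export
generate_dataset <- function(config = generator_config(),
                             out_dir = tempfile("synthdata")) {
  total <- config$n_basic + config$n_standard + config$n_sporting +
    config$n_falls
  if (total < 1L) stop("at least one trace must be requested")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  subjects <- lapply(seq_len(config$n_subjects),
                     function(i) draw_subject(sprintf("s%02d", i)))
  rows <- list()
  idx <- 0L
  emit <- function(tr) {
    fname <- paste0(tr$trace_id, ".csv")
    write_trace(tr, file.path(out_dir, fname))
    data.frame(trace_id = tr$trace_id, path = fname, label = tr$label,
               activity_type = tr$activity_type, category = tr$category,
               subject_id = tr$subject_id, fs = tr$fs, unit = "g",
               stringsAsFactors = FALSE)
  }
  for (cat in c("basic", "standard", "sporting")) {
    n_cat <- config[[paste0("n_", cat)]]
    for (j in seq_len(n_cat)) {
      idx <- idx + 1L
      subj <- subjects[[(idx - 1L) %% config$n_subjects + 1L]]
      tr <- generate_adl(cat, config, subject = subj,
                         trace_id = sprintf("adl_%s_%03d", cat, j))
      rows[[length(rows) + 1L]] <- emit(tr)
    }
  }
  for (j in seq_len(config$n_falls)) {
    idx <- idx + 1L
    subj <- subjects[[(idx - 1L) %% config$n_subjects + 1L]]
    tr <- generate_fall(config, subject = subj,
                        trace_id = sprintf("fall_%03d", j))
    rows[[length(rows) + 1L]] <- emit(tr)
  }
  m <- do.call(rbind, rows)
  m <- validate_manifest(m, dir = out_dir)
  write_manifest(m, file.path(out_dir, "manifest.csv"))
  m
}
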