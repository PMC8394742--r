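# Core trace / manifest data model and its on-disk CSV formats.
#
# The canonical internal acceleration unit is g (1 g = 9.80665 m/s^2);
# traces recorded in m/s^2 are converted at read time. Time is implicit:
# sample i occurs at (i - 1) / fs seconds.

GRAVITY_MS2 <- 9.80665

MANIFEST_COLUMNS <- c("trace_id", "path", "label", "activity_type",
                      "category", "subject_id", "fs", "unit")

#' Construct a labeled triaxial acceleration trace
#'
#' A trace is one recording of a single movement: an N x 3 matrix of
#' acceleration components (in g) plus the sampling rate and the activity
#' metadata the evaluation protocols rely on. Fall traces carry category
#' `"none"`: intensity categories describe activities of daily living (ADLs)
#' only.
#'
#' @param trace_id Unique identifier string.
#' @param samples Numeric N x 3 matrix (columns ax, ay, az) in g, N >= 2.
#' @param fs Sampling rate in Hz (> 0).
#' @param label `"ADL"` or `"FALL"`.
#' @param activity_type Free-text movement name (e.g. `"walking"`).
#' @param category ADL intensity category: `"basic"`, `"standard"`,
#'   `"sporting"`, or `"none"` (mandatory for falls).
#' @param subject_id Identifier of the (possibly synthetic) subject.
#' @return An object of class `fall_trace`.
#' @export
fall_trace <- function(trace_id, samples, fs, label,
                       activity_type = "unknown",
                       category = c("basic", "standard", "sporting", "none"),
                       subject_id = "s1") {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L)
    stop("samples must have exactly 3 columns (ax, ay, az)")
  if (nrow(samples) < 2L)
    stop("a trace needs at least 2 samples, got ", nrow(samples))
  if (!all(is.finite(samples)))
    stop("all acceleration components must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number (Hz)")
  label <- match.arg(label, c("ADL", "FALL"))
  category <- match.arg(category)
  if (label == "FALL" && category != "none")
    stop("FALL traces must have category 'none'")
  colnames(samples) <- c("ax", "ay", "az")
  structure(
    list(trace_id = as.character(trace_id), samples = unname(samples) ,
         fs = as.numeric(fs), label = label,
         activity_type = as.character(activity_type), category = category,
         subject_id = as.character(subject_id)),
    class = "fall_trace")
}

#' @export
print.fall_trace <- function(x, ...) {
  cat(sprintf("<fall_trace %s> %s/%s, %d samples @ %g Hz (%.2f s), subject %s\n",
              x$trace_id, x$label,
              if (x$label == "ADL") x$category else x$activity_type,
              nrow(x$samples), x$fs, nrow(x$samples) / x$fs, x$subject_id))
  invisible(x)
}

#' Read a dataset manifest
#'
#' The manifest is the single source of labels and metadata: one row per
#' trace file, with columns `trace_id, path, label, activity_type, category,
#' subject_id, fs, unit`. `path` entries may be relative to the manifest's
#' own directory. Unit conversion is deferred to [read_trace()].
#'
#' @param path Path to a manifest CSV.
#' @return A `data.frame` of class `fall_manifest` with a `dir` attribute
#'   recording the manifest directory (used to resolve relative paths).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(m, dir = dirname(path))
}

validate_manifest <- function(m, dir = ".") {
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(m))
  if (length(missing_cols))
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  m <- m[, MANIFEST_COLUMNS]
  m$trace_id <- as.character(m$trace_id)
  dup <- unique(m$trace_id[duplicated(m$trace_id)])
  if (length(dup))
    stop("duplicate trace_id in manifest: ", paste(dup, collapse = ", "))
  if (!all(m$label %in% c("ADL", "FALL")))
    stop("manifest labels must be ADL or FALL")
  if (!all(m$category %in% c("basic", "standard", "sporting", "none")))
    stop("manifest categories must be basic/standard/sporting/none")
  if (!all(m$unit %in% c("g", "m/s2")))
    stop("manifest unit must be 'g' or 'm/s2'")
  if (any(m$label == "FALL" & m$category != "none"))
    stop("FALL rows must have category 'none'")
  if (!is.numeric(m$fs) || any(!is.finite(m$fs)) || any(m$fs <= 0))
    stop("manifest fs column must be positive and numeric")
  attr(m, "dir") <- dir
  class(m) <- c("fall_manifest", "data.frame")
  m
}

#' Write a dataset manifest
#'
#' @param manifest A `fall_manifest` (or compatible data.frame).
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest)[, MANIFEST_COLUMNS], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

resolve_trace_path <- function(entry, dir = NULL) {
  p <- entry$path
  if (!is.null(dir) && !file.exists(p)) {
    cand <- file.path(dir, p)
    if (file.exists(cand)) p <- cand
  }
  p
}

#' Read one trace referenced by a manifest entry
#'
#' Reads the trace CSV (`ax,ay,az` header, one row per sample) and converts
#' to g if the entry declares `m/s2` (divisor 9.80665). No resampling is
#' performed.
#'
#' @param entry One manifest row (a list or single-row data.frame with at
#'   least `trace_id, path, label, activity_type, category, subject_id, fs,
#'   unit`).
#' @param dir Optional directory against which a relative `path` is resolved
#'   (defaults to the manifest's `dir` attribute when `entry` comes from one).
#' @return A [fall_trace()].
#' @export
read_trace <- function(entry, dir = NULL) {
  entry <- as.list(entry)
  p <- resolve_trace_path(entry, dir)
  if (!file.exists(p)) stop("trace file not found: ", p)
  d <- utils::read.csv(p, stringsAsFactors = FALSE)
  need <- c("ax", "ay", "az")
  if (!all(need %in% names(d)))
    stop("trace file ", p, " must have columns ax, ay, az")
  d <- d[, need]
  x <- suppressWarnings(vapply(d, function(col) as.numeric(col),
                               numeric(nrow(d))))
  x <- matrix(x, ncol = 3L)
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric or non-finite value in trace file ", p,
         " at row ", bad[1L, 1L])
  if (nrow(x) < 2L)
    stop("trace ", entry$trace_id, " has fewer than 2 samples")
  if (identical(entry$unit, "m/s2")) x <- x / GRAVITY_MS2
  fall_trace(entry$trace_id, x, fs = as.numeric(entry$fs),
             label = entry$label, activity_type = entry$activity_type,
             category = entry$category, subject_id = entry$subject_id)
}

#' Read every trace of a manifest into a named list
#'
#' @param manifest A `fall_manifest`.
#' @return Named list of `fall_trace` objects, keyed by `trace_id`.
#' @export
read_traces <- function(manifest) {
  dir <- attr(manifest, "dir")
  out <- lapply(seq_len(nrow(manifest)),
                function(i) read_trace(manifest[i, ], dir = dir))
  names(out) <- manifest$trace_id
  out
}

#' Write a trace to CSV
#'
#' Values are written with enough significant digits that a write/read
#' round-trip reproduces samples to within 1e-9 g.
#'
#' @param trace A [fall_trace()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "fall_trace"))
  if (nrow(trace$samples) < 1L) stop("refusing to write an empty trace")
  x <- trace$samples
  lines <- c("ax,ay,az",
             sprintf("%.12g,%.12g,%.12g", x[, 1L], x[, 2L], x[, 3L]))
  writeLines(lines, path)
  invisible(path)
}
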