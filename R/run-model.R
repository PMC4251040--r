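#' @title In-memory model of a full-scan LC-MS run
#' @description
#' A `ms_run` is an ordered list of MS1 scans plus acquisition metadata; it is
#' the unit all chromatogram, spectrum and binning operations work on. Each
#' scan holds a retention time (seconds) and parallel `mz` / `intensity`
#' vectors, valid for both profile- and centroid-mode point lists.
#' @name run-model
NULL

#' Construct a single MS1 scan
#'
#' @param rt Retention time in seconds (non-negative scalar).
#' @param mz Numeric vector of m/z values; must be strictly ascending.
#' @param intensity Numeric vector of non-negative intensities, same length as
#'   `mz`.
#' @param ms_level MS level (positive integer, default 1).
#' @return A list of class `ms_scan`.
#' @export
new_scan <- function(rt, mz = numeric(), intensity = numeric(), ms_level = 1L) {
  rt <- as.numeric(rt)
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(rt) != 1L || is.na(rt) || rt < 0)
    stop("scan retention time must be a single non-negative number")
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length")
  if (length(mz) > 1L && any(diff(mz) <= 0))
    stop("m/z values within a scan must be strictly ascending")
  if (any(intensity < 0))
    stop("intensities must be non-negative")
  structure(
    list(rt = rt, mz = mz, intensity = intensity,
         ms_level = as.integer(ms_level)),
    class = "ms_scan"
  )
}

#' Construct a run from a list of scans
#'
#' Scans are sorted by retention time; m/z and RT bounds are computed from the
#' data. A run must contain at least one scan.
#'
#' @param scans List of `ms_scan` objects (or lists with `rt`, `mz`,
#'   `intensity` fields).
#' @param source_name Text label for the run, used as the default sample name.
#' @return A list of class `ms_run` with fields `scans`, `source_name`,
#'   `mz_min`, `mz_max`, `rt_min`, `rt_max`, `n_scans`.
#' @export
new_run <- function(scans, source_name = "run") {
  if (length(scans) == 0L)
    stop("a run must contain at least one scan")
  rts <- vapply(scans, function(s) s$rt, numeric(1))
  scans <- scans[order(rts)]
  rts <- sort(rts)
  npts <- vapply(scans, function(s) length(s$mz), integer(1))
  if (any(npts > 0)) {
    mz_min <- min(vapply(scans[npts > 0], function(s) s$mz[1L], numeric(1)))
    mz_max <- max(vapply(scans[npts > 0], function(s) s$mz[length(s$mz)],
                         numeric(1)))
  } else {
    mz_min <- NA_real_
    mz_max <- NA_real_
  }
  structure(
    list(scans = scans, source_name = as.character(source_name),
         mz_min = mz_min, mz_max = mz_max,
         rt_min = rts[1L], rt_max = rts[length(rts)],
         n_scans = length(scans)),
    class = "ms_run"
  )
}

#' @export
print.ms_run <- function(x, ...) {
  cat("<ms_run>", x$source_name, "\n")
  cat(sprintf("  %d MS1 scans, rt %.2f-%.2f min, m/z %.4g-%.4g\n",
              x$n_scans, x$rt_min / 60, x$rt_max / 60, x$mz_min, x$mz_max))
  invisible(x)
}

#' Construct a (time, intensity) series
#'
#' Times are stored in seconds; user-facing tables and plots report minutes.
#'
#' @param times Numeric vector of retention times in seconds, non-decreasing.
#' @param values Numeric vector of intensities, same length.
#' @return A list of class `ms_timeseries`.
#' @export
new_timeseries <- function(times, values) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have the same length")
  if (length(times) > 1L && any(diff(times) < 0))
    stop("times must be non-decreasing")
  structure(list(times = times, values = values), class = "ms_timeseries")
}

#' @export
print.ms_timeseries <- function(x, ...) {
  cat(sprintf("<ms_timeseries> %d points, %.2f-%.2f min\n", length(x$times),
              if (length(x$times)) x$times[1] / 60 else NA,
              if (length(x$times)) x$times[length(x$times)] / 60 else NA))
  invisible(x)
}

#' Construct an (m/z, intensity) spectrum
#'
#' @param mz Strictly ascending numeric vector of m/z values.
#' @param intensity Non-negative numeric vector, same length.
#' @return A list of class `ms_spectrum`.
#' @export
new_spectrum <- function(mz, intensity) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length")
  if (length(mz) > 1L && any(diff(mz) <= 0))
    stop("spectrum m/z values must be strictly ascending")
  structure(list(mz = mz, intensity = intensity), class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("<ms_spectrum> %d points, m/z %.4g-%.4g\n", length(x$mz),
              if (length(x$mz)) x$mz[1] else NA,
              if (length(x$mz)) x$mz[length(x$mz)] else NA))
  invisible(x)
}

# Sort points by m/z and merge exact duplicates (sums their intensities) so
# the strict-ascending scan invariant holds for pooled point lists.
collapse_points <- function(mz, intensity) {
  if (length(mz) == 0L)
    return(list(mz = numeric(), intensity = numeric()))
  o <- order(mz)
  mz <- mz[o]
  intensity <- intensity[o]
  first <- c(TRUE, diff(mz) > 0)
  if (!all(first)) {
    grp <- cumsum(first)
    intensity <- as.numeric(rowsum(intensity, grp, reorder = TRUE))
    mz <- mz[first]
  }
  list(mz = mz, intensity = intensity)
}
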