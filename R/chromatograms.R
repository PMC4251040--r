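#' @title Chromatograms and time-averaged mass spectra
#' @description
#' TIC, BPC and EIC all produce one point per scan on the run's own time axis;
#' scans with no data points contribute a zero rather than being skipped, so
#' every series from one run is directly comparable. EIC mass windows are
#' CLOSED intervals `[lo, hi]` — the convention used when a window such as
#' 608–610 is meant to contain the ion at m/z 609. This deliberately differs
#' from the half-open membership rule of mass bins (see [make_grid()]).
#' @name chromatograms
NULL

#' Total ion chromatogram
#'
#' One point per scan; the value is the sum of the scan's intensity array.
#'
#' @param run An `ms_run`.
#' @return An `ms_timeseries`.
#' @export
total_ion_chromatogram <- function(run) {
  stopifnot(inherits(run, "ms_run"))
  new_timeseries(
    times = vapply(run$scans, function(s) s$rt, numeric(1)),
    values = vapply(run$scans, function(s) sum(s$intensity), numeric(1)))
}

#' Base peak chromatogram
#'
#' One point per scan; the value is the scan's maximum intensity (0 for an
#' empty scan). The BPC carries less baseline noise than the TIC because only
#' the tallest ion of each scan contributes.
#'
#' @param run An `ms_run`.
#' @return An `ms_timeseries`.
#' @export
base_peak_chromatogram <- function(run) {
  stopifnot(inherits(run, "ms_run"))
  new_timeseries(
    times = vapply(run$scans, function(s) s$rt, numeric(1)),
    values = vapply(run$scans, function(s)
      if (length(s$intensity)) max(s$intensity) else 0, numeric(1)))
}

#' Extracted ion chromatogram
#'
#' One point per scan; the value is the summed intensity of points whose m/z
#' lies in the closed interval `[mz_lo, mz_hi]`.
#'
#' @param run An `ms_run`.
#' @param mz_lo,mz_hi Mass window bounds (Th), `mz_lo < mz_hi`.
#' @return An `ms_timeseries`.
#' @export
extracted_ion_chromatogram <- function(run, mz_lo, mz_hi) {
  stopifnot(inherits(run, "ms_run"))
  if (!is.numeric(mz_lo) || !is.numeric(mz_hi) || mz_lo >= mz_hi)
    stop("mz_lo must be strictly smaller than mz_hi")
  if (!is.na(run$mz_min) && (mz_hi < run$mz_min || mz_lo > run$mz_max))
    warning("mass window [", mz_lo, ", ", mz_hi,
            "] is disjoint from the run's m/z range [", run$mz_min, ", ",
            run$mz_max, "]; the EIC is all zero")
  new_timeseries(
    times = vapply(run$scans, function(s) s$rt, numeric(1)),
    values = vapply(run$scans, function(s)
      sum(s$intensity[s$mz >= mz_lo & s$mz <= mz_hi]), numeric(1)))
}

# Half-open variant [lo, hi) used by the per-bin EIC export so that the zip
# contents exactly decompose the bin totals; `closed_hi` closes the last bin.
eic_halfopen <- function(run, mz_lo, mz_hi, closed_hi = FALSE) {
  new_timeseries(
    times = vapply(run$scans, function(s) s$rt, numeric(1)),
    values = vapply(run$scans, function(s) {
      inside <- s$mz >= mz_lo & (if (closed_hi) s$mz <= mz_hi
                                 else s$mz < mz_hi)
      sum(s$intensity[inside])
    }, numeric(1)))
}

#' Time-averaged mass spectrum over a retention-time window
#'
#' Pools all points of scans with `rt_lo <= rt <= rt_hi`, groups them by m/z
#' rounded to `mz_decimals` digits, and divides each group total by the number
#' of scans in the window (a per-scan average), so spectra from windows of
#' different widths are comparable.
#'
#' @param run An `ms_run`.
#' @param rt_lo,rt_hi Window bounds in seconds, `rt_lo < rt_hi`.
#' @param mz_decimals Decimals to which m/z is rounded before grouping
#'   (default 2, matching ion-trap resolution).
#' @return An `ms_spectrum` sorted by m/z.
#' @export
averaged_mass_spectrum <- function(run, rt_lo, rt_hi, mz_decimals = 2L) {
  stopifnot(inherits(run, "ms_run"))
  if (rt_lo >= rt_hi)
    stop("rt_lo must be strictly smaller than rt_hi")
  rts <- vapply(run$scans, function(s) s$rt, numeric(1))
  inside <- which(rts >= rt_lo & rts <= rt_hi)
  if (length(inside) == 0L)
    stop("no scans in the retention-time window [", rt_lo, ", ", rt_hi,
         "] seconds")
  mz <- round(unlist(lapply(run$scans[inside], function(s) s$mz),
                     use.names = FALSE), mz_decimals)
  ity <- unlist(lapply(run$scans[inside], function(s) s$intensity),
                use.names = FALSE)
  pts <- collapse_points(mz, ity)
  new_spectrum(mz = pts$mz, intensity = pts$intensity / length(inside))
}
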