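#' @title CSV export and raw-format writers
#' @description
#' Every result type exports as plain CSV: comma separator, `.` decimal,
#' header row, UTF-8, LF line endings. Chromatograms are written as
#' `time_min,intensity` (retention time reported in minutes at every user
#' interface even though it is stored in seconds), spectra as `mz,intensity`,
#' and bin matrices as one row per sample with leading `sample,group` columns
#' and one `lo_hi`-labeled column per bin. Writers for mzML (via \pkg{mzR})
#' and ANDI-MS netCDF (via \pkg{ncdf4}) serve the synthetic generator and
#' cross-format fixtures.
#' @name io-write
NULL

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a chromatogram time series as CSV
#'
#' @param series An `ms_timeseries`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(series, path) {
  stopifnot(inherits(series, "ms_timeseries"))
  write_csv_plain(
    data.frame(time_min = series$times / 60, intensity = series$values),
    path)
}

#' Read back a chromatogram CSV written by [write_timeseries_csv()]
#' @param path CSV file path.
#' @return An `ms_timeseries` (times converted back to seconds).
#' @export
read_timeseries_csv <- function(path) {
  df <- utils::read.csv(path)
  new_timeseries(times = df$time_min * 60, values = df$intensity)
}

#' Write a mass spectrum as CSV
#'
#' @param spec An `ms_spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "ms_spectrum"))
  write_csv_plain(data.frame(mz = spec$mz, intensity = spec$intensity), path)
}

#' Read back a spectrum CSV written by [write_spectrum_csv()]
#' @param path CSV file path.
#' @return An `ms_spectrum`.
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  new_spectrum(mz = df$mz, intensity = df$intensity)
}

#' Write a samples-by-bins matrix as CSV
#'
#' Columns are `sample`, `group`, then one column per bin labeled `lo_hi`.
#'
#' @param matrix A `bin_matrix` (see [group_bin()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "bin_matrix"))
  df <- data.frame(sample = matrix$samples, group = matrix$groups,
                   check.names = FALSE)
  vals <- as.data.frame(matrix$values)
  colnames(vals) <- bin_labels(matrix$grid)
  write_csv_plain(cbind(df, vals), path)
}

#' Read back a bin-matrix CSV written by [write_matrix_csv()]
#'
#' The bin grid is reconstructed from the `lo_hi` column labels.
#'
#' @param path CSV file path.
#' @return A `bin_matrix`.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("sample", "group") %in% colnames(df)[1:2]))
    stop("not a bin-matrix CSV: expected leading sample,group columns")
  labels <- colnames(df)[-(1:2)]
  parts <- strsplit(labels, "_", fixed = TRUE)
  lo <- vapply(parts, function(p) as.numeric(p[1L]), numeric(1))
  hi <- vapply(parts, function(p) as.numeric(p[2L]), numeric(1))
  grid <- make_grid(lo[1L], hi[length(hi)], lo[2L] - lo[1L])
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  dimnames(vals) <- NULL
  new_bin_matrix(grid = grid, samples = as.character(df$sample),
                 groups = as.character(df$group), values = vals)
}

#' Write a run as mzML
#'
#' Serializes an `ms_run` through the proteowizard writer in \pkg{mzR}; used
#' by the synthetic generator so simulated studies can round-trip through the
#' same reader as instrument data.
#'
#' @param run An `ms_run`.
#' @param path Output path (should end in `.mzML`).
#' @return `path`, invisibly.
#' @export
write_run_mzml <- function(run, path) {
  stopifnot(inherits(run, "ms_run"))
  n <- run$n_scans
  pk <- lapply(run$scans, function(s) cbind(mz = s$mz,
                                            intensity = s$intensity))
  tot <- vapply(run$scans, function(s) sum(s$intensity), numeric(1))
  bp <- lapply(run$scans, function(s) {
    if (length(s$intensity) == 0L) list(mz = 0, int = 0)
    else {
      i <- which.max(s$intensity)
      list(mz = s$mz[i], int = s$intensity[i])
    }
  })
  levels <- vapply(run$scans, function(s) s$ms_level %||% 1L, integer(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = levels, polarity = rep(0L, n),
    peaksCount = vapply(run$scans, function(s) length(s$mz), integer(1)),
    totIonCurrent = tot,
    retentionTime = vapply(run$scans, function(s) s$rt, numeric(1)),
    basePeakMZ = vapply(bp, `[[`, numeric(1), "mz"),
    basePeakIntensity = vapply(bp, `[[`, numeric(1), "int"),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(run$scans, function(s)
      if (length(s$mz)) s$mz[1L] else 0, numeric(1)),
    highMZ = vapply(run$scans, function(s)
      if (length(s$mz)) s$mz[length(s$mz)] else 0, numeric(1)),
    precursorScanNum = 0L, precursorMZ = ifelse(levels > 1L, 500, 0),
    precursorCharge = ifelse(levels > 1L, 1L, 0L),
    precursorIntensity = ifelse(levels > 1L, 100, 0),
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  suppressWarnings(mzR::writeMSData(pk, path, header = hdr,
                                    outformat = "mzml"))
  invisible(path)
}

#' Write a run as ANDI-MS netCDF
#'
#' Emits the classic ANDI-MS layout (`scan_index`, `point_count`,
#' `mass_values`, `intensity_values`, `scan_acquisition_time`); used to build
#' cross-format fixtures.
#'
#' @param run An `ms_run`.
#' @param path Output path (should end in `.cdf`).
#' @return `path`, invisibly.
#' @export
write_run_andi <- function(run, path) {
  stopifnot(inherits(run, "ms_run"))
  cnt <- vapply(run$scans, function(s) length(s$mz), integer(1))
  idx <- cumsum(c(0L, cnt[-length(cnt)]))
  mz <- unlist(lapply(run$scans, function(s) s$mz), use.names = FALSE)
  ity <- unlist(lapply(run$scans, function(s) s$intensity), use.names = FALSE)
  if (length(mz) == 0L)
    stop("cannot write an ANDI file for a run with no data points")
  dscan <- ncdf4::ncdim_def("scan_number", "", seq_along(cnt),
                            create_dimvar = FALSE)
  dpoint <- ncdf4::ncdim_def("point_number", "", seq_along(mz),
                             create_dimvar = FALSE)
  vars <- list(
    ncdf4::ncvar_def("scan_index", "", dscan, prec = "integer"),
    ncdf4::ncvar_def("point_count", "", dscan, prec = "integer"),
    ncdf4::ncvar_def("scan_acquisition_time", "seconds", dscan,
                     prec = "double"),
    ncdf4::ncvar_def("total_intensity", "", dscan, prec = "double"),
    ncdf4::ncvar_def("mass_values", "thomson", dpoint, prec = "double"),
    ncdf4::ncvar_def("intensity_values", "counts", dpoint, prec = "double"))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ncdf4::ncvar_put(nc, "scan_index", idx)
  ncdf4::ncvar_put(nc, "point_count", cnt)
  ncdf4::ncvar_put(nc, "scan_acquisition_time",
                   vapply(run$scans, function(s) s$rt, numeric(1)))
  ncdf4::ncvar_put(nc, "total_intensity",
                   vapply(run$scans, function(s) sum(s$intensity), numeric(1)))
  ncdf4::ncvar_put(nc, "mass_values", mz)
  ncdf4::ncvar_put(nc, "intensity_values", ity)
  invisible(path)
}
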