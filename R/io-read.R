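#' Read a full-scan LC-MS run
#'
#' Loads an mzML, mzXML or ANDI-MS netCDF file into an [new_run()] object.
#' Only MS1 scans are kept; MSn scans are dropped with a message reporting the
#' count. mzData input is rejected (obsolete dialect with no maintained
#' reader). XML formats are parsed through the proteowizard backend of
#' \pkg{mzR}; the netCDF dialect is ANDI-MS (`scan_index` / `point_count` /
#' `mass_values` / `intensity_values` / `scan_acquisition_time`).
#'
#' @param path Path to the data file.
#' @param format One of `"auto"`, `"mzml"`, `"mzxml"`, `"netcdf"`. `"auto"`
#'   sniffs the extension first, then the file's leading bytes.
#' @return An `ms_run` with scans sorted by retention time and m/z / RT bounds
#'   computed from the data.
#' @export
read_run <- function(path, format = c("auto", "mzml", "mzxml", "netcdf")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file not found: ", path)
  if (format == "auto")
    format <- sniff_format(path)
  if (format == "mzdata")
    stop("unsupported format: mzData is an obsolete dialect and is not read; ",
         "convert '", basename(path), "' to mzML")
  run <- switch(format,
    mzml = , mzxml = read_run_mzr(path),
    netcdf = read_run_andi(path),
    stop("unrecognized format for ", basename(path))
  )
  run
}

sniff_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  fmt <- switch(ext,
    mzml = "mzml", mzxml = "mzxml",
    cdf = "netcdf", nc = "netcdf",
    mzdata = "mzdata", NULL)
  if (!is.null(fmt))
    return(fmt)
  head <- readBin(path, what = "raw", n = 512L)
  if (length(head) >= 3L && rawToChar(head[1:3]) == "CDF")
    return("netcdf")
  txt <- suppressWarnings(rawToChar(head[head != as.raw(0)]))
  if (grepl("<mzML|indexedmzML", txt))
    return("mzml")
  if (grepl("<mzXML", txt))
    return("mzxml")
  if (grepl("<mzData", txt))
    return("mzdata")
  stop("cannot recognize the format of ", basename(path),
       " (expected mzML, mzXML or ANDI netCDF)")
}

read_run_mzr <- function(path) {
  handle <- tryCatch(
    mzR::openMSfile(path, backend = "pwiz"),
    error = function(e)
      stop("format error reading ", basename(path), ": ",
           conditionMessage(e), call. = FALSE)
  )
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- tryCatch(
    mzR::header(handle),
    error = function(e)
      stop("format error reading ", basename(path), ": ",
           conditionMessage(e), call. = FALSE)
  )
  if (nrow(hdr) == 0L)
    stop("empty run: no scans in ", basename(path))
  ms1 <- which(hdr$msLevel == 1L)
  n_dropped <- nrow(hdr) - length(ms1)
  if (length(ms1) == 0L)
    stop("empty run: no MS1 scans in ", basename(path))
  if (n_dropped > 0L)
    message("dropped ", n_dropped, " MSn scan(s) from ", basename(path))
  scans <- lapply(ms1, function(i) {
    pk <- mzR::peaks(handle, i)
    pts <- collapse_points(pk[, 1L], pk[, 2L])
    new_scan(rt = hdr$retentionTime[i], mz = pts$mz,
             intensity = pts$intensity)
  })
  new_run(scans, source_name = strip_ms_ext(basename(path)))
}

read_run_andi <- function(path) {
  nc <- tryCatch(
    ncdf4::nc_open(path),
    error = function(e)
      stop("format error reading ", basename(path), ": ",
           conditionMessage(e), call. = FALSE)
  )
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  need <- c("scan_index", "point_count", "mass_values", "intensity_values",
            "scan_acquisition_time")
  missing <- setdiff(need, names(nc$var))
  if (length(missing) > 0L)
    stop("format error reading ", basename(path),
         ": not ANDI-MS (missing ", paste(missing, collapse = ", "), ")")
  idx <- as.numeric(ncdf4::ncvar_get(nc, "scan_index"))
  cnt <- as.numeric(ncdf4::ncvar_get(nc, "point_count"))
  rt <- as.numeric(ncdf4::ncvar_get(nc, "scan_acquisition_time"))
  mz <- as.numeric(ncdf4::ncvar_get(nc, "mass_values"))
  ity <- as.numeric(ncdf4::ncvar_get(nc, "intensity_values"))
  n <- length(idx)
  if (n == 0L)
    stop("empty run: no scans in ", basename(path))
  scans <- lapply(seq_len(n), function(i) {
    if (cnt[i] == 0)
      return(new_scan(rt = rt[i]))
    sel <- seq.int(idx[i] + 1L, idx[i] + cnt[i])
    pts <- collapse_points(mz[sel], ity[sel])
    new_scan(rt = rt[i], mz = pts$mz, intensity = pts$intensity)
  })
  new_run(scans, source_name = strip_ms_ext(basename(path)))
}

strip_ms_ext <- function(x) {
  sub("\\.(mzml|mzxml|cdf|nc)$", "", x, ignore.case = TRUE)
}
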