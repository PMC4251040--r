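#' @title Mass binning: fingerprints of the mass dimension
#' @description
#' Binning collapses a run's mass dimension into `N = (mass range) / (bin
#' size)` fixed-width intervals (rounded up when the range is not an exact
#' multiple). Each bin's value is the total intensity of ALL ions, in ALL
#' scans, whose m/z falls inside it — a retention-time-free fingerprint of the
#' sample that needs no peak deconvolution or RT alignment. Bins are half-open
#' `[lo, hi)` with the last bin closed at the upper mass limit, and edges are
#' anchored at the user's lower mass limit, so a size-2 grid starting at 100
#' produces the even-numbered bins (608_610, 706_708, ...) that practitioners
#' quote.
#' @name binning
NULL

#' Define a bin grid over a mass range
#'
#' @param mass_lo,mass_hi Mass range bounds (Th), `mass_lo < mass_hi`.
#' @param bin_size Bin width (Th), positive. The number of bins is
#'   `ceiling((mass_hi - mass_lo) / bin_size)`; when the range divides
#'   exactly this equals `(mass_hi - mass_lo) / bin_size` and all bins have
#'   the nominal width, otherwise the last bin is narrower.
#' @return A `bin_grid` with fields `mass_lo`, `mass_hi`, `bin_size`,
#'   `n_bins` and `edges` (length `n_bins + 1`).
#' @export
make_grid <- function(mass_lo, mass_hi, bin_size) {
  if (!is.numeric(mass_lo) || !is.numeric(mass_hi) || mass_lo >= mass_hi)
    stop("mass_lo must be strictly smaller than mass_hi")
  if (!is.numeric(bin_size) || bin_size <= 0)
    stop("bin_size must be positive")
  span <- mass_hi - mass_lo
  n <- ceiling(span / bin_size - 1e-9)
  edges <- mass_lo + bin_size * seq.int(0L, n)
  edges[n + 1L] <- mass_hi
  structure(
    list(mass_lo = mass_lo, mass_hi = mass_hi, bin_size = bin_size,
         n_bins = as.integer(n), edges = edges),
    class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> %d bins of size %g over m/z %g-%g\n",
              x$n_bins, x$bin_size, x$mass_lo, x$mass_hi))
  invisible(x)
}

#' Bin labels in `lo_hi` form
#' @param grid A `bin_grid`.
#' @return Character vector of length `n_bins`, e.g. `"608_610"`.
#' @export
bin_labels <- function(grid) {
  fmt <- vapply(grid$edges, function(e)
    format(e, trim = TRUE, scientific = FALSE), character(1))
  paste0(fmt[-length(fmt)], "_", fmt[-1L])
}

# Bin index per point: 1..n_bins inside the grid, 0 below, n_bins + 1 above.
# Half-open [e_i, e_{i+1}) except the last bin, closed at mass_hi.
bin_index <- function(mz, grid) {
  findInterval(mz, grid$edges, rightmost.closed = TRUE)
}

new_bin_vector <- function(grid, values, sample, group = NA_character_,
                           discarded = 0) {
  stopifnot(length(values) == grid$n_bins, all(values >= 0))
  structure(
    list(grid = grid, values = as.numeric(values),
         sample = as.character(sample), group = as.character(group),
         discarded = as.numeric(discarded)),
    class = "bin_vector")
}

#' @export
print.bin_vector <- function(x, ...) {
  cat(sprintf("<bin_vector> %s: %d bins, total intensity %.6g\n",
              x$sample, x$grid$n_bins, sum(x$values)))
  invisible(x)
}

new_bin_matrix <- function(grid, samples, groups, values) {
  stopifnot(nrow(values) == length(samples),
            length(groups) == length(samples),
            ncol(values) == grid$n_bins)
  structure(
    list(grid = grid, samples = as.character(samples),
         groups = as.character(groups), values = values),
    class = "bin_matrix")
}

#' @export
print.bin_matrix <- function(x, ...) {
  cat(sprintf("<bin_matrix> %d samples x %d bins (groups: %s)\n",
              length(x$samples), x$grid$n_bins,
              paste(unique(x$groups), collapse = ", ")))
  invisible(x)
}

#' Bin one run
#'
#' Sums the intensities of every point of every scan into the grid's bins.
#' Points outside `[mass_lo, mass_hi]` are discarded; their count and total
#' intensity are reported with a message and kept on the result (`discarded`)
#' so the conservation law `sum(values) + discarded == total ion current` can
#' be audited.
#'
#' @param run An `ms_run`.
#' @param grid A `bin_grid`.
#' @param group Optional group label attached to the result.
#' @return A `bin_vector`.
#' @export
bin_run <- function(run, grid, group = NA_character_) {
  stopifnot(inherits(run, "ms_run"), inherits(grid, "bin_grid"))
  mz <- unlist(lapply(run$scans, function(s) s$mz), use.names = FALSE)
  ity <- unlist(lapply(run$scans, function(s) s$intensity), use.names = FALSE)
  idx <- bin_index(mz, grid)
  keep <- idx >= 1L & idx <= grid$n_bins
  values <- numeric(grid$n_bins)
  if (any(keep)) {
    agg <- rowsum(ity[keep], idx[keep], reorder = TRUE)
    values[as.integer(rownames(agg))] <- agg[, 1L]
  }
  n_out <- sum(!keep)
  if (n_out > 0L)
    message("bin_run: discarded ", n_out, " point(s) outside the grid (",
            format(sum(ity[!keep])), " total intensity)")
  new_bin_vector(grid = grid, values = values, sample = run$source_name,
                 group = group, discarded = sum(ity[!keep]))
}

#' Aggregate a bin vector onto a coarser aligned grid
#'
#' When the coarse width is an exact multiple of the fine width and the mass
#' range divides both exactly, the fine bins partition the coarse ones and the
#' aggregation is an exact regrouping (up to float summation order). Exposed
#' as a library utility so multi-size comparisons can be checked without
#' re-binning the raw data.
#'
#' @param bv A `bin_vector`.
#' @param new_size Coarser bin width; must be a whole multiple of the fine
#'   width, and the mass range must divide `new_size` exactly.
#' @return A `bin_vector` on the coarse grid.
#' @export
rebin_vector <- function(bv, new_size) {
  stopifnot(inherits(bv, "bin_vector"))
  old <- bv$grid
  k <- new_size / old$bin_size
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("new_size must be a whole multiple of the current bin size")
  k <- as.integer(round(k))
  span <- old$mass_hi - old$mass_lo
  if (abs(span / new_size - round(span / new_size)) > 1e-9 ||
      old$n_bins %% k != 0L)
    stop("the mass range must divide the coarse bin size exactly")
  coarse <- make_grid(old$mass_lo, old$mass_hi, new_size)
  groups <- rep(seq_len(coarse$n_bins), each = k)
  values <- as.numeric(rowsum(bv$values, groups, reorder = TRUE))
  new_bin_vector(grid = coarse, values = values, sample = bv$sample,
                 group = bv$group, discarded = bv$discarded)
}

#' Bin a set of runs into a samples-by-bins matrix
#'
#' Row `i` is `bin_run(runs[[i]], grid)`. Sample names come from each run's
#' `source_name`, deduplicated with numeric suffixes.
#'
#' @param runs List of `ms_run` objects (at least one).
#' @param grid A `bin_grid` shared by all rows.
#' @param groups Character vector of group labels, one per run.
#' @return A `bin_matrix`.
#' @export
group_bin <- function(runs, grid, groups) {
  if (length(runs) == 0L)
    stop("at least one run is required")
  if (length(groups) != length(runs))
    stop("groups must have one label per run (got ", length(groups),
         " labels for ", length(runs), " runs)")
  vectors <- lapply(seq_along(runs), function(i)
    bin_run(runs[[i]], grid, group = groups[i]))
  samples <- make.unique(vapply(vectors, function(v) v$sample, character(1)),
                         sep = "_")
  values <- do.call(rbind, lapply(vectors, function(v) v$values))
  new_bin_matrix(grid = grid, samples = samples,
                 groups = as.character(groups), values = values)
}

#' Export the EIC of every bin as a zip of CSV files
#'
#' Writes one `time_min,intensity` CSV per bin, computed with the bin's own
#' half-open membership (`[lo, hi)`, last bin closed) so the per-bin series
#' sum exactly to the bin totals, and bundles them into a zip archive. Note
#' this differs from the closed-interval convention of the user-facing
#' [extracted_ion_chromatogram()]. A small bin size produces a large number
#' of files; a warning is raised beyond 1000 bins.
#'
#' @param run An `ms_run`.
#' @param grid A `bin_grid`.
#' @param out_dir Writable output directory; the archive is written as
#'   `<out_dir>/<source_name>_bin_eics.zip`.
#' @return Invisibly, a list with `zip` (archive path) and `files` (the CSV
#'   names inside the archive).
#' @export
eics_for_all_bins <- function(run, grid, out_dir) {
  stopifnot(inherits(run, "ms_run"), inherits(grid, "bin_grid"))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (grid$n_bins > 1000L)
    warning("a small bin size will result in a large number of EIC files (",
            grid$n_bins, " bins)")
  stage <- file.path(tempfile("bin_eics_"))
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  labels <- bin_labels(grid)
  files <- paste0("eic_", labels, ".csv")
  for (i in seq_len(grid$n_bins)) {
    eic <- eic_halfopen(run, grid$edges[i], grid$edges[i + 1L],
                        closed_hi = (i == grid$n_bins))
    write_timeseries_csv(eic, file.path(stage, files[i]))
  }
  zip_path <- file.path(normalizePath(out_dir),
                        paste0(run$source_name, "_bin_eics.zip"))
  zip::zip(zip_path, files = files, root = stage, mode = "cherry-pick")
  invisible(list(zip = zip_path, files = files))
}
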