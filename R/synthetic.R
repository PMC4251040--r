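#' @title Synthetic LC-MS runs and two-group studies with known truth
#' @description
#' The generator builds full-scan runs from Gaussian chromatographic peaks —
#' each ion elutes with intensity `amplitude * exp(-(t - rt)^2 / (2
#' rt_sigma^2))` at its m/z — over a regular scan grid, plus an exponential
#' baseline (heavier-tailed than Gaussian and non-negative, as ion-trap
#' baselines are) scattered uniformly in m/z. Two-group studies add
#' log-normal sample-to-sample amplitude variation and multiply a chosen set
#' of "spiked" ions by an effect fold in one group, returning the complete
#' ground truth so recovery can be scored. Everything is deterministic under
#' a fixed seed, and all randomness is drawn independently of the effect
#' size, so effect grids share one random stream.
#' @name synthetic
NULL

#' Describe one chromatographic peak
#'
#' @param mz Ion m/z (Th).
#' @param rt Apex retention time (seconds).
#' @param rt_sigma Chromatographic width (seconds, Gaussian sigma).
#' @param amplitude Apex intensity (detector counts), positive.
#' @param mz_sigma Profile width in the mass dimension (Th); 0 gives a
#'   centroid (single point per scan). Satellite ions (isotopes, dimers) are
#'   expressed as additional `peak_spec` rows at their own m/z.
#' @return A one-row data frame; rows `rbind` into a peak list.
#' @export
peak_spec <- function(mz, rt, rt_sigma, amplitude, mz_sigma = 0) {
  stopifnot(all(amplitude > 0), all(rt_sigma >= 0), all(mz_sigma >= 0))
  data.frame(mz = mz, rt = rt, rt_sigma = rt_sigma, amplitude = amplitude,
             mz_sigma = mz_sigma)
}

# Profile points for one ion: 7 points across +-3 mz_sigma with Gaussian
# weights normalized to sum 1, so profile and centroid modes carry the same
# total intensity.
profile_offsets <- function(mz_sigma) {
  if (mz_sigma <= 0)
    return(list(d = 0, w = 1))
  d <- seq(-3, 3, length.out = 7L) * mz_sigma
  w <- exp(-d^2 / (2 * mz_sigma^2))
  list(d = d, w = w / sum(w))
}

#' Simulate one full-scan run
#'
#' @param peaks Peak list from [peak_spec()] (rows rbind-ed).
#' @param rt_grid Ascending vector of scan times (seconds).
#' @param noise_level Mean intensity of a single baseline point; 0 disables
#'   baseline noise.
#' @param noise_points_per_scan Number of baseline points per scan (default
#'   150).
#' @param mz_range m/z range over which baseline points are scattered
#'   (default `c(100, 1500)`, a typical ion-trap scan range).
#' @param seed Optional integer seed; fixing it makes the run byte-identical
#'   on repeat.
#' @param source_name Sample name carried by the run.
#' @return An `ms_run`.
#' @export
simulate_run <- function(peaks, rt_grid, noise_level = 0,
                         noise_points_per_scan = 150L,
                         mz_range = c(100, 1500), seed = NULL,
                         source_name = "synthetic") {
  stopifnot(is.data.frame(peaks) || is.null(peaks))
  if (is.unsorted(rt_grid, strictly = TRUE))
    stop("rt_grid must be strictly ascending")
  if (noise_level < 0)
    stop("noise_level must be non-negative")
  if (!is.null(seed))
    set.seed(seed)
  n_peaks <- if (is.null(peaks)) 0L else nrow(peaks)
  prof <- if (n_peaks > 0L)
    lapply(seq_len(n_peaks), function(i) profile_offsets(peaks$mz_sigma[i]))
  use_noise <- noise_level > 0 && noise_points_per_scan > 0
  scans <- lapply(rt_grid, function(t) {
    mz <- numeric()
    ity <- numeric()
    if (n_peaks > 0L) {
      h <- peaks$amplitude *
        exp(-(t - peaks$rt)^2 / (2 * pmax(peaks$rt_sigma, 1e-12)^2))
      if (all(peaks$mz_sigma <= 0)) {
        mz <- peaks$mz
        ity <- h
      } else {
        pt <- lapply(seq_len(n_peaks), function(i)
          list(mz = peaks$mz[i] + prof[[i]]$d, ity = h[i] * prof[[i]]$w))
        mz <- unlist(lapply(pt, `[[`, "mz"), use.names = FALSE)
        ity <- unlist(lapply(pt, `[[`, "ity"), use.names = FALSE)
      }
    }
    if (use_noise) {
      mz <- c(mz, stats::runif(noise_points_per_scan, mz_range[1L],
                               mz_range[2L]))
      ity <- c(ity, stats::rexp(noise_points_per_scan, rate = 1 / noise_level))
    }
    pts <- collapse_points(mz, ity)
    new_scan(rt = t, mz = pts$mz, intensity = pts$intensity)
  })
  new_run(scans, source_name = source_name)
}

#' Simulate a two-group spike-in study
#'
#' Generates `n_a + n_b` runs sharing `n_shared_peaks` background ions whose
#' amplitudes vary log-normally between samples (coefficient of variation
#' `cv`), plus `n_spiked` ions placed at the centers of distinct bins of
#' `grid` and multiplied by `effect_fold` in group A. The returned truth
#' manifest identifies the spiked bins, so downstream recovery (PCA
#' separation, volcano recall, clustering) can be scored exactly.
#'
#' @param n_a,n_b Group sizes (defaults 12 and 11, a realistic unbalanced
#'   two-treatment design after the loss of one replicate).
#' @param grid `bin_grid` defining the mass range and the spiked-bin truth
#'   (default: m/z 100-1500, size 2).
#' @param n_shared_peaks Background ions shared by all samples (default 30).
#' @param n_spiked Differential ions (default 10).
#' @param effect_fold Amplitude ratio of spiked ions, group A over group B
#'   (default 8); a scalar or a vector recycled to one value per spiked ion,
#'   so individual effect sizes can be varied independently.
#' @param cv Sample-to-sample coefficient of variation of every peak
#'   amplitude (default 0.15).
#' @param rt_grid Scan times in seconds (default 61 scans, 0-600 s).
#' @param noise_level Baseline point mean intensity; the default scales to
#'   1\% of the largest peak apex spread over one scan's baseline points.
#' @param noise_points_per_scan Baseline points per scan (default 150).
#' @param spiked_amplitude Apex amplitude of each spiked ion before the
#'   effect (default 4000, a modest constituent against shared ions of
#'   1e4-1e5).
#' @param group_names Two labels, default `c("A", "B")`; group A carries the
#'   spike.
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `runs` (list of `ms_run`), `groups` (label per run)
#'   and `truth` (list: `spiked_bins` (indices into the grid), `spiked_mz`,
#'   `effect_fold`, `shared_peaks`, `spiked_peaks`, `cv`, `seed`, `grid`).
#' @export
simulate_two_group_study <- function(n_a = 12L, n_b = 11L,
                                     grid = make_grid(100, 1500, 2),
                                     n_shared_peaks = 30L, n_spiked = 10L,
                                     effect_fold = 8, cv = 0.15,
                                     rt_grid = seq(0, 600, by = 10),
                                     noise_level = NULL,
                                     noise_points_per_scan = 150L,
                                     spiked_amplitude = 4000,
                                     group_names = c("A", "B"),
                                     seed = NULL) {
  stopifnot(n_a >= 2L, n_b >= 2L, all(effect_fold > 0), cv >= 0)
  effect_fold <- rep_len(effect_fold, n_spiked)
  if (!is.null(seed))
    set.seed(seed)
  margin <- 5 * grid$bin_size
  shared <- peak_spec(
    mz = stats::runif(n_shared_peaks, grid$mass_lo + margin,
                      grid$mass_hi - margin),
    rt = stats::runif(n_shared_peaks, min(rt_grid) + 60,
                      max(rt_grid) - 60),
    rt_sigma = 8,
    amplitude = 10^stats::runif(n_shared_peaks, 4, 5))
  shared_bins <- bin_index(shared$mz, grid)
  free_bins <- setdiff(seq_len(grid$n_bins), shared_bins)
  if (length(free_bins) < n_spiked)
    stop("grid too coarse to place ", n_spiked,
         " spiked ions in unused bins")
  spiked_bins <- sort(sample(free_bins, n_spiked))
  spiked_mz <- grid$edges[spiked_bins] + grid$bin_size / 2
  if (any(spiked_mz < grid$mass_lo | spiked_mz > grid$mass_hi))
    stop("spiked peak m/z falls outside the grid")
  spiked <- peak_spec(
    mz = spiked_mz,
    rt = stats::runif(n_spiked, min(rt_grid) + 60, max(rt_grid) - 60),
    rt_sigma = 8,
    amplitude = rep(spiked_amplitude, n_spiked))
  if (is.null(noise_level))
    noise_level <- 0.01 * max(shared$amplitude) /
      max(noise_points_per_scan, 1L)
  sdlog <- sqrt(log(1 + cv^2))
  n <- n_a + n_b
  groups <- rep(group_names, c(n_a, n_b))
  runs <- lapply(seq_len(n), function(i) {
    fac_shared <- stats::rlnorm(n_shared_peaks, -sdlog^2 / 2, sdlog)
    fac_spiked <- stats::rlnorm(n_spiked, -sdlog^2 / 2, sdlog)
    pk <- rbind(shared, spiked)
    pk$amplitude <- c(shared$amplitude * fac_shared,
                      spiked$amplitude * fac_spiked *
                        (if (groups[i] == group_names[1L]) effect_fold
                         else rep(1, n_spiked)))
    simulate_run(pk, rt_grid = rt_grid, noise_level = noise_level,
                 noise_points_per_scan = noise_points_per_scan,
                 mz_range = c(grid$mass_lo, grid$mass_hi),
                 source_name = sprintf("%s_%02d", groups[i], i))
  })
  list(runs = runs, groups = groups,
       truth = list(spiked_bins = spiked_bins, spiked_mz = spiked_mz,
                    effect_fold = effect_fold, shared_peaks = shared,
                    spiked_peaks = spiked, cv = cv,
                    noise_level = noise_level, seed = seed, grid = grid))
}
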