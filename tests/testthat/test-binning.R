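# Bin grids, fingerprints, refinement and per-bin EIC export.

test_that("the bin-count formula N = mass range / bin size holds", {
  g <- make_grid(100, 1500, 2)
  expect_equal(g$n_bins, 700L)
  expect_equal(g$edges[1:2], c(100, 102))
  expect_equal(g$edges[700:701], c(1498, 1500))

  expect_equal(make_grid(100, 1500, 50)$n_bins, 28L)
  expect_equal(vapply(c(50, 20, 10, 5, 2, 1), function(s)
    make_grid(100, 1500, s)$n_bins, integer(1)),
    as.integer(1400 / c(50, 20, 10, 5, 2, 1)))

  # inexact division rounds up; the last bin is narrower
  g3 <- make_grid(100, 105, 2)
  expect_equal(g3$n_bins, 3L)
  expect_equal(g3$edges, c(100, 102, 104, 105))

  expect_error(make_grid(100, 100, 2), "mass_lo")
  expect_error(make_grid(100, 200, 0), "bin_size")
})

test_that("bin labels are lo_hi at the grid's precision", {
  expect_equal(bin_labels(make_grid(100, 104, 2)), c("100_102", "102_104"))
  expect_equal(bin_labels(make_grid(100, 101, 0.5)), c("100_100.5",
                                                       "100.5_101"))
})

test_that("bin_run sums all scans' points into half-open bins", {
  run <- fixture_run()
  bv <- bin_run(run, make_grid(100, 300, 100))
  expect_equal(bv$values, c(15, 30))

  # one bin over the full scan range == total ion current
  one <- bin_run(run, make_grid(run$mz_min - 1, run$mz_max + 1, 1000))
  expect_equal(sum(one$values), sum(total_ion_chromatogram(run)$values))

  # points outside the grid are discarded and accounted for
  expect_message(bv2 <- bin_run(run, make_grid(140, 300, 80)), "discarded")
  expect_equal(bv2$discarded, 10)
  expect_equal(sum(bv2$values) + bv2$discarded,
               sum(total_ion_chromatogram(run)$values))
})

test_that("edge points land in exactly one bin", {
  run <- new_run(list(
    new_scan(rt = 1, mz = c(100, 102, 104, 106), intensity = c(1, 2, 3, 4))
  ), source_name = "edges")
  bv <- bin_run(run, make_grid(100, 106, 2))
  # [100,102) [102,104) [104,106]: each boundary point counted once, the
  # upper-limit point in the final closed bin
  expect_equal(bv$values, c(1, 2, 7))
  expect_equal(sum(bv$values), 10)
})

test_that("a dominant ion is recovered in its expected size-2 bin", {
  grid <- make_grid(100, 1500, 2)
  run <- simulate_run(rbind(
    peak_spec(mz = 609.2, rt = 25.89 * 60, rt_sigma = 8, amplitude = 5e4),
    peak_spec(mz = 301.1, rt = 700, rt_sigma = 8, amplitude = 5e3)),
    rt_grid = seq(1400, 1700, by = 10), noise_level = 1,
    noise_points_per_scan = 100, seed = 5L)
  bv <- bin_run(run, grid)
  expect_equal(bin_labels(grid)[which.max(bv$values)], "608_610")
})

test_that("fine grids aggregate exactly onto aligned coarser grids", {
  run <- cached_study()$study$runs[[1]]
  g1 <- make_grid(100, 1500, 1)
  b1 <- bin_run(run, g1)
  b2 <- rebin_vector(b1, 2)
  expect_equal(b2$grid$n_bins, 700L)
  expect_equal(b2$values, bin_run(run, make_grid(100, 1500, 2))$values,
               tolerance = 1e-9)
  b10 <- rebin_vector(b2, 10)
  expect_equal(b10$values, bin_run(run, make_grid(100, 1500, 10))$values,
               tolerance = 1e-9)
  b50 <- rebin_vector(b10, 50)
  expect_equal(b50$values, bin_run(run, make_grid(100, 1500, 50))$values,
               tolerance = 1e-9)

  expect_error(rebin_vector(b2, 3), "whole multiple")
})

test_that("group_bin assembles consistent rows with deduplicated names", {
  runs <- list(fixture_run(), fixture_run())
  grid <- make_grid(100, 300, 50)
  mat <- group_bin(runs, grid, groups = c("A", "B"))
  expect_equal(dim(mat$values), c(2L, 4L))
  expect_equal(mat$values[1, ], bin_run(runs[[1]], grid)$values)
  expect_equal(mat$values[2, ], bin_run(runs[[2]], grid)$values)
  expect_equal(anyDuplicated(mat$samples), 0L)

  expect_error(group_bin(list(), grid, character()), "at least one")
  expect_error(group_bin(runs, grid, "A"), "one label per run")
})

test_that("the study design yields a samples x 700 matrix", {
  cs <- cached_study()
  expect_equal(dim(cs$matrix$values), c(23L, 700L))
  expect_equal(table(cs$matrix$groups)[["A"]], 12L)
  expect_equal(table(cs$matrix$groups)[["B"]], 11L)
})

test_that("per-bin EIC export decomposes the bin totals", {
  run <- fixture_run()
  grid <- make_grid(100, 300, 100)
  out <- withr::local_tempdir()
  res <- eics_for_all_bins(run, grid, out)
  expect_true(file.exists(res$zip))
  expect_length(res$files, 2L)
  listing <- zip::zip_list(res$zip)
  expect_setequal(listing$filename, res$files)

  stage <- withr::local_tempdir()
  zip::unzip(res$zip, exdir = stage)
  bv <- bin_run(run, grid)
  for (i in seq_along(res$files)) {
    eic <- read_timeseries_csv(file.path(stage, res$files[i]))
    expect_equal(sum(eic$values), bv$values[i], tolerance = 1e-9)
  }
})

test_that("a fine grid warns about the number of EIC files", {
  run <- fixture_run()
  out <- withr::local_tempdir()
  expect_warning(res <- eics_for_all_bins(run, make_grid(100, 1500, 1), out),
                 "large number")
  expect_length(res$files, 1400L)
  expect_equal(nrow(zip::zip_list(res$zip)), 1400L)
})
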