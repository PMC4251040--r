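#' @title PNG plotting helpers
#' @description
#' Deterministic base-graphics renderings of every result type, at a fixed
#' figure size so outputs are reproducible; each plot is regenerable from the
#' corresponding CSV alone.
#' @name plots
NULL

plot_png <- function(path, draw, width = 900, height = 600) {
  grDevices::png(path, width = width, height = height, res = 96)
  on.exit(grDevices::dev.off())
  draw()
  invisible(path)
}

#' Plot a chromatogram
#' @param series An `ms_timeseries`.
#' @param main Title.
#' @param ylab Y-axis label.
#' @export
plot_chromatogram <- function(series, main = "Chromatogram",
                              ylab = "Intensity") {
  graphics::plot(series$times / 60, series$values, type = "l",
                 xlab = "Retention time (min)", ylab = ylab, main = main)
}

#' Plot a mass spectrum as a stick plot
#' @param spec An `ms_spectrum`.
#' @param main Title.
#' @export
plot_spectrum <- function(spec, main = "Mass spectrum") {
  graphics::plot(spec$mz, spec$intensity, type = "h", xlab = "m/z",
                 ylab = "Intensity", main = main)
}

#' Plot a bin vector as a histogram-style bar chart
#' @param bv A `bin_vector`.
#' @param main Title.
#' @export
plot_bins <- function(bv, main = NULL) {
  grid <- bv$grid
  mids <- (grid$edges[-1L] + grid$edges[-length(grid$edges)]) / 2
  if (is.null(main))
    main <- sprintf("Bin fingerprint (%s, size %g)", bv$sample,
                    grid$bin_size)
  graphics::plot(mids, bv$values, type = "h", xlab = "m/z bin",
                 ylab = "Total intensity", main = main)
}

#' Plot PCA scores colored by group
#' @param pca_res A `pca_result`.
#' @param groups Group labels, one per sample.
#' @export
plot_pca_scores <- function(pca_res, groups) {
  k <- ncol(pca_res$scores)
  x <- pca_res$scores[, 1L]
  y <- if (k >= 2L) pca_res$scores[, 2L] else rep(0, length(x))
  lev <- unique(groups)
  cols <- c("#D55E00", "#0072B2", "#009E73", "#CC79A7")
  col <- cols[(match(groups, lev) - 1L) %% length(cols) + 1L]
  graphics::plot(x, y, col = col, pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * pca_res$explained[1L]),
                 ylab = if (k >= 2L)
                   sprintf("PC2 (%.1f%%)", 100 * pca_res$explained[2L])
                 else "",
                 main = "PCA scores")
  graphics::legend("topright", legend = lev, col = cols[seq_along(lev)],
                   pch = 19, bty = "n")
}

#' Volcano plot
#' @param volcano_res A `volcano_result`.
#' @export
plot_volcano <- function(volcano_res) {
  lfc <- volcano_res$log2_fc
  logp <- -log10(pmax(volcano_res$p_value, 1e-300))
  keep <- is.finite(lfc)
  col <- rep("grey50", nrow(volcano_res))
  col[volcano_res$significant_up] <- "#D55E00"
  col[volcano_res$significant_down] <- "#009E73"
  graphics::plot(lfc[keep], logp[keep], col = col[keep], pch = 19,
                 xlab = sprintf("log2 fold change (%s / %s)",
                                attr(volcano_res, "reference"),
                                attr(volcano_res, "other")),
                 ylab = "-log10 p", main = "Volcano plot")
  graphics::abline(v = c(-1, 1) * log2(attr(volcano_res, "fc_thresh")),
                   lty = 2)
  graphics::abline(h = -log10(attr(volcano_res, "p_thresh")), lty = 2)
}

#' Plot an HCA dendrogram
#' @param hca_res An `hca_result`.
#' @param groups Optional labels appended to leaf names.
#' @export
plot_dendrogram <- function(hca_res, groups = NULL) {
  tree <- hca_res$tree
  if (!is.null(groups))
    tree$labels <- paste0(tree$labels, " [", groups, "]")
  graphics::plot(tree, xlab = "", sub = "",
                 main = sprintf("HCA (%s, Ward linkage)", hca_res$distance))
}
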