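#' @title Differential profiling over a feature table
#' @description
#' The automatic outputs of a two-group bin analysis: PCA scores and loadings
#' by singular value decomposition, a volcano analysis combining group-mean
#' fold changes (on sum-normalized data) with two-sided Welch t-tests (on the
#' transformed data), and agglomerative hierarchical clustering on
#' 1 - Pearson correlation with Ward linkage.
#' @name diffprofile
NULL

#' Principal component analysis
#'
#' Column-centers the matrix and decomposes it by SVD. Scores are `U %*% D`,
#' loadings are `V`, and the explained-variance fractions are the squared
#' singular values over their total. For determinism the sign of each
#' component is fixed so that its largest-magnitude loading is positive.
#'
#' @param x A fully preprocessed `feature_table` (autoscaled) or a plain
#'   numeric matrix (samples in rows).
#' @param n_components Number of components to keep; at most
#'   `min(n_samples - 1, n_features)`. Default keeps them all.
#' @return A `pca_result` with `scores` (samples x k), `loadings`
#'   (features x k), `explained` (variance fractions, length k), `samples`,
#'   `features`.
#' @export
pca <- function(x, n_components = NULL) {
  if (inherits(x, "feature_table")) {
    if (!"autoscaled" %in% x$steps)
      stop("pca expects a fully preprocessed (autoscaled) feature table; ",
           "pass a plain matrix to analyze unprocessed data")
    values <- x$values
    samples <- x$samples
    features <- x$features
  } else {
    values <- as.matrix(x)
    samples <- rownames(values) %||% paste0("sample", seq_len(nrow(values)))
    features <- colnames(values) %||% paste0("feature", seq_len(ncol(values)))
  }
  n <- nrow(values)
  p <- ncol(values)
  max_k <- min(n - 1L, p)
  if (is.null(n_components))
    n_components <- max_k
  if (n_components < 1L || n_components > max_k)
    stop("n_components must be between 1 and min(samples - 1, features) = ",
         max_k)
  centered <- sweep(values, 2L, colMeans(values))
  sv <- svd(centered, nu = max_k, nv = max_k)
  d <- sv$d[seq_len(max_k)]
  explained <- d^2 / sum(sv$d^2)
  k <- n_components
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(d[seq_len(k)], k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  rownames(scores) <- samples
  rownames(loadings) <- features
  structure(
    list(scores = scores, loadings = loadings,
         explained = explained[seq_len(k)], samples = samples,
         features = features),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components; explained: %s\n",
              ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}

#' Top PCA loadings of one component
#'
#' Features ranked by absolute loading, descending — the discriminatory
#' features a loadings inspection would shortlist. When the preprocessed
#' table is supplied, each feature also carries the direction (up/down in the
#' reference group) given by the sign of its group-mean difference.
#'
#' @param pca_res A `pca_result`.
#' @param component Component index (default 1).
#' @param k How many features to return (default 30); capped at the feature
#'   count.
#' @param table Optional `feature_table` with exactly two groups, used to
#'   assign directions.
#' @param reference Group treated as numerator/"up"; defaults to the first
#'   group level in the table.
#' @return A data frame with columns `feature`, `loading`, `abs_loading` and,
#'   when `table` is given, `direction` (`"up"`/`"down"` in the reference
#'   group).
#' @export
top_loadings <- function(pca_res, component = 1L, k = 30L, table = NULL,
                         reference = NULL) {
  stopifnot(inherits(pca_res, "pca_result"))
  if (component < 1L || component > ncol(pca_res$loadings))
    stop("component ", component, " does not exist")
  load <- pca_res$loadings[, component]
  k <- min(k, length(load))
  ord <- order(abs(load), decreasing = TRUE)[seq_len(k)]
  out <- data.frame(feature = pca_res$features[ord], loading = load[ord],
                    abs_loading = abs(load[ord]), row.names = NULL)
  if (!is.null(table)) {
    stopifnot(inherits(table, "feature_table"))
    lev <- unique(table$groups)
    if (length(lev) != 2L)
      stop("direction assignment needs exactly two groups")
    if (is.null(reference))
      reference <- lev[1L]
    idx <- match(out$feature, table$features)
    in_ref <- table$groups == reference
    diff <- colMeans(table$values[in_ref, idx, drop = FALSE]) -
      colMeans(table$values[!in_ref, idx, drop = FALSE])
    out$direction <- ifelse(diff >= 0, "up", "down")
  }
  out
}

# Textbook-free Welch test via stats::t.test; returns p only, NA-safe for
# degenerate inputs (both groups constant -> p = 1 when equal means).
welch_p <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Volcano analysis: fold change plus Welch t-test
#'
#' Fold changes are group-mean ratios computed on the sum-normalized,
#' pre-log table; significance is a two-sided Welch (unequal-variance)
#' t-test on the transformed (log2/autoscaled) table. A feature is flagged
#' up if `FC >= fc_thresh` and `p < p_thresh`, down if `FC <= 1/fc_thresh`
#' and `p < p_thresh`.
#'
#' @param normalized The sum-normalized `feature_table` (fold-change scale).
#' @param transformed The log2/autoscaled `feature_table` (test scale); must
#'   share samples and features with `normalized`.
#' @param reference Group used as the fold-change numerator; defaults to the
#'   first group level.
#' @param fc_thresh Fold-change threshold (default 4).
#' @param p_thresh p-value threshold (default 1e-10).
#' @return A `volcano_result`: a data frame with `feature`, `mean_ref`,
#'   `mean_other`, `fold_change`, `log2_fc`, `p_value`, `significant_up`,
#'   `significant_down`, plus attributes `reference`, `other`, `fc_thresh`,
#'   `p_thresh`.
#' @export
volcano <- function(normalized, transformed, reference = NULL,
                    fc_thresh = 4, p_thresh = 1e-10) {
  stopifnot(inherits(normalized, "feature_table"),
            inherits(transformed, "feature_table"))
  if (!identical(normalized$features, transformed$features) ||
      !identical(normalized$samples, transformed$samples))
    stop("the normalized and transformed tables must share samples and ",
         "features")
  lev <- unique(normalized$groups)
  if (length(lev) != 2L)
    stop("volcano analysis needs exactly two groups (got ",
         length(lev), ")")
  if (is.null(reference))
    reference <- lev[1L]
  if (!reference %in% lev)
    stop("reference group '", reference, "' is not a group label")
  other <- setdiff(lev, reference)
  in_ref <- normalized$groups == reference
  if (sum(in_ref) < 2L || sum(!in_ref) < 2L)
    stop("each group needs at least two samples")
  mean_ref <- colMeans(normalized$values[in_ref, , drop = FALSE])
  mean_other <- colMeans(normalized$values[!in_ref, , drop = FALSE])
  fc <- ifelse(mean_other == 0, Inf, mean_ref / mean_other)
  p <- vapply(seq_len(ncol(transformed$values)), function(j)
    welch_p(transformed$values[in_ref, j], transformed$values[!in_ref, j]),
    numeric(1))
  out <- data.frame(
    feature = normalized$features,
    mean_ref = mean_ref, mean_other = mean_other,
    fold_change = fc, log2_fc = log2(fc), p_value = p,
    infinite_fc = !is.finite(fc),
    significant_up = is.finite(fc) & fc >= fc_thresh & p < p_thresh,
    significant_down = fc <= 1 / fc_thresh & p < p_thresh,
    row.names = NULL)
  attr(out, "reference") <- reference
  attr(out, "other") <- other
  attr(out, "fc_thresh") <- fc_thresh
  attr(out, "p_thresh") <- p_thresh
  class(out) <- c("volcano_result", "data.frame")
  out
}

#' Hierarchical cluster analysis on Pearson dissimilarities
#'
#' Computes `d = 1 - r` (Pearson correlation between item profiles) over the
#' chosen axis and clusters agglomeratively with the Ward criterion applied
#' directly to these unsquared dissimilarities (`hclust` method `"ward.D"`),
#' so merge heights are reproducible across implementations.
#'
#' @param table A preprocessed `feature_table` (or any feature table with at
#'   least 2 items on the chosen axis).
#' @param axis `"samples"` (cluster rows) or `"features"` (cluster columns).
#' @return An `hca_result` with the `hclust` tree (`tree`), the axis, item
#'   labels, and the distance tag `"1 - pearson"`.
#' @export
hca <- function(table, axis = c("samples", "features")) {
  stopifnot(inherits(table, "feature_table"))
  axis <- match.arg(axis)
  profiles <- if (axis == "samples") t(table$values) else table$values
  labels <- if (axis == "samples") table$samples else table$features
  if (ncol(profiles) < 2L)
    stop("need at least 2 ", axis, " to cluster")
  sdev <- apply(profiles, 2L, stats::sd)
  if (any(sdev == 0))
    stop("zero-variance item(s) have undefined correlation: ",
         paste(labels[sdev == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(profiles))
  tree <- stats::hclust(d, method = "ward.D")
  tree$labels <- labels
  structure(
    list(tree = tree, axis = axis, labels = labels,
         distance = "1 - pearson"),
    class = "hca_result")
}

#' @export
print.hca_result <- function(x, ...) {
  cat(sprintf("<hca_result> %d %s, %s distance, Ward linkage\n",
              length(x$labels), x$axis, x$distance))
  invisible(x)
}

#' Cut a cluster tree into k groups
#' @param hca_res An `hca_result`.
#' @param k Number of clusters.
#' @return Integer cluster labels named by item.
#' @export
cut_tree <- function(hca_res, k) {
  stopifnot(inherits(hca_res, "hca_result"))
  stats::cutree(hca_res$tree, k = k)
}

#' Run the automatic two-group analysis over a bin matrix
#'
#' Executes the full chain — IQR filter, sum normalization, log2,
#' autoscaling — then PCA, volcano analysis and sample-axis HCA, and writes
#' every result as CSV plus PNG plots. With a single group the volcano stage
#' is skipped with a message; PCA and HCA still run.
#'
#' @param matrix A `bin_matrix` (or `feature_table`) with group labels.
#' @param out_dir Output directory, created if needed.
#' @param filter Apply the IQR filter (default `TRUE`).
#' @param fc_thresh,p_thresh Volcano thresholds (defaults 4 and 1e-10).
#' @param n_components PCA components to keep (default 2).
#' @param reference Fold-change numerator group (default: first label).
#' @return A manifest list: `csv` and `png` output paths, and `results`
#'   holding the `processed` table, `pca`, `volcano` (or `NULL`) and `hca`
#'   objects.
#' @export
run_group_analysis <- function(matrix, out_dir, filter = TRUE, fc_thresh = 4,
                               p_thresh = 1e-10, n_components = 2L,
                               reference = NULL) {
  table <- if (inherits(matrix, "bin_matrix")) as_feature_table(matrix)
           else matrix
  stopifnot(inherits(table, "feature_table"))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  chain <- preprocess_chain(table, filter = filter)
  processed <- chain$processed
  n_components <- min(n_components,
                      nrow(processed$values) - 1L, ncol(processed$values))
  pca_res <- pca(processed, n_components = n_components)
  two_groups <- length(unique(table$groups)) == 2L
  volcano_res <- NULL
  if (two_groups) {
    volcano_res <- volcano(chain$normalized, processed,
                           reference = reference, fc_thresh = fc_thresh,
                           p_thresh = p_thresh)
  } else {
    message("volcano analysis skipped: requires exactly two groups")
  }
  hca_res <- hca(processed, axis = "samples")

  csv <- character()
  png <- character()
  p <- function(f) file.path(out_dir, f)

  feat_df <- data.frame(sample = processed$samples, group = processed$groups,
                        check.names = FALSE)
  vals <- as.data.frame(processed$values)
  colnames(vals) <- processed$features
  csv["features"] <- write_csv_plain(cbind(feat_df, vals),
                                     p("processed_features.csv"))
  csv["scores"] <- write_csv_plain(
    data.frame(sample = pca_res$samples, group = processed$groups,
               pca_res$scores, check.names = FALSE),
    p("pca_scores.csv"))
  csv["loadings"] <- write_csv_plain(
    data.frame(feature = pca_res$features, pca_res$loadings,
               check.names = FALSE),
    p("pca_loadings.csv"))
  if (!is.null(volcano_res))
    csv["volcano"] <- write_csv_plain(as.data.frame(volcano_res),
                                      p("volcano.csv"))
  csv["linkage"] <- write_csv_plain(
    data.frame(step = seq_along(hca_res$tree$height),
               left = hca_res$tree$merge[, 1L],
               right = hca_res$tree$merge[, 2L],
               height = hca_res$tree$height),
    p("hca_linkage.csv"))

  png["scores"] <- plot_png(p("pca_scores.png"), function()
    plot_pca_scores(pca_res, processed$groups))
  if (!is.null(volcano_res))
    png["volcano"] <- plot_png(p("volcano.png"), function()
      plot_volcano(volcano_res))
  png["dendrogram"] <- plot_png(p("dendrogram.png"), function()
    plot_dendrogram(hca_res, processed$groups))

  list(csv = csv, png = png,
       results = list(processed = processed, normalized = chain$normalized,
                      pca = pca_res, volcano = volcano_res, hca = hca_res))
}
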