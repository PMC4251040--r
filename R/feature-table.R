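#' @title Feature tables and the chemometric preprocessing chain
#' @description
#' A `feature_table` is a samples-by-features matrix with group labels and a
#' provenance record of which preprocessing steps have been applied. The
#' chain is strictly ordered — interquartile-range filtering on raw totals,
#' sum normalization to the sample total, log2 transformation with a
#' pseudocount, then per-feature autoscaling — and each step refuses to run
#' twice or out of order, so a table's provenance flags always describe its
#' values.
#' @name feature-table
NULL

.step_order <- c("filtered", "normalized", "log2", "autoscaled")

#' Construct a feature table
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#'   Non-negative before transformation.
#' @param samples Character vector of sample names (rows).
#' @param groups Character vector of group labels, one per sample.
#' @param features Character vector of feature labels (columns).
#' @param steps Character vector of already-applied steps, in order; normally
#'   empty.
#' @return A `feature_table`.
#' @export
feature_table <- function(values, samples = NULL, groups = NULL,
                          features = NULL, steps = character()) {
  values <- as.matrix(values)
  if (is.null(samples))
    samples <- rownames(values) %||% paste0("sample", seq_len(nrow(values)))
  if (is.null(features))
    features <- colnames(values) %||% paste0("feature", seq_len(ncol(values)))
  if (is.null(groups))
    groups <- rep(NA_character_, nrow(values))
  stopifnot(length(samples) == nrow(values),
            length(groups) == nrow(values),
            length(features) == ncol(values))
  bad <- match(steps, .step_order)
  if (anyNA(bad) || is.unsorted(bad))
    stop("steps must be a prefix-free ordered subset of: ",
         paste(.step_order, collapse = ", "))
  dimnames(values) <- NULL
  structure(
    list(values = values, samples = as.character(samples),
         groups = as.character(groups), features = as.character(features),
         steps = steps),
    class = "feature_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a bin matrix to a feature table
#' @param matrix A `bin_matrix`.
#' @return A `feature_table` with `lo_hi` bin labels as features.
#' @export
as_feature_table <- function(matrix) {
  stopifnot(inherits(matrix, "bin_matrix"))
  feature_table(values = matrix$values, samples = matrix$samples,
                groups = matrix$groups, features = bin_labels(matrix$grid))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features; steps: %s\n",
              nrow(x$values), ncol(x$values),
              if (length(x$steps)) paste(x$steps, collapse = " -> ")
              else "(raw)"))
  invisible(x)
}

# Enforce the filter -> normalize -> log2 -> autoscale ordering.
check_step <- function(table, step) {
  stopifnot(inherits(table, "feature_table"))
  if (step %in% table$steps)
    stop("step '", step, "' has already been applied to this table")
  pos <- match(step, .step_order)
  later <- intersect(table$steps, .step_order[seq_along(.step_order) > pos])
  if (length(later) > 0L)
    stop("cannot apply '", step, "' after '", later[1L],
         "': the preprocessing order is ",
         paste(.step_order, collapse = " -> "))
  invisible(TRUE)
}

#' Fraction of features removed by the IQR filter, by feature count
#'
#' Low-variance features are pruned more aggressively the larger the table:
#' 5\% up to 250 features, 10\% up to 500, 25\% up to 1000, 40\% above. A
#' 700-bin table therefore loses a quarter of its variables, most of which
#' hold only baseline signal at the extremes of the mass range.
#'
#' @param n_features Number of features before filtering.
#' @return The removal fraction.
#' @export
iqr_filter_fraction <- function(n_features) {
  if (n_features <= 250) 0.05
  else if (n_features <= 500) 0.10
  else if (n_features <= 1000) 0.25
  else 0.40
}

#' Interquartile-range filter
#'
#' Ranks features by their IQR across samples and removes the lowest-IQR
#' fraction given by [iqr_filter_fraction()]; the removal count is
#' `floor(fraction * n_features)`. Ties keep the later (higher-m/z) feature,
#' i.e. among tied IQRs the earlier feature is removed first.
#'
#' @param table A raw `feature_table` (not yet filtered).
#' @return The filtered table, with step `"filtered"` recorded.
#' @export
iqr_filter <- function(table) {
  check_step(table, "filtered")
  n <- ncol(table$values)
  n_remove <- floor(iqr_filter_fraction(n) * n)
  if (n_remove > 0L) {
    iqr <- apply(table$values, 2L, stats::IQR)
    drop_idx <- order(iqr, seq_len(n))[seq_len(n_remove)]
    keep <- setdiff(seq_len(n), drop_idx)
  } else {
    keep <- seq_len(n)
  }
  feature_table(values = table$values[, keep, drop = FALSE],
                samples = table$samples, groups = table$groups,
                features = table$features[keep],
                steps = c(table$steps, "filtered"))
}

#' Sum normalization
#'
#' Divides each sample's features by the sample total, so rows sum to 1. This
#' puts samples of different overall signal (e.g. tissue mass) on a common
#' scale; note that a strong one-sided signal inflates its sample totals and
#' thus depresses every other normalized feature in that group.
#'
#' @param table A `feature_table` with non-negative values and positive row
#'   totals.
#' @return The normalized table, rows on the unit simplex.
#' @export
sum_normalize <- function(table) {
  check_step(table, "normalized")
  if (any(table$values < 0))
    stop("sum normalization requires non-negative values")
  totals <- rowSums(table$values)
  if (any(totals <= 0))
    stop("sample(s) with zero total signal cannot be normalized: ",
         paste(table$samples[totals <= 0], collapse = ", "))
  feature_table(values = table$values / totals, samples = table$samples,
                groups = table$groups, features = table$features,
                steps = c(table$steps, "normalized"))
}

#' Log2 transformation with pseudocount
#'
#' Applies `x -> log2(x + c)` with `c` equal to half the smallest positive
#' value in the table. The pseudocount keeps zero entries finite (binned
#' variables are usually strictly positive, but filtered or synthetic tables
#' can contain zeros) while preserving the ordering of every row.
#'
#' @param table A sum-normalized `feature_table`.
#' @return The transformed table, with the pseudocount stored as attribute
#'   `pseudocount`.
#' @export
log2_transform <- function(table) {
  check_step(table, "log2")
  if (!"normalized" %in% table$steps)
    stop("log2_transform expects a sum-normalized table")
  if (any(table$values < 0))
    stop("log2 transformation requires non-negative values")
  pos <- table$values[table$values > 0]
  if (length(pos) == 0L)
    stop("the table has no positive values")
  pc <- min(pos) / 2
  out <- feature_table(values = log2(table$values + pc),
                       samples = table$samples, groups = table$groups,
                       features = table$features,
                       steps = c(table$steps, "log2"))
  attr(out, "pseudocount") <- pc
  out
}

#' Per-feature autoscaling
#'
#' Centers each feature (column) to mean 0 and scales it to unit sample
#' standard deviation (n - 1 denominator), so every feature contributes
#' comparably to downstream PCA and clustering. Constant columns cannot be
#' scaled and are set to all-zero with a warning.
#'
#' @param table A log2-transformed `feature_table`.
#' @return The autoscaled table.
#' @export
autoscale <- function(table) {
  check_step(table, "autoscaled")
  if (!"log2" %in% table$steps)
    stop("autoscale expects a log2-transformed table")
  mu <- colMeans(table$values)
  sdev <- apply(table$values, 2L, stats::sd)
  const <- sdev == 0 | is.na(sdev)
  if (any(const))
    warning(sum(const), " constant feature(s) set to zero during autoscaling")
  sdev[const] <- 1
  values <- sweep(sweep(table$values, 2L, mu), 2L, sdev, "/")
  values[, const] <- 0
  feature_table(values = values, samples = table$samples,
                groups = table$groups, features = table$features,
                steps = c(table$steps, "autoscaled"))
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper applying [iqr_filter()] (optional), [sum_normalize()],
#' [log2_transform()] and [autoscale()] in order.
#'
#' @param table A raw `feature_table`.
#' @param filter Apply the IQR filter first? Default `TRUE`.
#' @return A list with `normalized` (the sum-normalized table, used for fold
#'   changes) and `processed` (the fully transformed table, used for PCA,
#'   t-tests and clustering).
#' @export
preprocess_chain <- function(table, filter = TRUE) {
  if (filter)
    table <- iqr_filter(table)
  normalized <- sum_normalize(table)
  processed <- autoscale(log2_transform(normalized))
  list(normalized = normalized, processed = processed)
}
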