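# Shared fixtures, built in code at test time.

# Two-scan toy run: scan1 rt=6 s, mz 100/200, int 10/30; scan2 rt=12 s,
# mz 150, int 5.
fixture_run <- function() {
  new_run(list(
    new_scan(rt = 6, mz = c(100, 200), intensity = c(10, 30)),
    new_scan(rt = 12, mz = 150, intensity = 5)
  ), source_name = "fixture")
}

# One small default-parameter two-group study per session, reused by the
# module tests that only need a realistic multi-sample dataset.
study_cache <- new.env(parent = emptyenv())
cached_study <- function() {
  if (is.null(study_cache$study)) {
    study <- simulate_two_group_study(seed = 7L)
    mat <- suppressMessages(group_bin(study$runs, study$truth$grid,
                                      study$groups))
    study_cache$study <- list(
      study = study,
      matrix = mat,
      spiked_labels = bin_labels(study$truth$grid)[study$truth$spiked_bins],
      chain = preprocess_chain(as_feature_table(mat)))
  }
  study_cache$study
}

# Textbook Welch two-sample test: statistic, Welch-Satterthwaite df,
# two-sided p. Independent of stats::t.test.
welch_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v1 <- sum((a - mean(a))^2) / (n1 - 1)
  v2 <- sum((b - mean(b))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * stats::pt(-abs(t), df)
}

# Brute-force PCA oracle: eigendecomposition of the sample covariance.
pca_oracle <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  eg <- eigen(stats::cov(xc), symmetric = TRUE)
  k <- min(nrow(x) - 1L, ncol(x))
  scores <- xc %*% eg$vectors[, seq_len(k), drop = FALSE]
  list(scores = scores,
       explained = eg$values[seq_len(k)] / sum(pmax(eg$values, 0)))
}

# All three pairings of 4 items; returns the one minimizing total
# within-pair 1 - Pearson dissimilarity, as two index pairs.
best_pairing_oracle <- function(profiles) {
  d <- 1 - stats::cor(profiles)
  pairings <- list(list(c(1, 2), c(3, 4)), list(c(1, 3), c(2, 4)),
                   list(c(1, 4), c(2, 3)))
  cost <- vapply(pairings, function(p)
    d[p[[1]][1], p[[1]][2]] + d[p[[2]][1], p[[2]][2]], numeric(1))
  pairings[[which.min(cost)]]
}

two_means_accuracy <- function(scores_pc1, groups) {
  km <- stats::kmeans(scores_pc1, centers = 2, nstart = 10)
  g <- groups == groups[1L]
  max(mean((km$cluster == 1) == g), mean((km$cluster == 2) == g))
}
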