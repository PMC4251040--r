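# PCA, loadings, volcano and HCA, each checked against an independent oracle.

test_that("PCA matches a brute-force covariance eigendecomposition", {
  set.seed(31)
  for (dims in list(c(5, 3), c(8, 8), c(10, 10), c(6, 10))) {
    x <- matrix(rnorm(prod(dims)), nrow = dims[1])
    res <- pca(x)
    oracle <- pca_oracle(x)
    k <- ncol(res$scores)
    expect_equal(res$explained, oracle$explained[seq_len(k)],
                 tolerance = 1e-8)
    for (j in seq_len(k)) {
      if (res$explained[j] < 1e-12) next
      expect_equal(abs(res$scores[, j]), abs(oracle$scores[, j]),
                   tolerance = 1e-6, ignore_attr = TRUE)
    }
  }
})

test_that("PCA is complete, sign-fixed and dimension-checked", {
  set.seed(32)
  x <- matrix(rnorm(7 * 5), nrow = 7)
  res <- pca(x)
  centered <- sweep(x, 2, colMeans(x))
  expect_equal(res$scores %*% t(res$loadings), centered,
               tolerance = 1e-8, ignore_attr = TRUE)
  # scores columns are mutually orthogonal
  gram <- crossprod(res$scores)
  off <- gram - diag(diag(gram))
  expect_lt(max(abs(off)), 1e-6 * max(diag(gram)))
  # largest-|loading| entry of each component is positive
  for (j in seq_len(ncol(res$loadings)))
    expect_gt(res$loadings[which.max(abs(res$loadings[, j])), j], 0)
  # two samples lie on a line
  expect_equal(pca(matrix(rnorm(2 * 6), nrow = 2))$explained[1], 1)
  expect_error(pca(x, n_components = 7), "n_components")
})

test_that("top_loadings ranks by absolute loading and caps k", {
  res <- structure(
    list(loadings = matrix(c(0.9, -0.95, 0.1), ncol = 1,
                           dimnames = list(NULL, "PC1")),
         scores = matrix(0, 3, 1), explained = 1,
         samples = "s", features = c("f1", "f2", "f3")),
    class = "pca_result")
  top <- top_loadings(res, 1, k = 2)
  expect_equal(top$feature, c("f2", "f1"))
  expect_equal(top_loadings(res, 1, k = 10)$feature, c("f2", "f1", "f3"))
  expect_error(top_loadings(res, 3), "does not exist")
})

test_that("Welch p-values match the textbook statistic to 1e-10", {
  set.seed(33)
  cases <- c(
    lapply(1:10, function(i) list(a = rnorm(sample(3:6, 1)),
                                  b = rnorm(sample(3:6, 1), sd = 2))),
    list(list(a = c(1, 2, 3), b = c(1.5, 2.5, 3.5, 10)),
         list(a = c(8, 8.1), b = c(2, 2.2, 1.9))))
  for (cs in cases) {
    p_pkg <- mzbin:::welch_p(cs$a, cs$b)
    expect_equal(p_pkg, welch_oracle(cs$a, cs$b), tolerance = 1e-10)
  }
})

test_that("volcano combines normalized fold change with transformed-scale p", {
  groups <- rep(c("A", "B"), each = 3)
  norm_vals <- cbind(c(8, 8, 8, 2, 2, 2),      # FC 4
                     c(1, 1.1, 0.9, 1, 1.05, 0.95), # FC ~1
                     c(0.5, 0.6, 0.55, 2.3, 2.2, 2.4)) # FC ~0.24
  norm <- feature_table(norm_vals, groups = groups,
                        features = c("up4", "flat", "down4"),
                        steps = c("normalized"))
  trans <- feature_table(log2(norm_vals), groups = groups,
                         features = norm$features,
                         steps = c("normalized", "log2"))
  res <- volcano(norm, trans, fc_thresh = 4, p_thresh = 0.05)
  expect_equal(res$fold_change[1], 4)
  expect_equal(res$fold_change[2], 1, tolerance = 0.05)
  expect_true(res$significant_up[1])
  expect_false(res$significant_up[2] || res$significant_down[2])
  expect_true(res$significant_down[3])

  # identical groups: FC 1, p ~ 1
  same <- feature_table(matrix(rep(c(1, 2, 1, 2), 3), nrow = 4),
                        groups = c("A", "A", "B", "B"),
                        steps = "normalized")
  res2 <- volcano(same, same)
  expect_equal(res2$fold_change, rep(1, 3))
  expect_true(all(res2$p_value > 0.9))
  expect_false(any(res2$significant_up | res2$significant_down))

  one_group <- feature_table(matrix(1:4, 2), groups = c("A", "A"))
  expect_error(volcano(one_group, one_group), "two groups")
})

test_that("zero denominator means are reported as infinite fold change", {
  groups <- rep(c("A", "B"), each = 2)
  vals <- cbind(c(1, 1, 0, 0), c(1, 2, 3, 4))
  norm <- feature_table(vals, groups = groups, steps = "normalized")
  res <- volcano(norm, norm, fc_thresh = 4, p_thresh = 0.05)
  expect_true(is.infinite(res$fold_change[1]))
  expect_true(res$infinite_fc[1])
  expect_false(res$significant_up[1])
})

test_that("HCA on 1 - Pearson with Ward linkage passes the small oracles", {
  # perfectly correlated pair merges at height 0
  tab <- feature_table(cbind(c(1, 2), c(2, 4), c(3, 6)),
                       samples = c("s1", "s2"))
  h <- hca(tab, axis = "samples")
  expect_equal(length(h$tree$height), 1L)
  expect_equal(h$tree$height, 0, tolerance = 1e-12)

  # two orthogonal pairs: the k=2 cut recovers the best pairing by
  # enumeration
  set.seed(34)
  base1 <- rnorm(20)
  base2 <- rnorm(20)
  profiles <- cbind(base1 + rnorm(20, sd = 0.1),
                    base1 + rnorm(20, sd = 0.1),
                    base2 + rnorm(20, sd = 0.1),
                    base2 + rnorm(20, sd = 0.1))
  tab4 <- feature_table(t(profiles),
                        samples = paste0("s", 1:4))
  cut <- cut_tree(hca(tab4, axis = "samples"), 2)
  oracle <- best_pairing_oracle(profiles)
  expect_equal(cut[oracle[[1]][1]], cut[oracle[[1]][2]],
               ignore_attr = TRUE)
  expect_equal(cut[oracle[[2]][1]], cut[oracle[[2]][2]],
               ignore_attr = TRUE)
  expect_true(cut[oracle[[1]][1]] != cut[oracle[[2]][1]])

  # merge heights are non-decreasing
  expect_true(!is.unsorted(hca(tab4, "samples")$tree$height))

  flat <- feature_table(rbind(c(1, 1, 1), c(1, 2, 3)),
                        samples = c("flat", "ok"))
  expect_error(hca(flat, "samples"), "flat")
})

test_that("the synthetic study resolves groups and discriminatory bins", {
  cs <- cached_study()
  processed <- cs$chain$processed
  groups <- processed$groups

  pr <- pca(processed, n_components = 2)
  # orient PC1 by the group-mean score difference, then signs match groups
  s1 <- pr$scores[, 1]
  if (mean(s1[groups == "A"]) < mean(s1[groups == "B"])) s1 <- -s1
  expect_true(all(sign(s1[groups == "A"]) == 1))
  expect_true(all(sign(s1[groups == "B"]) == -1))

  # >= 80% of the spiked bins appear among the top 30 PC1 loadings
  top <- top_loadings(pr, 1, 30, table = processed)
  expect_gte(sum(top$feature %in% cs$spiked_labels), 8)

  # k=2 HCA cut reproduces the design labels
  cut <- cut_tree(hca(processed, "samples"), 2)
  expect_true(all(table(cut, groups) %in% c(0, 12, 11)))
})

test_that("stronger spikes never lose PC1 loading rank", {
  ranks <- vapply(c(2, 4, 8), function(f) {
    study <- simulate_two_group_study(seed = 77L,
                                      effect_fold = c(f, rep(8, 9)))
    mat <- suppressMessages(group_bin(study$runs, study$truth$grid,
                                      study$groups))
    chain <- preprocess_chain(as_feature_table(mat))
    pr <- pca(chain$processed, n_components = 1)
    label <- bin_labels(study$truth$grid)[study$truth$spiked_bins[1]]
    idx <- match(label, chain$processed$features)
    rank_of <- rank(-abs(pr$loadings[, 1]))[idx]
    rank_of
  }, numeric(1))
  expect_true(all(diff(ranks) <= 0))
})

test_that("run_group_analysis reproduces the manual stage-by-stage chain", {
  cs <- cached_study()
  out <- withr::local_tempdir()
  manifest <- run_group_analysis(cs$matrix, out_dir = out)
  expect_length(manifest$csv, 5L)
  expect_length(manifest$png, 3L)
  expect_true(all(file.exists(manifest$csv)))
  expect_true(all(file.exists(manifest$png)))

  chain <- cs$chain
  expect_equal(manifest$results$processed$values, chain$processed$values)
  man_pca <- pca(chain$processed, n_components = 2)
  expect_equal(manifest$results$pca$scores, man_pca$scores)
  man_volc <- volcano(chain$normalized, chain$processed)
  expect_equal(manifest$results$volcano$p_value, man_volc$p_value)
  expect_equal(manifest$results$hca$tree$height,
               hca(chain$processed, "samples")$tree$height)
})

test_that("single-group analyses skip the volcano stage but still run", {
  cs <- cached_study()
  mono <- cs$matrix
  mono$groups <- rep("only", length(mono$groups))
  out <- withr::local_tempdir()
  expect_message(manifest <- run_group_analysis(mono, out_dir = out),
                 "skipped")
  expect_null(manifest$results$volcano)
  expect_length(manifest$csv, 4L)
  expect_length(manifest$png, 2L)
  expect_s3_class(manifest$results$pca, "pca_result")
  expect_s3_class(manifest$results$hca, "hca_result")
})
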