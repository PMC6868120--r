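test_that("ROC metrics match closed forms and an independent AUC oracle", {
  expect_equal(roc_metrics(1:10, rep(c("a", "b"), each = 5),
                           positive = "b")$auc, 1.0)
  expect_equal(roc_metrics(10:1, rep(c("a", "b"), each = 5),
                           positive = "b")$auc, 0.0)
  set.seed(9)
  d <- rnorm(2000)
  lab <- rep(c("a", "b"), 1000)
  expect_equal(roc_metrics(d, lab, positive = "b")$auc, 0.5, tolerance = 0.06)
  # invariance under strictly increasing transforms
  d2 <- rnorm(60)
  lab2 <- rep(c("a", "b"), 30)
  expect_equal(roc_metrics(exp(d2), lab2)$auc, roc_metrics(d2, lab2)$auc)
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(lab2, d2, levels = c("a", "b"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(roc_metrics(d2, lab2, positive = "b")$auc, ref,
               tolerance = 1e-12)
  expect_warning(r0 <- roc_metrics(rep(1, 10), rep(c("a", "b"), 5)),
                 "constant")
  expect_equal(r0$auc, 0.5)
})

test_that("rate identity links accuracy, sensitivity and specificity", {
  set.seed(3)
  d <- rnorm(50)
  lab <- sample(rep(c("a", "b"), 25))
  m <- roc_metrics(d, lab, positive = "b")
  n_pos <- sum(lab == "b")
  n_neg <- sum(lab == "a")
  expect_equal(m$accuracy_pct,
               (m$sensitivity_pct * n_pos + m$specificity_pct * n_neg) /
                 (n_pos + n_neg))
})

test_that("PCA reduction respects rank and variance targets", {
  set.seed(11)
  one_d <- matrix(rnorm(20), 20, 1)
  expect_equal(pca_reduce(one_d)$n_components, 1)
  base <- matrix(rnorm(40), 20, 2)
  rank2 <- base %*% matrix(rnorm(2 * 30), 2)   # 30 features, rank 2
  expect_lte(pca_reduce(rank2, variance_kept = 1)$n_components, 2)
  x <- matrix(rnorm(20 * 100), 20)
  fit <- pca_reduce(x, variance_kept = 0.9)
  # reconstruction error decreases monotonically with components kept
  errs <- sapply(seq_len(10), function(k) {
    pr <- prcomp(x)
    recon <- pr$x[, 1:k, drop = FALSE] %*% t(pr$rotation[, 1:k, drop = FALSE])
    sum((sweep(x, 2, colMeans(x)) - recon)^2)
  })
  expect_true(all(diff(errs) < 0))
  # projection learned on one set applies to another without refitting
  newx <- matrix(rnorm(5 * 100), 5)
  proj <- pca_reduce(newx, fit = fit)
  expect_equal(ncol(proj$scores), fit$n_components)
  expect_equal(proj$scores, sweep(newx, 2, fit$center) %*% fit$rotation)
})

test_that("relief weighting finds planted features and is null-centred", {
  set.seed(21)
  x <- matrix(rnorm(40 * 50), 40)
  lab <- factor(rep(c("a", "b"), each = 20))
  x[lab == "b", 7] <- x[lab == "b", 7] + 4
  w <- relief_weights(x, lab, k_neighbors = 5)
  expect_equal(which.max(w), 7L)
  sel <- relief_select(x, lab, k_keep = 5)
  expect_true(7 %in% attr(sel, "selected"))
  expect_equal(ncol(sel$matrix), 5)
  # identity selection
  all_sel <- relief_select(x, lab, k_keep = 50)
  expect_equal(attr(all_sel, "selected"), 1:50)
  expect_error(relief_select(x, lab, k_keep = 51), "exceeds")
  # shuffled labels: weights centred near zero
  w0 <- relief_weights(x, sample(lab), k_neighbors = 5)
  expect_lt(abs(mean(w0)), 0.05)
  expect_lt(max(abs(w0)), max(w))
})

test_that("SVM-RFE ranks informative features first with indexed tie-breaks", {
  set.seed(31)
  lab <- factor(rep(c("a", "b"), each = 15))
  x <- cbind(ifelse(lab == "b", 1, -1) + rnorm(30, sd = 0.3), rnorm(30))
  rk <- svm_rfe_rank(x, lab)
  expect_equal(rk[1], 1L)
  # duplicated columns: exactly tied weights, higher index eliminated first
  xd <- cbind(x[, 1], x[, 1], x[, 1])
  rkd <- svm_rfe_rank(xd, lab, elimination_fraction = 0.3)
  expect_equal(rkd, c(1L, 2L, 3L))
  # ranking is always a permutation
  x2 <- matrix(rnorm(30 * 23), 30)
  expect_setequal(svm_rfe_rank(x2, lab), 1:23)
  expect_error(svm_rfe_rank(matrix(c(1, NA), 2), factor(c("a", "b"))),
               "finite")
})

test_that("nested CV separates a separable cohort and not a shuffled one", {
  ft <- make_separable_features(n_per_group = 20, p = 60, planted = 5,
                                shift = 3, seed = 41)
  rep1 <- nested_cv_classify(ft, seed = 42)
  expect_gte(rep1$auc, 0.95)
  expect_gte(rep1$accuracy_pct, 90)
  # pooled-record rate identity at the zero threshold
  n_pos <- sum(ft$labels == "substate_B") * 5
  n_neg <- sum(ft$labels == "substate_A") * 5
  expect_equal(rep1$accuracy_pct,
               (rep1$sensitivity_pct * n_pos + rep1$specificity_pct * n_neg) /
                 (n_pos + n_neg))

  shuffled <- gcdmap:::with_seed(43, sample(ft$labels))
  rep0 <- nested_cv_classify(ft$matrix, shuffled, seed = 44)
  expect_gte(rep0$accuracy_pct, 35)
  expect_lte(rep0$accuracy_pct, 65)
})

test_that("metric combinations can beat the best single metric", {
  # inflow and outflow carry independent halves of the signal
  set.seed(51)
  n <- 40
  lab <- factor(rep(c("substate_A", "substate_B"), each = n / 2))
  nv <- 30
  mk_block <- function(shift_cols) {
    m <- matrix(rnorm(n * nv), n)
    m[lab == "substate_B", shift_cols] <- m[lab == "substate_B", shift_cols] + 1.2
    m
  }
  inflow_block <- mk_block(1:3)
  outflow_block <- mk_block(4:6)
  ft_in <- feature_table(inflow_block, lab)
  ft_out <- feature_table(outflow_block, lab)
  ft_both <- feature_table(cbind(inflow_block, outflow_block), lab,
                           data.frame(metric = rep(c("inflow", "outflow"),
                                                   each = nv),
                                      voxel = rep(1:nv, 2)))
  auc_in <- nested_cv_classify(ft_in, seed = 52)$auc
  auc_out <- nested_cv_classify(ft_out, seed = 52)$auc
  auc_both <- nested_cv_classify(ft_both, seed = 52)$auc
  expect_gte(auc_both, max(auc_in, auc_out) - 0.02)
  # combination subsetting drops foreign metrics
  rep_in <- nested_cv_classify(ft_both, combination = "inflow", seed = 52)
  expect_error(nested_cv_classify(ft_both, combination = "totalflow"),
               "combination matches no features")
  expect_s3_class(rep_in, "classifier_report")
})

test_that("per-voxel accuracy maps hit chance, ceiling and cluster rules", {
  set.seed(61)
  n <- 20
  lab <- factor(rep(c("substate_A", "substate_B"), each = 10))
  nv <- 27
  idx <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  feat <- matrix(rnorm(n * nv), n)
  # voxels 1..6 perfectly separated: +/-3 with sd 0.1 -> a 6-voxel cluster
  for (j in 1:6) feat[, j] <- ifelse(lab == "substate_B", 3, -3) +
    rnorm(n, sd = 0.1)
  am <- voxelwise_accuracy_map(feat, lab, idx, c(3, 3, 3),
                               threshold_pct = 70, min_extent = 5)
  expect_equal(am$accuracy_pct[1:6], rep(100, 6))
  expect_true(mean(am$accuracy_pct[7:27]) < 75)   # noise voxels near chance
  expect_gte(length(am$clusters), 1)
  expect_true(any(sapply(am$clusters, function(cl) all(1:6 %in% cl$voxels))))
  expect_true(all(sapply(am$clusters, `[[`, "size") >= 5))
  expect_true(all(am$accuracy_pct[unlist(lapply(am$clusters, `[[`,
                                                "voxels"))] > 70))

  # identical feature across classes stays near chance and is not reported
  flat <- matrix(rep(rnorm(n), nv), n)
  am0 <- voxelwise_accuracy_map(flat, lab, idx, c(3, 3, 3))
  expect_true(all(am0$accuracy_pct <= 70))

  # 4 contiguous supra-threshold voxels do not form a reportable cluster
  feat4 <- matrix(rnorm(n * nv), n)
  for (j in c(1, 2, 4, 5)) feat4[, j] <- ifelse(lab == "substate_B", 3, -3)
  am4 <- voxelwise_accuracy_map(feat4, lab, idx, c(3, 3, 3), min_extent = 5)
  expect_length(am4$clusters, 0)
  expect_error(voxelwise_accuracy_map(feat, factor(rep("a", n)), idx,
                                      c(3, 3, 3)), "two classes")
})

test_that("connected components respect the chosen connectivity", {
  idx <- rbind(c(1, 1, 1), c(2, 2, 1), c(5, 5, 5))
  # diagonal in-plane neighbours: separate under 6, joined under 18
  c6 <- gcdmap:::cluster_components(1:3, idx, c(5, 5, 5), 6)
  c18 <- gcdmap:::cluster_components(1:3, idx, c(5, 5, 5), 18)
  expect_length(c6, 3)
  expect_length(c18, 2)
})

test_that("permutation test calibrates against separable and null cohorts", {
  ft <- make_separable_features(n_per_group = 10, p = 20, planted = 4,
                                shift = 4, seed = 71)
  res <- permutation_test(ft, n_perm = 100, seed = 72)
  expect_equal(res$permutation_p, 1 / 101)
  expect_equal(res$accuracy_pct, 100)
  expect_error(permutation_test(ft, n_perm = 0), "n_perm")

  noise <- feature_table(matrix(rnorm(20 * 20), 20),
                         factor(rep(c("a", "b"), 10)))
  res0 <- permutation_test(noise, n_perm = 19, seed = 73)
  expect_gt(res0$permutation_p, 0.05)
})

test_that("fold stratification fails loudly on tiny classes", {
  lab <- factor(c(rep("a", 10), rep("b", 3)))
  expect_error(gcdmap:::with_seed(1, gcdmap:::stratified_folds(lab, 5)),
               "stratification failure")
})
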