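#' Subjects-by-features table for classification
#'
#' @param matrix subjects x features numeric matrix.
#' @param labels per-subject two-level factor (both classes present).
#' @param feature_origin data.frame with one row per feature, columns
#'   `metric` and `voxel` (index into the map's voxel list).
#' @return A `feature_table` object.
#' @export
feature_table <- function(matrix, labels, feature_origin = NULL) {
  matrix <- as.matrix(matrix)
  labels <- as.factor(labels)
  if (nrow(matrix) != length(labels)) stop("one label per subject required")
  if (anyNA(matrix)) stop("feature table must not contain missing values")
  if (nlevels(droplevels(labels)) != 2L) stop("both classes must be present")
  if (is.null(feature_origin))
    feature_origin <- data.frame(metric = "feature",
                                 voxel = seq_len(ncol(matrix)))
  if (nrow(feature_origin) != ncol(matrix))
    stop("feature_origin must have one row per feature")
  structure(list(matrix = matrix, labels = droplevels(labels),
                 feature_origin = feature_origin),
            class = "feature_table")
}

#' Assemble a feature table from per-subject GCD maps
#'
#' Concatenates the requested density metrics voxel-wise across subjects, the
#' multivariate-pattern input of the combination classifier.
#'
#' @param maps_list named list of [gcd_maps()] objects, one per subject.
#' @param labels per-subject group factor, aligned with `maps_list`.
#' @param metrics subset of `c("inflow", "outflow", "total_flow", "int_flow")`.
#' @return A [feature_table()].
#' @export
gcd_feature_table <- function(maps_list, labels,
                              metrics = c("inflow", "outflow", "int_flow")) {
  stopifnot(length(maps_list) == length(labels))
  valid <- c("inflow", "outflow", "total_flow", "int_flow")
  if (!all(metrics %in% valid))
    stop("metrics must be among: ", paste(valid, collapse = ", "))
  blocks <- lapply(metrics, function(m)
    do.call(rbind, lapply(maps_list, `[[`, m)))
  nv <- ncol(blocks[[1]])
  feature_table(do.call(cbind, blocks), labels,
                data.frame(metric = rep(metrics, each = nv),
                           voxel = rep(seq_len(nv), length(metrics))))
}

# Stratified k-fold assignment; errors if a class cannot reach every fold.
stratified_folds <- function(labels, k) {
  labels <- as.factor(labels)
  if (min(table(labels)) < k)
    stop(sprintf(
      "stratification failure: smallest class has %d subjects for %d folds",
      min(table(labels)), k))
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

scale_fit <- function(x) {
  mu <- colMeans(x)
  sg <- apply(x, 2, sd)
  sg[sg < .Machine$double.eps] <- 1
  list(center = mu, scale = sg)
}

scale_apply <- function(x, s) sweep(sweep(x, 2, s$center), 2, s$scale, "/")

#' Per-voxel leave-one-out SVM accuracy map
#'
#' Each voxel's single density value is used as the sole feature of a linear
#' SVM (C = 1) scored by leave-one-out cross-validation; the resulting
#' accuracy map is thresholded and connected components (6-neighbourhood by
#' default) of at least `min_extent` supra-threshold voxels are reported with
#' their peak accuracy and peak coordinate.
#'
#' @param features subjects x voxels matrix of one GCD metric.
#' @param labels two-level factor, at least 4 subjects per class.
#' @param voxel_index voxels x 3 matrix of 1-based grid coordinates.
#' @param grid_dim length-3 grid dimensions.
#' @param threshold_pct reporting threshold in percent (default 70).
#' @param min_extent minimum cluster size in voxels (default 5).
#' @param connectivity 6, 18 or 26.
#' @param cost SVM soft-margin parameter.
#' @return An `accuracy_map`: list with `accuracy_pct`, `threshold_pct`,
#'   `min_extent`, and `clusters` (each with `voxels`, `size`,
#'   `peak_accuracy`, `peak_coord`).
#' @export
voxelwise_accuracy_map <- function(features, labels, voxel_index, grid_dim,
                                   threshold_pct = 70, min_extent = 5,
                                   connectivity = 6, cost = 1) {
  features <- as.matrix(features)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("labels must contain exactly two classes")
  if (min(table(labels)) < 4L) stop("need at least 4 subjects per class")
  n <- nrow(features)
  v <- ncol(features)
  acc <- numeric(v)
  for (j in seq_len(v)) {
    x <- features[, j]
    correct <- 0L
    for (i in seq_len(n)) {
      fit <- linear_svm(matrix(x[-i], ncol = 1), labels[-i], cost = cost)
      if (predict(fit, matrix(x[i], ncol = 1), type = "class") == labels[i])
        correct <- correct + 1L
    }
    acc[j] <- 100 * correct / n
  }
  supra <- which(acc > threshold_pct)
  comps <- cluster_components(supra, voxel_index, grid_dim, connectivity)
  clusters <- lapply(comps[vapply(comps, length, 1L) >= min_extent],
                     function(vox) {
                       peak <- vox[which.max(acc[vox])]
                       list(voxels = vox, size = length(vox),
                            peak_accuracy = acc[peak],
                            peak_coord = voxel_index[peak, ])
                     })
  structure(list(accuracy_pct = acc, threshold_pct = threshold_pct,
                 min_extent = min_extent, connectivity = connectivity,
                 clusters = clusters),
            class = "accuracy_map")
}

# Connected components of the given voxel rows under grid connectivity.
cluster_components <- function(rows, voxel_index, grid_dim, connectivity = 6) {
  if (!length(rows)) return(list())
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  nn <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6" = offs[nn == 1, ], "18" = offs[nn <= 2, ],
                 "26" = offs,
                 stop("connectivity must be 6, 18 or 26"))
  lin <- function(co) (co[, 3] - 1) * grid_dim[1] * grid_dim[2] +
    (co[, 2] - 1) * grid_dim[1] + co[, 1]
  coords <- voxel_index[rows, , drop = FALSE]
  lookup <- new.env(hash = TRUE, size = length(rows))
  keys <- as.character(lin(coords))
  for (i in seq_along(rows)) assign(keys[i], i, envir = lookup)
  seen <- logical(length(rows))
  comps <- list()
  for (start in seq_along(rows)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    member <- integer(0)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      member <- c(member, cur)
      nb <- sweep(as.matrix(offs), 2, coords[cur, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1 &
        nb[, 1] <= grid_dim[1] & nb[, 2] <= grid_dim[2] & nb[, 3] <= grid_dim[3]
      for (key in as.character(lin(nb[ok, , drop = FALSE]))) {
        hit <- mget(key, envir = lookup, ifnotfound = list(NULL))[[1]]
        if (!is.null(hit) && !seen[hit]) {
          seen[hit] <- TRUE
          queue <- c(queue, hit)
        }
      }
    }
    comps[[length(comps) + 1]] <- sort(rows[member])
  }
  comps
}

#' PCA dimension reduction
#'
#' Fits a principal-component projection on training subjects and keeps the
#' smallest number of components reaching `variance_kept`; inside
#' cross-validation the fit must come from the training fold only, so the
#' fitted projection is returned and can be applied to held-out subjects via
#' the `fit` argument.
#'
#' @param x subjects x features matrix to project.
#' @param variance_kept fraction of variance to retain, in (0, 1].
#' @param fit a previous `pca_reduce` result whose projection is re-applied.
#' @return List with `scores` (projected data), `rotation`, `center`,
#'   `n_components`, `variance_kept`.
#' @export
pca_reduce <- function(x, variance_kept = 0.95, fit = NULL) {
  x <- as.matrix(x)
  if (!is.null(fit)) {
    scores <- sweep(x, 2, fit$center) %*% fit$rotation
    return(list(scores = scores, rotation = fit$rotation, center = fit$center,
                n_components = fit$n_components,
                variance_kept = fit$variance_kept))
  }
  if (nrow(x) < 2L) stop("need at least 2 subjects to fit a projection")
  if (!(variance_kept > 0 && variance_kept <= 1))
    stop("variance_kept must be in (0, 1]")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- which(cumsum(ev) / sum(ev) >= variance_kept - 1e-12)[1]
  keep <- max(keep, 1L)
  rot <- pc$rotation[, seq_len(keep), drop = FALSE]
  list(scores = pc$x[, seq_len(keep), drop = FALSE], rotation = rot,
       center = pc$center, n_components = keep,
       variance_kept = variance_kept)
}

#' ReliefF feature weights and selection
#'
#' Nearest-neighbour feature weighting: a feature is rewarded when it
#' separates a subject from its `k` nearest other-class neighbours (misses)
#' more than from its `k` nearest same-class neighbours (hits). Distances and
#' differences are computed on standardized features; every subject acts as a
#' probe once, so the result is deterministic (ties broken by subject then
#' feature index).
#'
#' @param x subjects x features matrix.
#' @param labels two-level factor.
#' @param k_neighbors nearest hits/misses per probe (default 5).
#' @return `relief_weights`: numeric vector of per-feature weights.
#' @export
relief_weights <- function(x, labels, k_neighbors = 5) {
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("labels must contain exactly two classes")
  n <- nrow(x)
  s <- scale_fit(x)
  z <- scale_apply(x, s)
  d <- as.matrix(stats::dist(z, method = "manhattan"))
  w <- numeric(ncol(x))
  for (i in seq_len(n)) {
    same <- which(labels == labels[i] & seq_len(n) != i)
    diff <- which(labels != labels[i])
    kh <- min(k_neighbors, length(same))
    km <- min(k_neighbors, length(diff))
    if (kh < 1L || km < 1L) stop("each class needs at least 2 subjects")
    hits <- same[order(d[i, same], same)][seq_len(kh)]
    misses <- diff[order(d[i, diff], diff)][seq_len(km)]
    dh <- abs(sweep(z[hits, , drop = FALSE], 2, z[i, ]))
    dm <- abs(sweep(z[misses, , drop = FALSE], 2, z[i, ]))
    w <- w + colMeans(dm) - colMeans(dh)
  }
  w / n
}

#' @rdname relief_weights
#' @param features a [feature_table()] or plain matrix.
#' @param k_keep number of features to retain (ties broken by feature index).
#' @return `relief_select`: the reduced [feature_table()] with an attribute
#'   `selected` giving the retained column indices.
#' @export
relief_select <- function(features, labels = NULL, k_keep, k_neighbors = 5) {
  if (inherits(features, "feature_table")) {
    labels <- labels %||% features$labels
    x <- features$matrix
    origin <- features$feature_origin
  } else {
    x <- as.matrix(features)
    origin <- NULL
  }
  if (k_keep > ncol(x)) stop("k_keep exceeds the feature count")
  w <- relief_weights(x, labels, k_neighbors)
  sel <- sort(order(-w, seq_along(w))[seq_len(k_keep)])
  out <- feature_table(x[, sel, drop = FALSE], labels,
                       if (!is.null(origin)) origin[sel, , drop = FALSE])
  attr(out, "selected") <- sel
  attr(out, "weights") <- w
  out
}

#' SVM recursive feature elimination ranking
#'
#' Trains a linear SVM (C = 1 by default), removes the fraction of features
#' with the smallest squared weights, and repeats until one feature remains.
#' Ties are broken by feature index (the lower index survives longer).
#'
#' @param x subjects x features matrix, or a [feature_table()].
#' @param labels two-level factor (taken from the table if omitted).
#' @param elimination_fraction fraction removed per iteration (default 0.1,
#'   always at least one feature).
#' @param cost SVM soft-margin parameter.
#' @param positive label mapped to +1.
#' @return Integer vector: feature indices from most to least informative.
#' @export
svm_rfe_rank <- function(x, labels = NULL, elimination_fraction = 0.1,
                         cost = 1, positive = NULL) {
  if (inherits(x, "feature_table")) {
    labels <- labels %||% x$labels
    x <- x$matrix
  }
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("features must be finite")
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("labels must contain exactly two classes")
  positive <- positive %||% levels(labels)[2]
  ys <- ifelse(labels == positive, 1, -1)
  res <- cpp_svm_rfe(x, as.numeric(ys), cost, elimination_fraction,
                     matrix(0, 0, ncol(x)))
  res$ranking
}

# Sizes visited by the RFE sweep for p features (matches cpp_svm_rfe).
rfe_path_sizes <- function(p, frac) {
  sizes <- integer(0)
  while (p >= 1L) {
    sizes <- c(sizes, p)
    if (p == 1L) break
    p <- p - max(1L, min(as.integer(floor(frac * p)), p - 1L))
  }
  sizes
}

#' Nested cross-validated combination classifier
#'
#' The outer loop is stratified 5-fold cross-validation repeated `repeats`
#' times; within each outer training set an inner stratified cross-validation
#' chooses the SVM-RFE feature count that maximises inner accuracy (the
#' per-size accuracies are read off the held-out predictions made during each
#' inner elimination sweep). The selected size is then refitted by RFE on the
#' whole outer training set and scored on the outer test fold.
#' Standardization, elimination and size selection only ever see training
#' subjects. Accuracy, sensitivity and specificity are computed from the
#' pooled fold records at the zero-decision threshold; the AUC from the
#' pooled decision values.
#'
#' @param features a [feature_table()] (or plain matrix).
#' @param labels two-level factor (taken from the table if omitted).
#' @param combination optional character vector of GCD metric names; columns
#'   whose `feature_origin$metric` is outside the combination are dropped.
#' @param k_outer outer folds (default 5).
#' @param k_inner inner folds within each outer training set (default 4).
#' @param repeats outer repetitions (default 5).
#' @param cost SVM soft-margin parameter (default 1).
#' @param elimination_fraction RFE elimination fraction (default 0.1).
#' @param seed integer seed controlling all fold assignments.
#' @param positive label of the positive class (sensitivity is its recall);
#'   defaults to the second factor level.
#' @return A `classifier_report`: list with `auc`, `accuracy_pct`,
#'   `sensitivity_pct`, `specificity_pct`, `permutation_p` (`NA` until
#'   [permutation_test()] fills it), `n_features_selected` (median over
#'   folds), `fold_records` (one row per repeat x held-out subject), `seed`,
#'   `combination`.
#' @export
nested_cv_classify <- function(features, labels = NULL, combination = NULL,
                               k_outer = 5L, k_inner = 4L, repeats = 5L,
                               cost = 1, elimination_fraction = 0.1,
                               seed = 1L, positive = NULL) {
  if (inherits(features, "feature_table")) {
    labels <- labels %||% features$labels
    if (!is.null(combination)) {
      keep <- features$feature_origin$metric %in% combination
      if (!any(keep)) stop("combination matches no features")
      x <- features$matrix[, keep, drop = FALSE]
    } else x <- features$matrix
  } else {
    x <- as.matrix(features)
  }
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("labels must contain exactly two classes")
  positive <- positive %||% levels(labels)[2]
  ys <- ifelse(labels == positive, 1, -1)
  n <- nrow(x)
  p <- ncol(x)
  sizes <- rfe_path_sizes(p, elimination_fraction)
  rec <- list()
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold <- stratified_folds(labels, k_outer)
      for (k in seq_len(k_outer)) {
        test <- which(fold == k)
        train <- which(fold != k)
        # inner loop: per-size held-out accuracy, training data only
        inner_fold <- stratified_folds(labels[train], k_inner)
        correct <- numeric(length(sizes))
        for (ki in seq_len(k_inner)) {
          ite <- train[inner_fold == ki]
          itr <- train[inner_fold != ki]
          s <- scale_fit(x[itr, , drop = FALSE])
          res <- cpp_svm_rfe(scale_apply(x[itr, , drop = FALSE], s),
                             as.numeric(ys[itr]), cost, elimination_fraction,
                             scale_apply(x[ite, , drop = FALSE], s))
          pred <- sign(res$test_decisions)
          pred[pred == 0] <- -1
          correct <- correct +
            rowSums(pred == matrix(ys[ite], nrow(pred), length(ite),
                                   byrow = TRUE))
        }
        best <- which(correct == max(correct))
        step_sel <- best[length(best)]       # ties -> fewest features
        # refit the sweep on the full outer training set, score the test fold
        s <- scale_fit(x[train, , drop = FALSE])
        res <- cpp_svm_rfe(scale_apply(x[train, , drop = FALSE], s),
                           as.numeric(ys[train]), cost, elimination_fraction,
                           scale_apply(x[test, , drop = FALSE], s))
        dec <- res$test_decisions[step_sel, ]
        rec[[length(rec) + 1]] <- data.frame(
          rep = r, fold = k, subject = test, label = labels[test],
          y = ys[test], decision = dec,
          predicted = ifelse(dec > 0, 1, -1),
          n_features = sizes[step_sel],
          inner_acc = max(correct) / length(train))
      }
    }
  })
  rec <- do.call(rbind, rec)
  roc <- roc_metrics(rec$decision, rec$y, positive = 1)
  structure(list(auc = roc$auc, accuracy_pct = roc$accuracy_pct,
                 sensitivity_pct = roc$sensitivity_pct,
                 specificity_pct = roc$specificity_pct,
                 permutation_p = NA_real_,
                 n_features_selected = stats::median(rec$n_features),
                 fold_records = rec, seed = seed,
                 combination = combination, positive = positive),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "<classifier_report>%s AUC %.3f | accuracy %.2f%% | sens %.1f%% | spec %.1f%% | median k %g%s\n",
    if (is.null(x$combination)) ""
    else paste0(" [", paste(x$combination, collapse = "+"), "]"),
    x$auc, x$accuracy_pct, x$sensitivity_pct, x$specificity_pct,
    x$n_features_selected,
    if (is.na(x$permutation_p)) ""
    else sprintf(" | perm p %.4f", x$permutation_p)))
  invisible(x)
}

#' Label-permutation test for the combination classifier
#'
#' Re-runs the nested cross-validation under `n_perm` random relabelings and
#' compares the observed accuracy against the permutation distribution:
#' `p = (1 + #{perm >= observed}) / (n_perm + 1)`. Permuted runs use
#' `perm_repeats` outer repetitions (default 1); the observed statistic is
#' taken from `observed` or computed with the default 5 repetitions.
#'
#' @param features,labels,combination,... passed to [nested_cv_classify()].
#' @param n_perm number of permutations (default 100, must be >= 1).
#' @param perm_repeats outer repetitions per permuted run.
#' @param observed optional precomputed `classifier_report`.
#' @param seed controls both the permutations and the fold assignments.
#' @return The observed `classifier_report` with `permutation_p` filled in
#'   and a `perm_accuracies` attribute.
#' @export
permutation_test <- function(features, labels = NULL, combination = NULL,
                             n_perm = 100L, perm_repeats = 1L,
                             observed = NULL, seed = 1L, ...) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (is.null(observed))
    observed <- nested_cv_classify(features, labels, combination,
                                   seed = seed, ...)
  lab <- if (inherits(features, "feature_table"))
    labels %||% features$labels else as.factor(labels)
  perm_acc <- numeric(n_perm)
  perms <- with_seed(seed + 1L, replicate(n_perm, sample(seq_along(lab)),
                                          simplify = FALSE))
  for (b in seq_len(n_perm)) {
    rep_b <- nested_cv_classify(features, lab[perms[[b]]], combination,
                                repeats = perm_repeats, seed = seed + 1L + b,
                                ...)
    perm_acc[b] <- rep_b$accuracy_pct
  }
  observed$permutation_p <- (1 + sum(perm_acc >= observed$accuracy_pct)) /
    (n_perm + 1)
  attr(observed, "perm_accuracies") <- perm_acc
  observed
}

#' ROC metrics from decision values
#'
#' AUC by the trapezoidal rule over all thresholds (ties contribute half),
#' and accuracy / sensitivity / specificity at the SVM's zero-decision
#' threshold. Sensitivity is the recall of the positive class.
#'
#' @param decision_values numeric decision values, larger meaning more
#'   positive-like.
#' @param labels class labels, two levels (or +/-1).
#' @param positive the positive label; defaults to the second factor level.
#' @return List with `auc`, `accuracy_pct`, `sensitivity_pct`,
#'   `specificity_pct`.
#' @export
roc_metrics <- function(decision_values, labels, positive = NULL) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("both classes must be present")
  positive <- as.character(positive %||% levels(labels)[2])
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  d <- as.numeric(decision_values)
  if (length(d) != length(labels)) stop("one decision value per label required")
  if (max(d) - min(d) < .Machine$double.eps) {
    warning("constant decision values; AUC undefined, reporting 0.5")
    auc <- 0.5
  } else {
    r <- rank(d)
    n1 <- sum(pos); n0 <- sum(!pos)
    auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  pred_pos <- d > 0
  sens <- 100 * sum(pred_pos & pos) / sum(pos)
  spec <- 100 * sum(!pred_pos & !pos) / sum(!pos)
  acc <- 100 * (sum(pred_pos & pos) + sum(!pred_pos & !pos)) / length(d)
  list(auc = auc, accuracy_pct = acc, sensitivity_pct = sens,
       specificity_pct = spec)
}
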