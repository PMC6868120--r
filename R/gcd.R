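#' Fit the restricted and full bivariate autoregressions for one voxel pair
#'
#' Quantifies the directed influence of `x` on `y`. The restricted model
#' regresses the target on its own lags `1..order` plus an intercept; the full
#' model adds the predictor's lags `1..order`. Both are ordinary least
#' squares, and the residual series of both models are kept so that the
#' influence statistic can be formed from their magnitudes.
#'
#' @param x numeric predictor (source) series.
#' @param y numeric target series, same length.
#' @param order autoregressive lag count (default 1).
#' @return A `var_fit` object with elements `order_m`, `lag_window`,
#'   `coeffs_restricted` (`a0..am`), `coeffs_full` (`a` plus `b1..bm`),
#'   `resid_restricted`, `resid_full`, `n_obs`, and a `degenerate` flag set
#'   for near-constant inputs (for which the downstream p-value is 1).
#' @export
fit_bivariate_var <- function(x, y, order = 1L) {
  x <- as.numeric(x); y <- as.numeric(y)
  tt <- length(y)
  order <- as.integer(order)
  if (length(x) != tt) stop("x and y must have the same length")
  if (order < 1L) stop("order must be >= 1")
  if (tt <= 3L * order + 3L)
    stop(sprintf("need more than %d timepoints for order %d", 3L * order + 3L,
                 order))
  n <- tt - order
  rows <- (order + 1L):tt
  lags <- function(v) sapply(seq_len(order), function(l) v[rows - l])
  ylag <- matrix(lags(y), n, order)
  xlag <- matrix(lags(x), n, order)
  yt <- y[rows]
  zr <- cbind(1, ylag)
  zf <- cbind(zr, xlag)
  qf <- qr(zf)
  degenerate <- qf$rank < ncol(zf)
  if (degenerate) {
    coefs_r <- rep(NA_real_, order + 1L)
    coefs_f <- rep(NA_real_, 2L * order + 1L)
    e1 <- e2 <- rep(0, n)
  } else {
    qr_r <- qr(zr)
    coefs_r <- qr.coef(qr_r, yt)
    e1 <- qr.resid(qr_r, yt)
    coefs_f <- qr.coef(qf, yt)
    e2 <- qr.resid(qf, yt)
    if (sum(e2^2) <= 1e-12 * max(sum(yt^2), 1)) degenerate <- TRUE
  }
  names(coefs_r) <- paste0("a", 0:order)
  names(coefs_f) <- c(paste0("a", 0:order), paste0("b", seq_len(order)))
  structure(list(order_m = order, lag_window = c(1L, order),
                 coeffs_restricted = coefs_r, coeffs_full = coefs_f,
                 resid_restricted = e1, resid_full = e2,
                 n_obs = n, degenerate = degenerate),
            class = "var_fit")
}

#' Granger causality value from a fitted voxel pair
#'
#' The influence is the log ratio of restricted to full residual magnitude,
#' `F = ln(|e1| / |e2|)`, with the residual magnitude read as the residual
#' standard deviation (so the value equals half the log residual-variance
#' ratio); `residual_measure = "var"` exposes the variance reading, which is
#' exactly twice the default. Nonnegativity is guaranteed by least-squares
#' nesting. The significance is the canonical nested-model F-test with
#' `(order, n_obs - 2*order - 1)` degrees of freedom.
#'
#' @param fit a `var_fit` from [fit_bivariate_var()].
#' @param residual_measure `"sd"` (default) or `"var"`.
#' @return A `gc_value`: list with `f_value`, `p_value`, `statistic`, `df`,
#'   and `degenerate`.
#' @export
gc_f_value <- function(fit, residual_measure = c("sd", "var")) {
  stopifnot(inherits(fit, "var_fit"))
  residual_measure <- match.arg(residual_measure)
  m <- fit$order_m
  df2 <- fit$n_obs - 2L * m - 1L
  if (fit$degenerate)
    return(structure(list(f_value = 0, p_value = 1, statistic = NA_real_,
                          df = c(m, df2), degenerate = TRUE),
                     class = "gc_value"))
  rss1 <- sum(fit$resid_restricted^2)
  rss2 <- sum(fit$resid_full^2)
  fstat <- ((rss1 - rss2) / m) / (rss2 / df2)
  fstat <- max(fstat, 0)
  f <- 0.5 * log(rss1 / rss2)
  if (residual_measure == "var") f <- 2 * f
  structure(list(f_value = max(f, 0),
                 p_value = pf(fstat, m, df2, lower.tail = FALSE),
                 statistic = fstat, df = c(m, df2), degenerate = FALSE),
            class = "gc_value")
}

#' Construct a set of Granger causality density maps
#'
#' `total_flow` and `int_flow` are derived, not stored independently:
#' `total_flow = inflow + outflow` and `int_flow = inflow - outflow` hold
#' exactly on every voxel. A voxel with strongly negative int-flow is a net
#' causal source; strongly positive, a net causal target.
#'
#' @param inflow,outflow nonnegative per-voxel density vectors.
#' @param alpha significance threshold used in the summation.
#' @param lag_order VAR order used.
#' @param degenerate logical per-voxel flag for excluded (near-constant)
#'   voxels.
#' @return An object of class `gcd_maps`.
#' @export
gcd_maps <- function(inflow, outflow, alpha, lag_order,
                     degenerate = rep(FALSE, length(inflow))) {
  inflow <- as.numeric(inflow); outflow <- as.numeric(outflow)
  if (length(inflow) != length(outflow)) stop("map lengths differ")
  if (any(inflow < 0) || any(outflow < 0)) stop("densities must be >= 0")
  structure(list(inflow = inflow, outflow = outflow,
                 total_flow = inflow + outflow, int_flow = inflow - outflow,
                 alpha = alpha, lag_order = lag_order,
                 degenerate = degenerate),
            class = "gcd_maps")
}

#' @export
print.gcd_maps <- function(x, ...) {
  cat(sprintf(
    "<gcd_maps> %d voxels, order %d, alpha %.3g; outflow max %.3g, inflow max %.3g\n",
    length(x$inflow), x$lag_order, x$alpha, max(x$outflow), max(x$inflow)))
  invisible(x)
}

#' Voxelwise Granger causality density maps
#'
#' For every ordered voxel pair the directed influence and its nested-model
#' F-test p-value are computed; a voxel's outflow is the sum of its
#' significant outgoing influences, its inflow the sum of significant incoming
#' ones (the threshold is applied symmetrically to both directions, no
#' multiplicity correction inside the sum). Near-constant voxels are flagged
#' degenerate and contribute zero everywhere. Order-1 maps use a closed-form
#' vectorised least-squares path; higher orders fall back to per-pair fits.
#'
#' @param series a [voxel_series()] (at least 2 voxels).
#' @param order VAR order (default 1).
#' @param alpha per-pair significance threshold (default 0.05).
#' @param residual_measure `"sd"` (default) or `"var"`, see [gc_f_value()].
#' @return A [gcd_maps()] object aligned with `series$voxel_index`.
#' @export
compute_gcd_maps <- function(series, order = 1L, alpha = 0.05,
                             residual_measure = c("sd", "var")) {
  stopifnot(inherits(series, "voxel_series"))
  residual_measure <- match.arg(residual_measure)
  v <- nrow(series$matrix)
  tt <- ncol(series$matrix)
  order <- as.integer(order)
  if (v < 2L) stop("need at least 2 voxels")
  if (tt <= 3L * order + 3L)
    stop(sprintf("need more than %d timepoints for order %d",
                 3L * order + 3L, order))
  if (order == 1L) {
    res <- gcd_pairwise_order1(series$matrix)
  } else {
    res <- gcd_pairwise_loop(series$matrix, order)
  }
  # res: list(f2 = log-variance-ratio matrix [target, source], p, degenerate)
  f <- 0.5 * res$log_vr
  if (residual_measure == "var") f <- res$log_vr
  f[f < 0] <- 0
  sig <- (res$p < alpha) & !is.na(res$p)
  contrib <- f * sig
  contrib[is.na(contrib)] <- 0
  diag(contrib) <- 0
  contrib[res$degenerate, ] <- 0
  contrib[, res$degenerate] <- 0
  gcd_maps(inflow = rowSums(contrib), outflow = colSums(contrib),
           alpha = alpha, lag_order = order, degenerate = res$degenerate)
}

# Closed-form order-1 pairwise residual sums via centered cross-products.
# Returns matrices indexed [target, source].
gcd_pairwise_order1 <- function(mat) {
  v <- nrow(mat); tt <- ncol(mat)
  n <- tt - 1L
  a <- mat[, 2:tt, drop = FALSE]            # targets y_t
  b <- mat[, 1:(tt - 1L), drop = FALSE]     # lags y_{t-1}
  a <- a - rowMeans(a)
  b <- b - rowMeans(b)
  s <- rowSums(a^2)
  g <- tcrossprod(b)              # g[v,w] = b_v . b_w
  h <- tcrossprod(b, a)           # h[w,v] = b_w . a_v
  gvv <- diag(g)
  hvv <- diag(h)
  scale_ref <- pmax(gvv, 1)
  degenerate <- gvv <= 1e-12 * max(scale_ref) | s <= 1e-12 * max(s, 1)
  rss1 <- s - hvv^2 / gvv                             # per target
  det <- outer(gvv, gvv) - g^2                         # [v,w]
  th <- t(h)                                           # th[v,w] = b_w . a_v
  num <- outer(hvv^2, gvv) - 2 * g * (hvv * th) + gvv * th^2
  rss2 <- s - num / det                                # [target v, source w]
  rss2 <- pmax(rss2, 0)
  df2 <- n - 3L
  fstat <- pmax((rss1 - rss2), 0) / (rss2 / df2)
  p <- pf(fstat, 1, df2, lower.tail = FALSE)
  log_vr <- log(rss1 / rss2)
  bad <- !is.finite(log_vr) | rss2 <= 1e-12 * pmax(s, 1)
  log_vr[bad] <- 0
  p[bad] <- 1
  list(log_vr = log_vr, p = p, degenerate = degenerate)
}

# General-order pairwise path: per-voxel restricted fits, per-pair full fits.
gcd_pairwise_loop <- function(mat, order) {
  v <- nrow(mat); tt <- ncol(mat)
  n <- tt - order
  rows <- (order + 1L):tt
  lag_block <- function(i)
    sapply(seq_len(order), function(l) mat[i, rows - l])
  targets <- lapply(seq_len(v), function(i) mat[i, rows])
  blocks <- lapply(seq_len(v), lag_block)
  degenerate <- vapply(seq_len(v), function(i)
    var(mat[i, ]) <= 1e-12, logical(1))
  rss1 <- rep(NA_real_, v)
  qrs <- vector("list", v)
  for (i in seq_len(v)) {
    if (degenerate[i]) next
    qrs[[i]] <- qr(cbind(1, blocks[[i]]))
    rss1[i] <- sum(qr.resid(qrs[[i]], targets[[i]])^2)
  }
  log_vr <- matrix(0, v, v)
  p <- matrix(1, v, v)
  df2 <- n - 2L * order - 1L
  for (tv in seq_len(v)) {
    if (degenerate[tv]) next
    for (sv in seq_len(v)) {
      if (sv == tv || degenerate[sv]) next
      qf <- qr(cbind(1, blocks[[tv]], blocks[[sv]]))
      if (qf$rank < 2L * order + 1L) next
      rss2 <- sum(qr.resid(qf, targets[[tv]])^2)
      if (rss2 <= 1e-12 * max(sum(targets[[tv]]^2), 1)) next
      fstat <- max(rss1[tv] - rss2, 0) / order / (rss2 / df2)
      p[tv, sv] <- pf(fstat, order, df2, lower.tail = FALSE)
      log_vr[tv, sv] <- max(log(rss1[tv] / rss2), 0)
    }
  }
  list(log_vr = log_vr, p = p, degenerate = degenerate)
}

#' Batch GCD mapping over a cohort
#'
#' Runs the preprocessing chain and [compute_gcd_maps()] for every subject in
#' a manifest, writing four NIfTI maps per subject (plus a provenance
#' sidecar). All subjects must share the mask geometry.
#'
#' @param manifest data.frame from [read_manifest()] with `image_path` and
#'   (optionally) `motion_path` columns.
#' @param mask 3D [image_volume()] shared by the cohort.
#' @param out_dir directory for the per-subject maps.
#' @param order,alpha,residual_measure see [compute_gcd_maps()].
#' @param preprocess if `TRUE` (default) run [preprocess_series()] first.
#' @param ... further arguments to [preprocess_series()].
#' @return Named list of per-subject [gcd_maps()] objects, invisibly.
#' @export
gcd_cohort <- function(manifest, mask, out_dir, order = 1L, alpha = 0.05,
                       residual_measure = "sd", preprocess = TRUE, ...) {
  stopifnot(inherits(mask, "image_volume"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    vol <- read_image(manifest$image_path[i])
    if (!all(dim(vol$data)[1:3] == dim(mask$data)))
      stop("subject ", sid, " image grid does not match the cohort mask")
    if (preprocess) {
      motion <- if (!is.null(manifest$motion_path) &&
                    nzchar(manifest$motion_path[i] %||% ""))
        read_motion_params(manifest$motion_path[i]) else NULL
      series <- preprocess_series(vol, mask, motion = motion, ...)
    } else {
      series <- mask_series(vol, mask)
    }
    maps <- compute_gcd_maps(series, order = order, alpha = alpha,
                             residual_measure = residual_measure)
    write_gcd_maps(maps, mask, out_dir, sid)
    out[[sid]] <- maps
  }
  invisible(out)
}
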