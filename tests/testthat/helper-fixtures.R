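# Shared fixtures, all generated in code.

# Small stationary VAR pair: y driven by x with the given lag-1 coupling.
make_driven_pair <- function(tt, coupling = 0.8, self = 0.3, seed = 1) {
  gcdmap:::with_seed(seed, {
    x <- numeric(tt + 100)
    y <- numeric(tt + 100)
    for (t in 2:(tt + 100)) {
      x[t] <- self * x[t - 1] + rnorm(1)
      y[t] <- self * y[t - 1] + coupling * x[t - 1] + rnorm(1)
    }
    list(x = x[101:(tt + 100)], y = y[101:(tt + 100)])
  })
}

# Random multi-voxel series on a line of grid coordinates.
make_series <- function(v, tt, seed = 1, tr = 2) {
  gcdmap:::with_seed(seed,
    voxel_series(matrix(rnorm(v * tt), v), cbind(seq_len(v), 1L, 1L), tr))
}

# Independent brute-force GCD oracle: per-pair lm() fits and anova F-tests.
brute_force_gcd <- function(mat, order = 1, alpha = 0.05) {
  v <- nrow(mat)
  tt <- ncol(mat)
  rows <- (order + 1):tt
  lagm <- function(i) sapply(seq_len(order), function(l) mat[i, rows - l])
  inflow <- outflow <- numeric(v)
  for (tv in seq_len(v)) for (sv in seq_len(v)) {
    if (tv == sv) next
    df <- data.frame(yt = mat[tv, rows], yl = lagm(tv), xl = lagm(sv))
    fit_r <- lm(yt ~ ., data = df[, 1:(order + 1), drop = FALSE])
    fit_f <- lm(yt ~ ., data = df)
    an <- anova(fit_r, fit_f)
    fval <- 0.5 * log(sum(fit_r$residuals^2) / sum(fit_f$residuals^2))
    if (an$`Pr(>F)`[2] < alpha) {
      inflow[tv] <- inflow[tv] + fval
      outflow[sv] <- outflow[sv] + fval
    }
  }
  list(inflow = inflow, outflow = outflow)
}

# Separable two-class feature table: planted columns shifted by `shift` sds.
make_separable_features <- function(n_per_group = 20, p = 60, planted = 5,
                                    shift = 3, seed = 1) {
  gcdmap:::with_seed(seed, {
    x <- matrix(rnorm(2 * n_per_group * p), 2 * n_per_group)
    labels <- factor(rep(c("substate_A", "substate_B"), each = n_per_group))
    x[labels == "substate_B", seq_len(planted)] <-
      x[labels == "substate_B", seq_len(planted)] + shift
    feature_table(x, labels)
  })
}

# Full synthetic cohort -> preprocessed GCD feature table.
cohort_features <- function(spec, effect, seed,
                            metrics = c("inflow", "outflow", "int_flow"),
                            n_per_group = 21, n_discard = 10) {
  coh <- simulate_cohort(spec, n_per_group = n_per_group, effect = effect,
                         seed = seed)
  maps <- lapply(coh$subjects, function(s) {
    ser <- preprocess_series(s$volume, spec$mask, motion = s$motion,
                             n_discard = n_discard)
    compute_gcd_maps(ser)
  })
  list(features = gcd_feature_table(maps, coh$manifest$group_label,
                                    metrics = metrics),
       maps = maps, cohort = coh)
}
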