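test_that("initial-volume discard shortens the time axis from the front", {
  arr <- array(rnorm(4 * 4 * 4 * 250), c(4, 4, 4, 250))
  vol <- image_volume(arr, tr_seconds = 2)
  out <- discard_initial_volumes(vol, 10)
  expect_equal(dim(out$data)[4], 240)
  expect_equal(out$data[, , , 1], arr[, , , 11])
  expect_identical(discard_initial_volumes(vol, 0), vol)
  short <- image_volume(arr[, , , 1:5, drop = FALSE], tr_seconds = 2)
  expect_error(discard_initial_volumes(short, 10), "cannot discard")
})

test_that("framewise displacement follows the translation + arc-length sum", {
  zero <- motion_params(matrix(0, 40, 3), matrix(0, 40, 3))
  expect_equal(compute_fd(zero)$fd_mm, rep(0, 40))

  tr <- matrix(0, 5, 3); tr[3, 1] <- 1           # +1 mm step in x at frame 3
  fd <- compute_fd(motion_params(tr, matrix(0, 5, 3)))
  expect_equal(fd$fd_mm, c(0, 0, 1, 1, 0))       # step in, step back out

  ro <- matrix(0, 4, 3); ro[2, 2] <- 0.02        # 0.02 rad at 50 mm = 1 mm arc
  fd2 <- compute_fd(motion_params(matrix(0, 4, 3), ro), head_radius_mm = 50)
  expect_equal(fd2$fd_mm[2], 1.0)
  expect_error(compute_fd(motion_params(matrix(0, 1, 3), matrix(0, 1, 3))),
               "at least 2")
})

test_that("scrubbing replaces only censored frames by piecewise-linear values", {
  vs <- voxel_series(matrix(c(1, 2, 3, 4, 5), 1), cbind(1, 1, 1), 2)
  fd_ok <- structure(list(fd_mm = rep(0, 5), threshold_mm = 0.5),
                     class = "fd_series")
  expect_identical(scrub_interpolate(vs, fd_ok)$censored_frames, integer(0))
  expect_equal(scrub_interpolate(vs, fd_ok)$matrix, vs$matrix)

  vs2 <- voxel_series(matrix(c(1, 9, 3), 1), cbind(1, 1, 1), 2)
  fd1 <- structure(list(fd_mm = c(0, 1, 0), threshold_mm = 0.5),
                   class = "fd_series")
  out <- scrub_interpolate(vs2, fd1)
  expect_equal(out$matrix[1, ], c(1, 2, 3))       # midpoint of 1 and 3
  expect_equal(out$censored_frames, 2L)

  vs3 <- voxel_series(matrix(c(0, 9, 9, 3, 7), 1), cbind(1, 1, 1), 2)
  fd2 <- structure(list(fd_mm = c(0, 1, 1, 0, 0), threshold_mm = 0.5),
                   class = "fd_series")
  expect_equal(scrub_interpolate(vs3, fd2)$matrix[1, ], c(0, 1, 2, 3, 7))

  # leading censored frame takes the nearest kept value
  fd3 <- structure(list(fd_mm = c(1, 0, 0, 0, 0), threshold_mm = 0.5),
                   class = "fd_series")
  expect_equal(scrub_interpolate(vs3, fd3)$matrix[1, 1], 9)

  fd_all <- structure(list(fd_mm = rep(1, 5), threshold_mm = 0.5),
                      class = "fd_series")
  expect_error(scrub_interpolate(vs3, fd_all), "all frames")
})

test_that("Friston-24 expansion has the documented column structure", {
  zero <- motion_params(matrix(0, 10, 3), matrix(0, 10, 3))
  expect_equal(build_friston24(zero), matrix(0, 10, 24), ignore_attr = TRUE)

  const <- motion_params(matrix(2, 10, 3), matrix(0.1, 10, 3))
  f24 <- build_friston24(const)
  expect_equal(ncol(f24), 24)
  expect_equal(f24[2:10, 7], f24[2:10, 1])        # lag equals original
  expect_equal(unname(f24[1, 7:12]), rep(0, 6))   # zero-padded first row
  expect_equal(f24[, 13], f24[, 1]^2)

  rnd <- motion_params(matrix(rnorm(30), 10, 3), matrix(rnorm(30), 10, 3))
  f <- build_friston24(rnd)
  expect_equal(f[2:10, 7], f[1:9, 1])             # index bookkeeping
  expect_equal(f[, 19], f[, 7]^2)
})

test_that("nuisance regression leaves residuals orthogonal to the design", {
  vs <- make_series(4, 60, seed = 2)
  demeaned <- regress_nuisance(vs, NULL)
  expect_equal(rowMeans(demeaned$matrix), rep(0, 4), tolerance = 1e-12)

  reg <- matrix(rnorm(60 * 3), 60)
  vs2 <- voxel_series(rbind(reg[, 1], vs$matrix), cbind(1:5, 1, 1), 2)
  out <- regress_nuisance(vs2, reg)
  expect_lt(max(abs(out$matrix[1, ])), 1e-10)     # regressor-equal voxel
  expect_lt(max(abs(out$matrix %*% reg)), 1e-8)   # orthogonality
  # idempotence
  twice <- regress_nuisance(out, reg)
  expect_equal(twice$matrix, out$matrix, tolerance = 1e-10)
  # collinear columns are dropped with a warning, not an error
  expect_warning(regress_nuisance(vs, cbind(reg, reg[, 1])), "collinear")
})

test_that("linear detrend removes exactly the least-squares line", {
  tt <- 50
  ramp <- voxel_series(matrix(3 + 0.5 * seq_len(tt), 1), cbind(1, 1, 1), 2)
  expect_lt(max(abs(detrend_linear(ramp)$matrix)), 1e-10)

  sine <- sin(2 * pi * seq_len(tt) / 10)
  mixed <- voxel_series(matrix(2 - 0.3 * seq_len(tt) + sine, 1),
                        cbind(1, 1, 1), 2)
  expect_equal(detrend_linear(mixed)$matrix[1, ],
               sine - mean(sine) - coef(lm(sine ~ seq_len(tt)))[2] *
                 (seq_len(tt) - mean(seq_len(tt))),
               tolerance = 1e-8)
  noise <- detrend_linear(make_series(1, 100, seed = 3))
  expect_equal(detrend_linear(noise)$matrix, noise$matrix, tolerance = 1e-10)
})

test_that("band-pass keeps the passband and removes drift and DC", {
  tt <- 240; tr <- 2
  gain <- function(f) {
    x <- sin(2 * pi * f * seq_len(tt) * tr)
    out <- bandpass(voxel_series(matrix(x, 1), cbind(1, 1, 1), tr))$matrix[1, ]
    k <- round(f * tt * tr) + 1
    Mod(fft(out)[k]) / Mod(fft(x)[k])
  }
  expect_gt(gain(0.05), 0.95)                 # in-band amplitude preserved
  expect_lt(gain(0.005), 0.2)                 # sub-band drift attenuated >=80%
  const <- voxel_series(matrix(5, 1, tt), cbind(1, 1, 1), tr)
  expect_lt(max(abs(bandpass(const)$matrix)), 1e-8)
  expect_error(bandpass(const, 0.01, 0.3), "Nyquist")
  expect_error(bandpass(const, 0.2, 0.1), "low_hz")
})

test_that("the full chain preserves length, censoring record and order", {
  spec <- network_spec(grid_dim = c(4, 4, 4), mask = sphere_mask(c(4, 4, 4), 1.8),
                       n_timepoints = 80)
  sub <- simulate_var_subject(spec, seed = 4)
  motion <- gcdmap:::simulate_motion(80, seed = 5, spike_prob = 0.1)
  out <- preprocess_series(sub$volume, spec$mask, motion = motion,
                           n_discard = 10)
  expect_equal(ncol(out$matrix), 70)
  expect_equal(nrow(out$matrix), sum(spec$mask$data))
  fd <- compute_fd(motion_params(motion$translations_mm[-(1:10), ],
                                 motion$rotations_rad[-(1:10), ]))
  expect_equal(out$censored_frames, which(fd$fd_mm > 0.5))
  expect_false(anyNA(out$matrix))
})
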