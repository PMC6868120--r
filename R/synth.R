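#' Spherical analysis mask on a voxel grid
#'
#' @param grid_dim length-3 grid dimensions.
#' @param radius sphere radius in voxels around the grid centre; the default
#'   for an 8x8x8 grid encloses roughly 200 voxels.
#' @param voxel_size_mm voxel edge lengths.
#' @return 3D binary [image_volume()].
#' @export
sphere_mask <- function(grid_dim = c(8L, 8L, 8L), radius = 3.6,
                        voxel_size_mm = c(3, 3, 3)) {
  ctr <- (grid_dim + 1) / 2
  co <- as.matrix(expand.grid(x = seq_len(grid_dim[1]),
                              y = seq_len(grid_dim[2]),
                              z = seq_len(grid_dim[3])))
  d2 <- rowSums(sweep(co, 2, ctr)^2)
  image_volume(array(as.numeric(d2 <= radius^2), grid_dim),
               voxel_size_mm = voxel_size_mm)
}

#' Specification of a synthetic VAR voxel network
#'
#' Defines the generative model behind the simulator: each in-mask voxel
#' follows a first-order vector autoregression
#' `x_t = self_coeff * x_{t-1} + A' x_{t-1} + drift + noise`, where
#' `adjacency[i, j]` couples source voxel `i` into target voxel `j` at lag 1,
#' the innovation noise is Gaussian, and the drift is a slow (one cycle per
#' run) sinusoid. Stationarity (spectral radius of the lag-1 transition below
#' 1) is enforced at construction.
#'
#' @param grid_dim voxel grid (default 8x8x8).
#' @param mask 3D [image_volume()] (default [sphere_mask()] on the grid).
#' @param adjacency V x V coupling matrix over in-mask voxels (default zero).
#' @param self_coeff per-voxel autoregressive coefficient (scalar recycled).
#' @param noise_sd innovation standard deviation (> 0).
#' @param drift_amplitude amplitude of the slow drift component.
#' @param tr_seconds sampling interval (default 2 s).
#' @param n_timepoints series length (default 240).
#' @return A `network_spec` object.
#' @export
network_spec <- function(grid_dim = c(8L, 8L, 8L), mask = NULL,
                         adjacency = NULL, self_coeff = 0.3, noise_sd = 1,
                         drift_amplitude = 1, tr_seconds = 2,
                         n_timepoints = 240L) {
  mask <- mask %||% sphere_mask(grid_dim)
  if (!all(dim(mask$data) == grid_dim)) stop("mask does not match grid_dim")
  v <- sum(mask$data != 0)
  adjacency <- adjacency %||% matrix(0, v, v)
  if (!all(dim(adjacency) == c(v, v)))
    stop(sprintf("adjacency must be %d x %d (in-mask voxels)", v, v))
  self_coeff <- rep_len(self_coeff, v)
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  spec <- structure(list(grid_dim = as.integer(grid_dim), mask = mask,
                         n_voxels = v, adjacency = adjacency,
                         self_coeff = self_coeff, noise_sd = noise_sd,
                         drift_amplitude = drift_amplitude,
                         tr_seconds = tr_seconds,
                         n_timepoints = as.integer(n_timepoints)),
                    class = "network_spec")
  rho <- spectral_radius(transition_matrix(spec))
  if (rho >= 1)
    stop(sprintf("non-stationary network: spectral radius %.3f >= 1", rho))
  spec
}

transition_matrix <- function(spec)
  diag(spec$self_coeff, spec$n_voxels) + t(spec$adjacency)

spectral_radius <- function(m) max(Mod(eigen(m, only.values = TRUE)$values))

#' Planted hub group effect
#'
#' Picks the in-mask voxel closest to the grid centre as a causal hub and its
#' `n_edges` nearest in-mask neighbours as targets; the returned edge set
#' (hub -> target, coupling increment `delta`) is the adjacency change that
#' one group receives in [simulate_cohort()]. Spatial contiguity of the
#' affected voxels is what lets the voxelwise accuracy maps form clusters.
#'
#' @param spec a [network_spec()].
#' @param n_edges number of hub -> target edges (default 10).
#' @param delta coupling increment per edge (default 0.5).
#' @return List with `edges` (n x 2 matrix of in-mask voxel rows:
#'   source, target), `delta`, `hub`, `targets`, `affected` voxel rows.
#' @export
planted_hub_effect <- function(spec, n_edges = 10L, delta = 0.5) {
  co <- mask_coords(spec)
  ctr <- (spec$grid_dim + 1) / 2
  d2 <- rowSums(sweep(co, 2, ctr)^2)
  ord <- order(d2, seq_len(nrow(co)))
  hub <- ord[1]
  targets <- ord[2:(n_edges + 1L)]
  list(edges = cbind(source = hub, target = targets), delta = delta,
       hub = hub, targets = targets, affected = c(hub, targets))
}

mask_coords <- function(spec)
  arrayInd(which(spec$mask$data != 0), spec$grid_dim)

#' Simulate one subject from a VAR network
#'
#' Runs the stationary VAR(1) with a 100-step burn-in (discarded), adds the
#' slow sinusoidal drift, and packs the result as a 4D image on the spec's
#' grid. Deterministic for a given seed.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed.
#' @return List with `volume` (4D [image_volume()]), `series`
#'   ([voxel_series()]), and `ground_truth` (per-voxel true coupling-weighted
#'   out-/in-flow).
#' @export
simulate_var_subject <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  m <- transition_matrix(spec)
  if (spectral_radius(m) >= 1) stop("non-stationary network spec")
  v <- spec$n_voxels
  tt <- spec$n_timepoints
  burn <- 100L
  series <- with_seed(seed, {
    x <- matrix(0, v, tt + burn)
    eps <- matrix(rnorm(v * (tt + burn), sd = spec$noise_sd), v)
    for (t in 2:(tt + burn)) x[, t] <- m %*% x[, t - 1] + eps[, t]
    phase <- runif(v, 0, 2 * pi)
    x <- x[, (burn + 1):(burn + tt), drop = FALSE]
    freq <- 1 / (tt * spec$tr_seconds)     # one cycle per run, sub-passband
    drift <- spec$drift_amplitude *
      sin(outer(phase, 2 * pi * freq * spec$tr_seconds * seq_len(tt), "+"))
    x + drift
  })
  vs <- voxel_series(series, mask_coords(spec), spec$tr_seconds,
                     grid_dim = spec$grid_dim)
  vol <- image_volume(series_to_array(series, vs, fill = 0),
                      voxel_size_mm = spec$mask$voxel_size_mm,
                      tr_seconds = spec$tr_seconds)
  gt <- list(true_outflow = rowSums(abs(spec$adjacency)),
             true_inflow = colSums(abs(spec$adjacency)))
  list(volume = vol, series = vs, ground_truth = gt)
}

# Motion trace: slow random walk plus occasional spikes that push FD over
# the scrubbing threshold, so cohort runs exercise the censoring path.
simulate_motion <- function(n_timepoints, seed = 1L, walk_sd_mm = 0.02,
                            walk_sd_rad = 4e-4, spike_prob = 0.02,
                            spike_mm = 0.7) {
  with_seed(seed, {
    tr <- apply(matrix(rnorm(n_timepoints * 3, sd = walk_sd_mm),
                       n_timepoints), 2, cumsum)
    ro <- apply(matrix(rnorm(n_timepoints * 3, sd = walk_sd_rad),
                       n_timepoints), 2, cumsum)
    spikes <- which(runif(n_timepoints) < spike_prob & seq_len(n_timepoints) > 1)
    for (s in spikes) {
      j <- sample(3, 1)
      tr[s, j] <- tr[s, j] + spike_mm
    }
    motion_params(tr, ro)
  })
}

#' Simulate a two-group cohort with a planted coupling difference
#'
#' Group `substate_B` receives `effect$delta` added to the designated
#' adjacency edges; every subject additionally gets Gaussian jitter on its
#' nonzero couplings, an independent noise realisation, a synthetic motion
#' trace with occasional super-threshold spikes, and demographics (age,
#' sex, epilepsy-duration style covariate). Subject `i` is seeded with
#' `seed + i`, so cohorts are reproducible from the single run seed.
#'
#' @param spec a [network_spec()]; its adjacency is the shared base network.
#' @param n_per_group subjects per group (default 21).
#' @param effect a [planted_hub_effect()]-style list (`edges`, `delta`), or
#'   `NULL` for a null cohort with no group difference.
#' @param seed integer run seed.
#' @param dir optional directory; when given, 4D images, motion files, the
#'   manifest TSV and a ground-truth JSON are written there.
#' @param subject_jitter_sd sd of the per-subject coupling jitter.
#' @return List with `manifest` (data.frame), `subjects` (per-subject list
#'   with `series`, `volume`, `motion`), `ground_truth`, `spec`.
#' @export
simulate_cohort <- function(spec = network_spec(), n_per_group = 21L,
                            effect = planted_hub_effect(spec), seed = 1L,
                            dir = NULL, subject_jitter_sd = 0.02) {
  if (n_per_group < 2L) stop("n_per_group must be >= 2")
  n <- 2L * n_per_group
  groups <- rep(c("substate_A", "substate_B"), each = n_per_group)
  ids <- sprintf("sub-%03d", seq_len(n))
  demo <- with_seed(seed, data.frame(
    age = pmax(round(rnorm(n, 8.7, 2), 1), 5),
    sex = rbinom(n, 1, 0.5),
    duration = round(abs(rnorm(n, 20, 18)), 1)))
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    a <- spec$adjacency
    if (!is.null(effect) && groups[i] == "substate_B")
      a[effect$edges] <- a[effect$edges] + effect$delta
    jit <- which(a != 0)
    if (length(jit))
      a[jit] <- a[jit] + with_seed(seed + i,
                                   rnorm(length(jit), sd = subject_jitter_sd))
    sspec <- network_spec(spec$grid_dim, spec$mask, a, spec$self_coeff,
                          spec$noise_sd, spec$drift_amplitude,
                          spec$tr_seconds, spec$n_timepoints)
    sim <- simulate_var_subject(sspec, seed = seed + i)
    sim$motion <- simulate_motion(spec$n_timepoints, seed = seed + n + i)
    subjects[[i]] <- sim
  }
  names(subjects) <- ids
  manifest <- data.frame(subject_id = ids, group_label = groups,
                         image_path = "", motion_path = "", demo)
  gt <- list(effect = effect,
             affected = if (is.null(effect)) integer(0) else effect$affected,
             base_adjacency_nonzero = sum(spec$adjacency != 0))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(n)) {
      ip <- file.path(dir, paste0(ids[i], "_bold.nii.gz"))
      mp <- file.path(dir, paste0(ids[i], "_motion.txt"))
      write_image(subjects[[i]]$volume, ip)
      write.table(cbind(subjects[[i]]$motion$translations_mm,
                        subjects[[i]]$motion$rotations_rad),
                  mp, row.names = FALSE, col.names = FALSE)
      manifest$image_path[i] <- ip
      manifest$motion_path[i] <- mp
    }
    write_image(spec$mask, file.path(dir, "mask.nii.gz"))
    write_manifest(manifest, file.path(dir, "manifest.tsv"))
    jsonlite::write_json(
      list(seed = seed, n_per_group = n_per_group,
           delta = if (is.null(effect)) 0 else effect$delta,
           edges = if (is.null(effect)) NULL else unname(effect$edges),
           affected = gt$affected),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
  }
  list(manifest = manifest, subjects = subjects, ground_truth = gt,
       spec = spec)
}
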