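#' Configure a synthetic resting-state BOLD cohort
#'
#' The generator emulates a two-group resting-state fMRI study: per subject,
#' voxelwise BOLD data are built as latent spatial network maps times
#' band-limited network time courses, plus seed-region (ROI) signals whose
#' correlation with the network time courses is planted per group, plus
#' global/white-matter/CSF nuisance processes, a constant baseline intensity
#' and i.i.d. Gaussian noise. The group difference is a shift of the target
#' ROI-to-network correlations (patients relative to controls), concentrated
#' in per-system coupling blocks -- mean activity is identical between groups.
#'
#' Defaults mirror the emulated study design: 18 subjects per group, 300
#' volumes at a repetition time of 2 s, 16 seed ROIs in four
#' subcortical-cerebellar systems, and shifts that are large for cerebellum
#' and MTL and small for striatum and amygdala.
#'
#' @param n_per_group subjects per group (>= 2; default 18).
#' @param n_volumes time points per subject (default 300).
#' @param tr_seconds repetition time in seconds (default 2).
#' @param grid a [bold_grid()] (default [default_grid()], ~10^4 voxels).
#' @param n_latent_networks number of latent spatial networks (default 8,
#'   a desk-scale stand-in for the 22 cortical networks of the full design).
#' @param roi_table ROI specification data.frame ([default_roi_table()]).
#' @param baseline_coupling control-group target correlation between each ROI
#'   and its system's designated networks (default 0.2).
#' @param effect_size_per_system named numeric: correlation-scale shift added
#'   to the patient group's coupling, per system; `|shift| < 1`.
#' @param within_group_sd between-subject SD of the planted coupling entries
#'   (default 0.1); this is what makes subjects within a group vary.
#' @param nuisance_amplitudes named numeric `c(global=, wm=, csf=)` scales of
#'   the three nuisance signals (data units).
#' @param network_amplitude,roi_amplitude,noise_sd,baseline_intensity scales
#'   of network signal, ROI signal, i.i.d. noise and constant baseline.
#' @param motion_step named numeric `c(trans_mm=, rot_rad=)` random-walk step
#'   SDs of the six rigid-body motion parameters.
#' @param seed integer RNG seed; identical configs (including seed) produce
#'   bit-identical cohorts.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 18L,
                       n_volumes = 300L,
                       tr_seconds = 2,
                       grid = default_grid(),
                       n_latent_networks = 8L,
                       roi_table = default_roi_table(),
                       baseline_coupling = 0.2,
                       effect_size_per_system = c(striatum = -0.05,
                                                  cerebellum = -0.45,
                                                  MTL = -0.40,
                                                  amygdala = -0.05),
                       within_group_sd = 0.1,
                       nuisance_amplitudes = c(global = 0.5, wm = 0.3,
                                               csf = 0.3),
                       network_amplitude = 1,
                       roi_amplitude = 1.5,
                       noise_sd = 1,
                       baseline_intensity = 100,
                       motion_step = c(trans_mm = 0.01, rot_rad = 2e-4),
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_per_group, 2L))
    stopf("n_per_group must be an integer >= 2")
  if (!is_count(cfg$n_volumes, 32L))
    stopf("n_volumes must be an integer >= 32 (the band-limited generator needs headroom for its filters)")
  if (!(cfg$tr_seconds > 0)) stopf("tr_seconds must be positive")
  if (!inherits(cfg$grid, "bold_grid")) stopf("grid must be a bold_grid")
  if (!is_count(cfg$n_latent_networks, 2L))
    stopf("n_latent_networks must be an integer >= 2")
  systems <- unique(cfg$roi_table$system)
  if (cfg$n_latent_networks < length(systems))
    stopf("need at least one latent network per ROI system")
  eff <- cfg$effect_size_per_system
  if (!all(systems %in% names(eff)))
    stopf("effect_size_per_system must name every ROI system (missing: %s)",
          paste(setdiff(systems, names(eff)), collapse = ", "))
  if (any(abs(eff) >= 1)) stopf("effect sizes must satisfy |effect| < 1")
  if (cfg$within_group_sd < 0) stopf("within_group_sd must be >= 0")
  # Reject group-level coupling targets that cannot come from a valid
  # (positive semi-definite) joint correlation matrix.
  nets <- assign_system_networks(systems, cfg$n_latent_networks)
  for (g in c("control", "patient")) {
    C <- group_coupling(cfg, g, nets)
    plant_covariance(C, label = sprintf("%s group", g))
  }
  invisible(cfg)
}

# Round-robin assignment of latent networks to ROI systems (contiguous
# blocks of floor(K / n_systems) networks each).
assign_system_networks <- function(systems, k) {
  m <- k %/% length(systems)
  out <- lapply(seq_along(systems), function(i) seq.int((i - 1L) * m + 1L,
                                                        i * m))
  names(out) <- systems
  out
}

# Group-level target ROI x network coupling matrix (no subject jitter).
group_coupling <- function(cfg, group, nets = NULL) {
  systems <- unique(cfg$roi_table$system)
  if (is.null(nets)) nets <- assign_system_networks(systems,
                                                    cfg$n_latent_networks)
  C <- matrix(0, nrow(cfg$roi_table), cfg$n_latent_networks,
              dimnames = list(cfg$roi_table$name,
                              sprintf("network_%02d",
                                      seq_len(cfg$n_latent_networks))))
  for (s in systems) {
    val <- cfg$baseline_coupling +
      if (group == "patient") cfg$effect_size_per_system[[s]] else 0
    C[cfg$roi_table$system == s, nets[[s]]] <- val
  }
  C
}

#' Joint correlation target for planted network and ROI series
#'
#' Builds the `(K + R) x (K + R)` joint correlation matrix implied by a
#' ROI-by-network coupling matrix `C`: networks are mutually uncorrelated,
#' `cor(roi, network)` blocks equal `C`, and ROI-ROI correlations are those
#' induced by shared network drive (`C C^T` off the diagonal). The matrix is
#' checked for positive semi-definiteness; an indefinite request is projected
#' to the nearest correlation matrix (eigenvalue clipping, diagonal
#' rescaling). Adjustments with Frobenius norm above `1e-6` raise a warning
#' and above `0.05` an error naming the offending system block.
#'
#' @param C ROI x network coupling matrix (rownames = ROI names).
#' @param systems optional character vector of per-ROI system labels, used in
#'   diagnostics.
#' @param label context string for diagnostics.
#' @return The (possibly adjusted) joint correlation matrix, networks first.
#' @export
plant_covariance <- function(C, systems = NULL, label = "planted coupling") {
  k <- ncol(C); r <- nrow(C)
  d <- 1 - rowSums(C^2)
  sigma <- rbind(cbind(diag(k), t(C)),
                 cbind(C, C %*% t(C) + diag(d, r)))
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) >= -1e-12) return(sigma)
  offending <- rownames(C)[d < 0]
  sysmsg <- if (!is.null(systems)) {
    paste(unique(systems[d < 0]), collapse = ", ")
  } else paste(offending, collapse = ", ")
  vals <- pmax(ev$values, 0)
  adj <- ev$vectors %*% (vals * t(ev$vectors))
  s <- sqrt(diag(adj)); s[s <= 0] <- 1
  adj <- adj / tcrossprod(s)
  delta <- sqrt(sum((adj - sigma)^2))
  if (delta > 0.05)
    stopf(paste0("%s: joint covariance is not positive semi-definite ",
                 "(nearest-correlation adjustment %.3g); offending block: %s"),
          label, delta, sysmsg)
  if (delta > 1e-6)
    warnf("%s: covariance adjusted to nearest correlation matrix (%.3g)",
          label, delta)
  adj
}

# Band-limited unit-variance noise: white Gaussian noise low-pass filtered
# below `cutoff_hz` (4th-order Butterworth, zero phase), then standardized.
band_limited_noise <- function(n, ncol, tr_seconds, cutoff_hz = 0.1) {
  x <- matrix(rnorm(n * ncol), n, ncol)
  w <- cutoff_hz / (1 / (2 * tr_seconds))
  bf <- signal::butter(4, min(w, 0.99), type = "low")
  x <- apply(x, 2L, function(col) signal::filtfilt(bf, col))
  zscore_cols(matrix(x, n, ncol))
}

# Deterministic latent network maps: Gaussian blobs (sigma 8 mm) on a dorsal
# lattice, mutually separated so each map has a disjoint-dominant peak.
make_network_maps <- function(grid, k, sigma_mm = 8) {
  ext <- grid_extent(grid)
  span <- function(a, b, n) if (n == 1) (a + b) / 2 else seq(a, b, length.out = n)
  xs <- span(ext["lo", 1] + 10, ext["hi", 1] - 10, 4)
  ys <- span(ext["lo", 2] + 12, ext["hi", 2] - 12, max(2, ceiling(k / 8)) * 2)
  zs <- span(max(ext["lo", 3], 7.5), ext["hi", 3] - 5, 2)
  cand <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  if (nrow(cand) < k)
    stopf("grid too small to place %d separated network blobs", k)
  # deterministic farthest-point ordering keeps blob peaks well separated
  sel <- 1L
  while (length(sel) < k) {
    d2min <- apply(cand, 1L, function(p)
      min(colSums((t(cand[sel, , drop = FALSE]) - p)^2)))
    d2min[sel] <- -1
    sel <- c(sel, which.max(d2min))
  }
  centers <- cand[sel, , drop = FALSE]
  ctr <- voxel_centers(grid)
  maps <- vapply(seq_len(k), function(i) {
    d2 <- (ctr[, 1] - centers[i, 1])^2 + (ctr[, 2] - centers[i, 2])^2 +
      (ctr[, 3] - centers[i, 3])^2
    m <- exp(-d2 / (2 * sigma_mm^2))
    m[m < 0.01] <- 0
    m
  }, numeric(nrow(ctr)))
  t(maps)  # k x voxels
}

# Broad nuisance spatial patterns and the tissue masks used to extract the
# corresponding mean signals downstream. Blob centers are placed at fixed
# fractions of the grid extent so any grid yields non-empty masks.
make_nuisance_maps <- function(grid) {
  ctr <- voxel_centers(grid)
  ext <- grid_extent(grid)
  at <- function(frac) ext["lo", ] + frac * (ext["hi", ] - ext["lo", ])
  blob <- function(cen, sigma) {
    d2 <- (ctr[, 1] - cen[1])^2 + (ctr[, 2] - cen[2])^2 +
      (ctr[, 3] - cen[3])^2
    exp(-d2 / (2 * sigma^2))
  }
  wm <- blob(at(c(0.5, 0.5, 0.65)), 15)
  csf <- blob(at(c(0.5, 0.3, 0.35)), 10)
  nearest <- function(cen) which.min((ctr[, 1] - cen[1])^2 +
                                       (ctr[, 2] - cen[2])^2 +
                                       (ctr[, 3] - cen[3])^2)
  wm_mask <- which(wm > 0.5)
  if (!length(wm_mask)) wm_mask <- nearest(at(c(0.5, 0.5, 0.65)))
  csf_mask <- setdiff(which(csf > 0.5), wm_mask)
  if (!length(csf_mask)) csf_mask <- nearest(at(c(0.5, 0.3, 0.35)))
  gm_mask <- setdiff(seq_len(nrow(ctr)), union(wm_mask, csf_mask))
  list(maps = list(global = rep(1, nrow(ctr)), wm = wm, csf = csf),
       masks = list(gm = gm_mask, wm = wm_mask, csf = csf_mask))
}

new_volume_series <- function(data, grid, tr_seconds) {
  structure(list(data = data, grid = grid, tr_seconds = tr_seconds),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  cat(sprintf("<volume_series> %d voxels x %d volumes, TR %g s\n",
              nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

n_timepoints <- function(series) ncol(series$data)

#' Generate a synthetic two-group BOLD cohort
#'
#' See [sim_config()] for the generative model. Controls come first
#' (`sub-01` ...), then patients. The returned ground truth carries
#' everything needed for recovery testing: latent network maps and per-subject
#' time courses, planted per-subject coupling matrices, planted ROI signal
#' time courses, nuisance maps/time courses/masks, ROI masks and group labels.
#'
#' @param config a [sim_config()].
#' @return A `bold_cohort`: list with `subjects` (list of `volume_series`),
#'   `motion` (list of `motion_trace`) and `truth`.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  grid <- config$grid
  V <- n_voxels(grid)
  T_ <- config$n_volumes
  k <- config$n_latent_networks
  n <- 2L * config$n_per_group
  systems <- unique(config$roi_table$system)
  nets <- assign_system_networks(systems, k)
  masks <- make_roi_masks(config$roi_table, grid)
  R <- length(masks)
  maps <- make_network_maps(grid, k)
  nui <- make_nuisance_maps(grid)
  labels <- rep(c("control", "patient"), each = config$n_per_group)
  ids <- sprintf("sub-%02d", seq_len(n))
  roi_sys <- config$roi_table$system

  with_seed(config$seed, {
    subjects <- vector("list", n)
    motion <- vector("list", n)
    nw_tcs <- vector("list", n)
    roi_sigs <- vector("list", n)
    couplings <- vector("list", n)
    nui_tcs <- vector("list", n)
    for (s in seq_len(n)) {
      C <- group_coupling(config, labels[s], nets)
      if (config$within_group_sd > 0) {
        jit <- matrix(rnorm(R * k, sd = config$within_group_sd), R, k)
        jit[C == 0] <- 0
        C <- C + jit
      }
      C[C > 0.9] <- 0.9; C[C < -0.9] <- -0.9
      rn <- sqrt(rowSums(C^2))
      over <- rn > 0.95
      if (any(over)) C[over, ] <- C[over, ] * (0.95 / rn[over])
      sigma <- plant_covariance(C, systems = roi_sys,
                                label = sprintf("subject %s", ids[s]))
      z <- band_limited_noise(T_, k + R, config$tr_seconds)
      joint <- z %*% chol(sigma)
      nw <- joint[, seq_len(k), drop = FALSE]
      rs <- joint[, k + seq_len(R), drop = FALSE]
      colnames(nw) <- colnames(C)
      colnames(rs) <- rownames(C)

      g_tc <- band_limited_noise(T_, 3L, config$tr_seconds)
      g_tc[, 1] <- g_tc[, 1] + seq(-1, 1, length.out = T_)  # scanner drift
      amp <- config$nuisance_amplitudes

      # One BLAS call assembles all structured signal (networks, nuisance,
      # constant baseline): spatial loadings (V x (k+4)) times time courses.
      spatial <- cbind(config$network_amplitude * t(maps),
                       nui$maps$global, nui$maps$wm, nui$maps$csf,
                       rep(1, V))
      tcs <- cbind(nw,
                   amp[["global"]] * g_tc[, 1], amp[["wm"]] * g_tc[, 2],
                   amp[["csf"]] * g_tc[, 3],
                   rep(config$baseline_intensity, T_))
      Y <- matrix(rnorm(V * T_, sd = config$noise_sd), V, T_)
      Y <- Y + tcrossprod(spatial, tcs)
      for (j in seq_len(R))
        Y[masks[[j]]$voxels, ] <-
          Y[masks[[j]]$voxels, ] +
          config$roi_amplitude * rep(rs[, j], each = length(masks[[j]]$voxels))

      subjects[[s]] <- new_volume_series(Y, grid, config$tr_seconds)
      motion[[s]] <- random_walk_motion(T_, config$motion_step)
      nw_tcs[[s]] <- nw
      roi_sigs[[s]] <- rs
      couplings[[s]] <- C
      nui_tcs[[s]] <- g_tc
    }
    names(subjects) <- names(motion) <- ids
    truth <- list(network_maps = maps,
                  network_tcs = nw_tcs,
                  roi_signals = roi_sigs,
                  planted_coupling = couplings,
                  group_labels = labels,
                  subject_ids = ids,
                  roi_masks = masks,
                  system_networks = nets,
                  nuisance = list(maps = nui$maps, masks = nui$masks,
                                  tcs = nui_tcs),
                  config = config)
    structure(list(subjects = subjects, motion = motion, truth = truth),
              class = "bold_cohort")
  })
}

#' @export
print.bold_cohort <- function(x, ...) {
  tab <- table(x$truth$group_labels)
  cat(sprintf("<bold_cohort> %d subjects (%s), %d volumes, %d voxels, TR %g s\n",
              length(x$subjects),
              paste(sprintf("%d %s", tab, names(tab)), collapse = " + "),
              n_timepoints(x$subjects[[1]]), nrow(x$subjects[[1]]$data),
              x$subjects[[1]]$tr_seconds))
  invisible(x)
}
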