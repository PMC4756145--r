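# Shared fixtures and independent oracles used across the suite.

# -- small-scale simulation fixtures -----------------------------------------

tiny_grid <- function(n = 10L) {
  half <- (n - 1) * 5 / 2
  bold_grid(rep(n, 3L), c(5, 5, 5), rep(-half, 3L))
}

tiny_roi_table <- function(radius_mm = 6) {
  data.frame(
    name = c("striatum_L", "cerebellum_L", "hippocampus_R", "amygdala_R"),
    system = c("striatum", "cerebellum", "MTL", "amygdala"),
    hemisphere = c("left", "left", "right", "right"),
    x = c(-10, -10, 10, 10), y = c(-10, 10, -10, 10), z = -10,
    radius_mm = radius_mm, stringsAsFactors = FALSE)
}

tiny_sim_config <- function(seed = 1L, n_per_group = 5L, n_volumes = 100L,
                            ...) {
  sim_config(n_per_group = n_per_group, n_volumes = n_volumes,
             grid = tiny_grid(), n_latent_networks = 4L,
             roi_table = tiny_roi_table(), seed = seed, ...)
}

tiny_run_config <- function(seed = 1L, ...) {
  run_config(sim = tiny_sim_config(seed = 0L, ...),
             ica = ica_config(n_group_components = 6L, n_icasso_runs = 2L,
                              max_iter = 60L, tol = 1e-4),
             seed = seed)
}

# -- brute-force lattice oracle for spherical masks --------------------------

# Count integer lattice points within Euclidean distance `r_vox` (in voxel
# units) of the origin: the expected mask size for a sphere centered on a
# voxel center of an isotropic grid.
sphere_lattice_count <- function(r_vox) {
  r <- ceiling(r_vox)
  n <- 0L
  for (i in -r:r) for (j in -r:r) for (k in -r:r)
    if (i^2 + j^2 + k^2 <= r_vox^2 + 1e-9) n <- n + 1L
  n
}

# -- exhaustive-enumeration oracle for the paired binomial test --------------

# P(Bin(N, 1/2) >= W) by enumerating all 2^N equally likely discordance
# sign patterns.
binom_enum_upper <- function(W, N) {
  if (N == 0L) return(1)
  wins <- vapply(0:(2^N - 1L), function(m)
    sum(bitwAnd(m, bitwShiftL(1L, 0:(N - 1L))) != 0L), integer(1))
  mean(wins >= W)
}

# -- interior-point QP oracle for the SVM dual -------------------------------

# Solves min 1/2 a' Q a - 1'a  s.t.  y'a = 0, 0 <= a <= C with kernlab's
# interior-point solver; returns alpha, dual objective, w, b and decision
# values. Entirely independent of the package's SMO path.
svm_qp_oracle <- function(X, y01, C = 1) {
  y <- ifelse(y01 == 1, 1, -1)
  n <- nrow(X)
  K <- tcrossprod(X)
  Q <- (y %o% y) * K + diag(1e-7, n)
  fit <- NULL
  for (sigf in c(9, 8, 7)) {     # tightest precision the solver sustains
    fit <- try(kernlab::ipop(c = matrix(-1, n), H = Q, A = matrix(y, 1),
                             b = 0, l = matrix(0, n), u = matrix(C, n),
                             r = 0, sigf = sigf, maxiter = 200),
               silent = TRUE)
    if (!inherits(fit, "try-error")) break
  }
  alpha <- as.numeric(kernlab::primal(fit))
  w <- drop(crossprod(X, alpha * y))
  # b as the midpoint of the KKT-admissible interval computed from the
  # oracle's own solution (robust to interior-point bound smoothing)
  ths <- 1e-3 * C
  u <- drop(X %*% w)
  g <- y - u
  i_up <- (y > 0 & alpha < C - ths) | (y < 0 & alpha > ths)
  i_low <- (y > 0 & alpha > ths) | (y < 0 & alpha < C - ths)
  b <- (max(g[i_up]) + min(g[i_low])) / 2
  obj <- sum(alpha) - 0.5 * drop(crossprod(alpha * y, K %*% (alpha * y)))
  list(alpha = alpha, objective = obj, w = w, b = b,
       decision = drop(X %*% w + b))
}

# Principal angles between the column spaces of two matrices.
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  sv <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(sv, -1), 1))
}

# Disjoint-support sparse spatial sources (super-Gaussian, exactly
# uncorrelated supports) for ICA recovery tests.
planted_sparse_sources <- function(k, n_vox, frac = 0.05) {
  S <- matrix(0, k, n_vox)
  per <- floor(n_vox * frac)
  for (i in seq_len(k)) {
    idx <- ((i - 1L) * per + 1L):(i * per)
    S[i, idx] <- rnorm(per, mean = 3, sd = 0.5) *
      sample(c(-1, 1), per, replace = TRUE)
  }
  S
}

# Pair components to references by greedy absolute correlation.
match_abs_cor <- function(est, ref) {
  cc <- abs(cor(t(est), t(ref)))
  best <- numeric(nrow(ref))
  used <- rep(FALSE, nrow(est))
  for (j in order(-apply(cc, 2, max))) {
    i <- order(-cc[, j])
    i <- i[!used[i]][1]
    used[i] <- TRUE
    best[j] <- cc[i, j]
  }
  best
}
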