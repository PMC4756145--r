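#' Configure group spatial ICA
#'
#' @param n_group_components number of group components (desk default 8; the
#'   emulated full design uses 75).
#' @param n_subject_pcs temporal principal components kept per subject in the
#'   first reduction step; default `ceiling(1.5 * n_group_components)`,
#'   capped by the data rank at run time.
#' @param n_icasso_runs number of infomax restarts clustered for stability
#'   (desk default 10; full design 40).
#' @param learning_rate initial natural-gradient step size.
#' @param max_iter maximum infomax epochs.
#' @param tol convergence tolerance on the maximum absolute weight change
#'   per epoch.
#' @param bootstrap resample voxels (with replacement) in each ICASSO run in
#'   addition to varying the seed (default FALSE).
#' @param seed integer seed; run `r` of ICASSO uses a child seed derived from
#'   it.
#' @return An `ica_config`.
#' @export
ica_config <- function(n_group_components = 8L,
                       n_subject_pcs = NULL,
                       n_icasso_runs = 10L,
                       learning_rate = 0.01,
                       max_iter = 200L,
                       tol = 1e-5,
                       bootstrap = FALSE,
                       seed = 1L) {
  if (!is_count(n_group_components, 2L))
    stopf("n_group_components must be an integer >= 2")
  if (is.null(n_subject_pcs))
    n_subject_pcs <- as.integer(ceiling(1.5 * n_group_components))
  if (!is_count(n_subject_pcs, 1L))
    stopf("n_subject_pcs must be a positive integer")
  if (!is_count(n_icasso_runs, 1L))
    stopf("n_icasso_runs must be a positive integer")
  structure(list(n_group_components = as.integer(n_group_components),
                 n_subject_pcs = as.integer(n_subject_pcs),
                 n_icasso_runs = as.integer(n_icasso_runs),
                 learning_rate = learning_rate, max_iter = as.integer(max_iter),
                 tol = tol, bootstrap = isTRUE(bootstrap),
                 seed = as.integer(seed)),
            class = "ica_config")
}

#' Two-step PCA reduction of temporally concatenated subjects
#'
#' Step 1: each subject's voxel x time matrix is row-centered (voxel means
#' removed) and projected onto its top `n_subject_pcs` temporal principal
#' components. Step 2: the reduced subject matrices are concatenated along
#' the reduced-time axis and projected onto the top `n_group_components`
#' group principal components. Both steps are deterministic (eigenvector
#' signs fixed by making each vector's largest-magnitude entry positive).
#'
#' @param subject_data list of voxel x time matrices on a shared grid.
#' @param cfg an [ica_config()].
#' @return List: `X` (voxel x n_group_components reduced group matrix),
#'   `subject_ops` (per subject: `basis` time x p, `row_means`), `group_op`
#'   (concatenated-dim x n_group_components), `evals` (group eigenvalues).
#' @export
concat_reduce <- function(subject_data, cfg) {
  V <- nrow(subject_data[[1]])
  if (!all(vapply(subject_data, nrow, 1L) == V))
    stopf("all subjects must share the voxel grid")
  p <- cfg$n_subject_pcs
  fix_sign <- function(v) {
    j <- which.max(abs(v)); if (v[j] < 0) -v else v
  }
  subject_ops <- vector("list", length(subject_data))
  reduced <- vector("list", length(subject_data))
  for (s in seq_along(subject_data)) {
    Y <- subject_data[[s]]
    if (p > min(dim(Y)))
      stopf("n_subject_pcs (%d) exceeds the rank bound of subject %d (%d)",
            p, s, min(dim(Y)))
    mu <- rowMeans(Y)
    Yc <- Y - mu
    ct <- crossprod(Yc)                  # T x T temporal covariance (x V)
    ev <- eigen(ct, symmetric = TRUE)
    basis <- apply(ev$vectors[, seq_len(p), drop = FALSE], 2L, fix_sign)
    subject_ops[[s]] <- list(basis = basis, row_means = mu)
    reduced[[s]] <- Yc %*% basis         # V x p
  }
  G <- do.call(cbind, reduced)
  k <- cfg$n_group_components
  if (k > min(dim(G)))
    stopf("n_group_components (%d) exceeds the rank bound of the %s",
          k, sprintf("concatenated reduced matrix (%d x %d)", nrow(G),
                     ncol(G)))
  ev2 <- eigen(crossprod(G), symmetric = TRUE)
  group_op <- apply(ev2$vectors[, seq_len(k), drop = FALSE], 2L, fix_sign)
  list(X = G %*% group_op, subject_ops = subject_ops, group_op = group_op,
       evals = ev2$values[seq_len(k)])
}

# Reconstruct one subject's (centered+mean) data from its step-1 reduction;
# exact when the data are rank <= n_subject_pcs.
reconstruct_subject <- function(reduction, subject_data, s) {
  op <- reduction$subject_ops[[s]]
  Yc <- (subject_data[[s]] - op$row_means) %*% op$basis
  Yc %*% t(op$basis) + op$row_means
}

#' Infomax independent component analysis
#'
#' Natural-gradient infomax with the logistic nonlinearity (Bell-Sejnowski),
#' suited to the super-Gaussian spatial sources of BOLD networks. The input
#' is whitened internally; learning proceeds in mini-batches over randomly
#' permuted samples, with the learning rate annealed whenever the weight
#' update oscillates, until the per-epoch weight change falls below `tol` or
#' `max_iter` epochs elapse. Non-convergence is flagged, not silent.
#'
#' @param X channels x samples matrix (e.g. the transposed reduced group
#'   matrix: components in rows, voxels as samples).
#' @param cfg an [ica_config()]; uses `learning_rate`, `max_iter`, `tol`,
#'   `seed`.
#' @param seed optional seed overriding `cfg$seed` (used by ICASSO restarts).
#' @return List: `sources` (k x samples, unit variance rows), `unmixing`
#'   (k x k, sources = unmixing %*% centered X), `mixing` (its inverse),
#'   `converged`, `iterations`.
#' @export
infomax_ica <- function(X, cfg = ica_config(), seed = NULL) {
  if (is.null(seed)) seed <- cfg$seed
  k <- nrow(X); n <- ncol(X)
  if (k >= n) stopf("need more samples than channels for ICA (%d x %d)", k, n)
  mu <- rowMeans(X)
  Xc <- X - mu
  cv <- tcrossprod(Xc) / (n - 1L)
  ev <- eigen(cv, symmetric = TRUE)
  if (min(ev$values) <= 1e-12 * max(ev$values))
    stopf("input is rank deficient; reduce the number of components")
  wh <- diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
  Xw <- wh %*% Xc
  with_seed(seed, {
    # random orthogonal start: multi-run stability analysis relies on runs
    # exploring genuinely different initializations
    W <- qr.Q(qr(matrix(rnorm(k * k), k)))
    lr <- cfg$learning_rate
    block <- as.integer(min(max(64L, floor(sqrt(n))), 512L))
    last_change <- Inf
    converged <- FALSE
    it <- 0L
    while (it < cfg$max_iter) {
      it <- it + 1L
      W_old <- W
      perm <- sample.int(n)
      starts <- seq.int(1L, n, by = block)
      for (b in starts) {
        idx <- perm[b:min(b + block - 1L, n)]
        u <- W %*% Xw[, idx, drop = FALSE]
        y <- 1 / (1 + exp(-u))
        nb <- length(idx)
        W <- W + (lr / nb) * (nb * diag(k) + (1 - 2 * y) %*% t(u)) %*% W
        if (!all(is.finite(W)) || max(abs(W)) > 1e8) {
          # diverged: restart colder from a fresh rotation
          W <- qr.Q(qr(matrix(rnorm(k * k), k)))
          lr <- lr / 2; last_change <- Inf
          break
        }
      }
      change <- max(abs(W - W_old))
      if (change > last_change) lr <- lr * 0.9
      last_change <- change
      if (change < cfg$tol) { converged <- TRUE; break }
    }
    if (!converged)
      warnf("infomax did not reach tol %.1e in %d epochs (last change %.2e)",
            cfg$tol, cfg$max_iter, last_change)
    S <- W %*% Xw
    sc <- apply(S, 1L, sd); sc[sc <= 0] <- 1
    S <- S / sc
    unmix <- (W %*% wh) / sc
    list(sources = S, unmixing = unmix, mixing = solve(unmix),
         converged = converged, iterations = it)
  })
}

#' ICASSO-style stability analysis of infomax components
#'
#' Runs infomax `n_icasso_runs` times with different child seeds (optionally
#' also bootstrap-resampling the samples), pools all estimated components,
#' clusters them by absolute spatial correlation (average-linkage
#' agglomerative clustering on the distance `1 - |r|`, cut at
#' `n_group_components` clusters) and returns each cluster's centrotype (the
#' member with the highest total within-cluster similarity). The stability
#' index of a cluster is its mean within-cluster `|r|` minus its mean
#' between-cluster `|r|`; values near 1 indicate a component re-estimated
#' almost identically in every run.
#'
#' @param X channels x samples matrix (as in [infomax_ica()]).
#' @param cfg an [ica_config()].
#' @return A `component_set`: `maps` (k x samples, z-scaled across samples),
#'   `stability` (length k, `NA` when `n_icasso_runs == 1`), `runs_converged`,
#'   `provenance = "group"`. Components are ordered by decreasing stability.
#' @export
icasso_stability <- function(X, cfg = ica_config()) {
  k <- cfg$n_group_components
  if (nrow(X) != k)
    stopf("X must have n_group_components (%d) rows, got %d", k, nrow(X))
  runs <- cfg$n_icasso_runs
  comp <- vector("list", runs)
  conv <- logical(runs)
  for (r in seq_len(runs)) {
    Xr <- X
    if (cfg$bootstrap && runs > 1L)
      Xr <- with_seed(child_seed(cfg$seed, 1000L + r),
                      X[, sample.int(ncol(X), replace = TRUE), drop = FALSE])
    fit <- infomax_ica(Xr, cfg, seed = child_seed(cfg$seed, r))
    if (cfg$bootstrap && runs > 1L) {
      # express bootstrap-run components on the original samples
      fit$sources <- fit$unmixing %*% (X - rowMeans(X))
    }
    comp[[r]] <- fit$sources
    conv[r] <- fit$converged
  }
  if (runs == 1L) {
    warnf("stability is undefined for a single ICASSO run; returning NA")
    maps <- zscore_rows(comp[[1]])
    return(new_component_set(maps, stability = rep(NA_real_, k),
                             runs_converged = conv))
  }
  all_maps <- do.call(rbind, comp)              # (runs*k) x samples
  sim <- abs(cor(t(all_maps)))
  sim[!is.finite(sim)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  cl <- stats::cutree(hc, k = k)
  if (length(unique(cl)) < k)
    warnf("found only %d distinct clusters for %d requested components",
          length(unique(cl)), k)
  maps <- matrix(0, k, ncol(X))
  stab <- numeric(k)
  for (g in seq_len(k)) {
    members <- which(cl == g)
    within <- sim[members, members, drop = FALSE]
    between <- sim[members, -members, drop = FALSE]
    centro <- members[which.max(rowSums(within))]
    maps[g, ] <- all_maps[centro, ]
    w_mean <- if (length(members) > 1L)
      mean(within[upper.tri(within)]) else 1
    b_mean <- if (length(members) < nrow(sim)) mean(between) else 0
    stab[g] <- w_mean - b_mean
  }
  ord <- order(stab, decreasing = TRUE)
  new_component_set(zscore_rows(maps[ord, , drop = FALSE]),
                    stability = stab[ord], runs_converged = conv)
}

new_component_set <- function(maps, timecourses = NULL, stability = NULL,
                              runs_converged = NULL, provenance = "group") {
  rownames(maps) <- sprintf("IC_%02d", seq_len(nrow(maps)))
  structure(list(maps = maps, timecourses = timecourses,
                 stability = stability, runs_converged = runs_converged,
                 provenance = provenance),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d components x %d voxels (%s)\n",
              nrow(x$maps), ncol(x$maps), x$provenance))
  if (!is.null(x$stability) && !all(is.na(x$stability)))
    cat("  stability:", paste(sprintf("%.2f", x$stability), collapse = " "),
        "\n")
  invisible(x)
}

#' Back-reconstruct subject components by dual regression
#'
#' Spatio-temporal (dual) regression: each subject's time courses are the
#' least-squares regression of the subject's (row-centered) data on the
#' group spatial maps; the subject's spatial maps are then the regression of
#' the data on those time courses. Subject maps are z-scaled across voxels.
#'
#' @param group a `component_set` of group maps (k x voxels).
#' @param subject_data list of voxel x time matrices, same grid as the maps.
#' @return List of per-subject `component_set`s, each with `maps`
#'   (k x voxels) and `timecourses` (time x k).
#' @export
back_reconstruct <- function(group, subject_data) {
  M <- t(group$maps)                             # V x k
  gram <- crossprod(M)
  if (rcond(gram) < 1e-12)
    stopf("group spatial maps are (near) rank deficient; cannot dual-regress")
  proj <- solve(gram, t(M))                      # k x V
  lapply(seq_along(subject_data), function(s) {
    Y <- subject_data[[s]]
    if (nrow(Y) != nrow(M))
      stopf("subject %d is not on the group voxel grid", s)
    Yc <- Y - rowMeans(Y)
    tc <- t(proj %*% Yc)                         # T x k
    g2 <- crossprod(tc)
    maps_s <- if (rcond(g2) > 1e-12) t(solve(g2, crossprod(tc, t(Yc))))
              else matrix(0, nrow(M), ncol(M))   # degenerate (e.g. zero data)
    sdv <- apply(maps_s, 2L, sd)
    nz <- sdv > 0
    maps_s[, nz] <- scale(maps_s[, nz, drop = FALSE])
    colnames(tc) <- rownames(group$maps)
    new_component_set(t(maps_s), timecourses = tc,
                      provenance = sprintf("subject_%d", s))
  })
}

#' Match spatial templates to estimated components
#'
#' For each template map, a multiple spatial regression of the template on
#' all component maps is performed; the goodness of a (template, component)
#' pair is the standardized regression coefficient (set
#' `method = "correlation"` for plain spatial correlation instead).
#' Assignment is greedy in descending goodness, without replacement, so each
#' component serves at most one template; ties break deterministically on the
#' lower template, then component, index.
#'
#' @param components a `component_set` (k x voxels).
#' @param templates matrix (templates x voxels) or `component_set`; row
#'   names are template names.
#' @param method `"regression"` (default) or `"correlation"`.
#' @return data.frame with columns `template`, `component` (index into the
#'   component set), `goodness`, ordered by template.
#' @export
match_templates <- function(components, templates,
                            method = c("regression", "correlation")) {
  method <- match.arg(method)
  tm <- if (inherits(templates, "component_set")) templates$maps
        else as.matrix(templates)
  if (is.null(rownames(tm))) rownames(tm) <- sprintf("template_%02d",
                                                     seq_len(nrow(tm)))
  cm <- components$maps
  if (ncol(tm) != ncol(cm))
    stopf("templates (%d voxels) and components (%d voxels) differ in grid",
          ncol(tm), ncol(cm))
  if (nrow(tm) > nrow(cm))
    stopf("more templates (%d) than components (%d)", nrow(tm), nrow(cm))
  G <- matrix(NA_real_, nrow(tm), nrow(cm))
  if (method == "correlation") {
    G <- cor(t(tm), t(cm))
  } else {
    Xs <- scale(t(cm))                           # V x k standardized
    gram <- crossprod(Xs)
    for (i in seq_len(nrow(tm))) {
      y <- scale(tm[i, ])
      G[i, ] <- solve(gram, crossprod(Xs, y))
    }
  }
  score <- abs(G)
  assign_t <- integer(nrow(tm)); assign_c <- integer(nrow(tm))
  good <- numeric(nrow(tm))
  open_t <- rep(TRUE, nrow(tm)); open_c <- rep(TRUE, nrow(cm))
  for (step in seq_len(nrow(tm))) {
    sub <- score
    sub[!open_t, ] <- -Inf; sub[, !open_c] <- -Inf
    best <- which(sub == max(sub), arr.ind = TRUE)
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
    assign_t[step] <- best[1L]; assign_c[step] <- best[2L]
    good[step] <- G[best[1L], best[2L]]
    open_t[best[1L]] <- FALSE; open_c[best[2L]] <- FALSE
  }
  ord <- order(assign_t)
  data.frame(template = rownames(tm)[assign_t[ord]],
             component = assign_c[ord], goodness = good[ord],
             stringsAsFactors = FALSE)
}
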