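test_that("two-step PCA reduction is lossless on low-rank data", {
  set.seed(10)
  k <- 4L
  subj <- lapply(1:3, function(s) {
    U <- matrix(rnorm(500 * k), 500)
    W <- matrix(rnorm(k * 60), k)
    U %*% W                       # exactly rank k
  })
  cfg <- ica_config(n_group_components = 3L, n_subject_pcs = k)
  red <- concat_reduce(subj, cfg)
  for (s in 1:3)
    expect_lt(max(abs(netconsist:::reconstruct_subject(red, subj, s) -
                        subj[[s]])) / max(abs(subj[[s]])), 1e-8)
})

test_that("one subject's two-step reduction equals direct PCA", {
  set.seed(11)
  Y <- matrix(rnorm(400 * 50), 400)
  cfg <- ica_config(n_group_components = 5L, n_subject_pcs = 12L)
  red <- concat_reduce(list(Y), cfg)
  Yc <- Y - rowMeans(Y)
  direct <- Yc %*% eigen(crossprod(Yc), symmetric = TRUE)$vectors[, 1:5]
  expect_lt(max(principal_angles(red$X, direct)), 1e-6)
})

test_that("the group subspace is invariant to subject order", {
  set.seed(12)
  subj <- lapply(1:4, function(s) matrix(rnorm(300 * 40), 300))
  cfg <- ica_config(n_group_components = 6L, n_subject_pcs = 8L)
  r1 <- concat_reduce(subj, cfg)
  r2 <- concat_reduce(subj[c(3, 1, 4, 2)], cfg)
  expect_lt(max(principal_angles(r1$X, r2$X)), 1e-6)
  expect_error(concat_reduce(subj, ica_config(n_group_components = 6L,
                                              n_subject_pcs = 50L)),
               "rank")
})

test_that("infomax recovers planted sparse spatial sources", {
  set.seed(13)
  S <- planted_sparse_sources(3L, 5000L)
  A <- matrix(rnorm(9), 3)
  X <- A %*% S
  fit <- infomax_ica(X, ica_config(n_group_components = 3L, max_iter = 400L,
                                   tol = 1e-7), seed = 1L)
  expect_true(all(match_abs_cor(fit$sources, S) >= 0.95))
  expect_true(fit$converged)
  # already-independent input comes back as a signed permutation
  fit0 <- infomax_ica(S, ica_config(n_group_components = 3L,
                                    max_iter = 400L, tol = 1e-7), seed = 2L)
  cc <- abs(cor(t(fit0$sources), t(S)))
  expect_true(all(apply(cc, 1, max) > 0.99))
  expect_true(all(sort(round(cc, 1)) %in% c(0, 1)))
  # determinism contract
  fit2 <- infomax_ica(X, ica_config(n_group_components = 3L,
                                    max_iter = 400L, tol = 1e-7), seed = 1L)
  expect_identical(fit$sources, fit2$sources)
})

test_that("ICASSO separates stable planted structure from noise", {
  set.seed(14)
  S <- planted_sparse_sources(4L, 4000L)
  X <- matrix(rnorm(16), 4) %*% S
  cfg <- ica_config(n_group_components = 4L, n_icasso_runs = 5L,
                    max_iter = 300L, tol = 1e-6)
  cs <- icasso_stability(X, cfg)
  expect_s3_class(cs, "component_set")
  expect_true(all(cs$stability >= 0.95))
  expect_equal(dim(cs$maps), c(4L, 4000L))
  # pure-noise input: markedly lower stability
  Xn <- matrix(rnorm(4 * 4000), 4)
  csn <- suppressWarnings(icasso_stability(Xn, cfg))
  expect_lt(min(csn$stability), min(cs$stability))
  expect_lt(mean(csn$stability), 0.9)
  # single run: stability undefined
  expect_warning(
    cs1 <- icasso_stability(X, ica_config(n_group_components = 4L,
                                          n_icasso_runs = 1L,
                                          max_iter = 300L)),
    "undefined")
  expect_true(all(is.na(cs1$stability)))
})

test_that("dual regression recovers planted subject time courses", {
  set.seed(15)
  k <- 4L; V <- 2000L; T_ <- 80L
  maps <- netconsist:::zscore_rows(planted_sparse_sources(k, V))
  group <- netconsist:::new_component_set(maps)
  tcs <- lapply(1:3, function(s) matrix(rnorm(T_ * k), T_))
  clean <- lapply(tcs, function(tc) t(maps) %*% t(tc))
  out <- back_reconstruct(group, clean)
  for (s in 1:3)
    for (j in 1:k)
      expect_gt(abs(cor(out[[s]]$timecourses[, j], tcs[[s]][, j])), 0.999)
  # zero data give zero time courses and maps
  z <- back_reconstruct(group, list(matrix(0, V, T_)))
  expect_equal(max(abs(z[[1]]$timecourses)), 0)
  expect_equal(max(abs(z[[1]]$maps)), 0)
  # white noise at SNR 1: degraded but still faithful
  noisy <- lapply(seq_along(clean), function(s) {
    sig <- clean[[s]]
    sig + matrix(rnorm(length(sig), sd = sd(sig)), nrow(sig))
  })
  outn <- back_reconstruct(group, noisy)
  for (s in 1:3)
    for (j in 1:k)
      expect_gt(abs(cor(outn[[s]]$timecourses[, j], tcs[[s]][, j])), 0.8)
})

test_that("template matching recovers identity, permutations and ties", {
  set.seed(16)
  maps <- netconsist:::zscore_rows(planted_sparse_sources(5L, 3000L))
  comps <- netconsist:::new_component_set(maps)
  # identical templates: identity assignment, goodness ~ 1
  m <- match_templates(comps, maps)
  expect_equal(m$component, 1:5)
  expect_true(all(abs(m$goodness) > 0.999))
  # permuted templates: the inverse permutation comes back exactly
  perm <- c(3L, 5L, 1L, 2L, 4L)
  tm <- maps[perm, , drop = FALSE]
  rownames(tm) <- sprintf("tpl_%d", 1:5)
  mp <- match_templates(comps, tm)
  expect_equal(mp$component[match(sprintf("tpl_%d", 1:5), mp$template)],
               perm)
  # two templates preferring one component: higher goodness wins,
  # the other template falls back to its next-best component
  t1 <- maps[1, ]
  t2 <- 0.8 * maps[1, ] + 0.6 * maps[2, ]
  tie <- rbind(a = t1, b = t2)
  mt <- match_templates(comps, tie)
  expect_equal(mt$component[mt$template == "a"], 1L)
  expect_equal(mt$component[mt$template == "b"], 2L)
  expect_error(match_templates(netconsist:::new_component_set(maps[1:2, ]),
                               maps), "more templates")
})

test_that("classification is invariant to component sign flips", {
  co <- generate_cohort(tiny_sim_config(seed = 17L, n_per_group = 4L))
  sys_of <- setNames(tiny_roi_table()$system, tiny_roi_table()$name)
  nw <- co$truth$network_tcs
  nw_flip <- lapply(nw, function(m) { m[, 2] <- -m[, 2]; m })
  fam <- feature_family("allROIs-NWs")
  f1 <- build_feature_matrix(co$truth$roi_signals, nw, fam,
                             co$truth$subject_ids, co$truth$group_labels,
                             roi_systems_of = sys_of)
  f2 <- build_feature_matrix(co$truth$roi_signals, nw_flip, fam,
                             co$truth$subject_ids, co$truth$group_labels,
                             roi_systems_of = sys_of)
  expect_identical(loocv(f1)$outcomes, loocv(f2)$outcomes)
})
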