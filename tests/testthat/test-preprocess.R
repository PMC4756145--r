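make_series <- function(data, tr = 2) {
  g <- bold_grid(c(nrow(data), 1, 1), c(2, 2, 2), c(0, 0, 0))
  netconsist:::new_volume_series(data, g, tr)
}

test_that("initial-volume discard removes exactly the leading volumes", {
  x <- matrix(seq_len(5 * 300), 5)
  s <- make_series(x)
  out <- discard_initial(s, 3)
  expect_equal(ncol(out$data), 297L)
  expect_equal(out$data, x[, -(1:3)])
  expect_identical(discard_initial(s, 0), s)
  s5 <- make_series(x[, 1:5])
  expect_error(discard_initial(s5, 5), "discard")
  tr <- motion_trace(matrix(0, 300, 3), matrix(0, 300, 3))
  expect_equal(nrow(trim_motion(tr, 3)$translations), 297L)
})

test_that("motion QC computes the defined metrics and thresholds", {
  zeros <- motion_trace(matrix(0, 100, 3), matrix(0, 100, 3))
  q <- qc_motion(zeros)
  expect_false(q$excluded)
  expect_equal(q$cumulative_translation_mm, 0)
  expect_equal(q$mean_p2p_translation_mm, 0)
  expect_equal(q$rms_translation_mm, 0)

  # alternating 0 / 0.2 mm in x: every point-to-point step is 0.2 mm
  alt <- motion_trace(cbind(rep(c(0, 0.2), 50), 0, 0), matrix(0, 100, 3))
  qa <- qc_motion(alt)
  expect_equal(qa$mean_p2p_translation_mm, 0.2)
  expect_true(qa$excluded)
  expect_match(paste(qa$reasons, collapse = " "), "point-to-point translation")

  # slow monotone drift to (3.5, 0, 0) mm: tiny steps, large displacement
  drift <- motion_trace(cbind(seq(0, 3.5, length.out = 100), 0, 0),
                        matrix(0, 100, 3))
  qd <- qc_motion(drift)
  expect_equal(qd$cumulative_translation_mm, 3.5)
  expect_lt(qd$mean_p2p_translation_mm, 0.15)
  expect_true(qd$excluded)
  expect_match(paste(qd$reasons, collapse = " "), "cumulative")

  # rotation analog in degrees
  rot <- motion_trace(matrix(0, 100, 3), cbind(rep(c(0, 0.11), 50), 0, 0))
  expect_true(qc_motion(rot)$excluded)

  expect_error(qc_motion(zeros, make_series(matrix(rnorm(99), 1))),
               "lengths differ")
})

test_that("QC metrics ignore a constant offset of the translation traces", {
  set.seed(1)
  tr_ <- apply(matrix(rnorm(80 * 3, sd = 0.03), 80), 2, cumsum)
  rot <- apply(matrix(rnorm(80 * 3, sd = 0.01), 80), 2, cumsum)
  q1 <- qc_motion(motion_trace(tr_, rot))
  q2 <- qc_motion(motion_trace(sweep(tr_, 2, c(5, -3, 11), `+`), rot))
  for (f in c("cumulative_translation_mm", "mean_p2p_translation_mm",
              "mean_p2p_rotation_deg", "rms_translation_mm"))
    expect_equal(q1[[f]], q2[[f]], tolerance = 1e-12)
})

test_that("tSNR is mean over SD with constant voxels excluded and counted", {
  set.seed(2)
  z <- as.numeric(scale(rnorm(50)))       # exactly mean 0, sd 1
  x <- rbind(100 + 10 * z, 100 + 10 * z, 100 + 10 * z)
  expect_equal(as.numeric(compute_tsnr(make_series(x))), 10,
               tolerance = 1e-10)
  # a constant voxel is dropped from the average and counted
  xc <- rbind(x, rep(42, 50))
  ts <- compute_tsnr(make_series(xc))
  expect_equal(as.numeric(ts), 10, tolerance = 1e-10)
  expect_equal(attr(ts, "n_constant"), 1L)
  expect_error(compute_tsnr(make_series(matrix(7, 2, 50))), "constant")
  # Monte-Carlo: white noise with known mu/sigma at 10^4 time points
  xm <- matrix(50 + rnorm(10000, sd = 5), 1)
  expect_lt(abs(as.numeric(compute_tsnr(make_series(xm))) - 10) / 10, 0.02)
})

test_that("the band-pass matches its analytic magnitude-response oracle", {
  tr <- 2
  t_ <- seq(0, by = tr, length.out = 1200)
  amp_ratio <- function(f) {
    x <- sin(2 * pi * f * t_)
    y <- bandpass(x, tr_seconds = tr)
    core <- 301:900                     # avoid filter edge transients
    max(abs(y[core])) / max(abs(x[core]))
  }
  oracle <- function(f) netconsist:::bandpass_gain(f, tr_seconds = tr)
  # passband center region: near-unit gain
  expect_gte(amp_ratio(0.04), 0.9)
  expect_equal(amp_ratio(0.04), oracle(0.04), tolerance = 0.02)
  # stopband: strong attenuation
  expect_lte(amp_ratio(0.2), 0.1)
  expect_lt(oracle(0.2), 0.01)
  # DC is removed entirely
  const <- bandpass(rep(5, 400), tr_seconds = tr)
  expect_lt(max(abs(const)), 1e-8 * 5)
  expect_error(bandpass(rnorm(100), 0.01, 0.3, tr_seconds = 2), "Nyquist")
  expect_error(bandpass(rnorm(100), 0.08, 0.009, tr_seconds = 2), "band")
})

test_that("band-pass and nuisance regression are linear operators", {
  set.seed(3)
  x <- rnorm(300); y <- rnorm(300)
  a <- 2.5; b <- -1.3
  expect_equal(bandpass(a * x + b * y, tr_seconds = 2),
               a * bandpass(x, tr_seconds = 2) +
                 b * bandpass(y, tr_seconds = 2),
               tolerance = 1e-8)
  reg <- matrix(rnorm(300 * 4), 300)
  expect_equal(regress_nuisance(a * x + b * y, reg),
               a * regress_nuisance(x, reg) + b * regress_nuisance(y, reg),
               tolerance = 1e-8)
})

test_that("nuisance regression is exact OLS with orthogonal residuals", {
  set.seed(4)
  reg <- matrix(rnorm(250 * 9), 250)
  tc <- rnorm(250)
  res <- regress_nuisance(tc, reg)
  expect_true(all(abs(crossprod(res, reg)) < 1e-8))
  expect_lt(abs(sum(res)), 1e-8)
  # pseudoinverse-based oracle
  X <- cbind(1, reg)
  res_oracle <- tc - X %*% (solve(crossprod(X)) %*% crossprod(X, tc))
  expect_equal(res, drop(res_oracle), tolerance = 1e-10)
  # degenerate cases
  expect_lt(max(abs(regress_nuisance(reg[, 1], reg))), 1e-10)
  ortho <- qr.resid(qr(X), rnorm(250))
  expect_equal(regress_nuisance(ortho, reg), ortho, tolerance = 1e-10)
  expect_error(regress_nuisance(tc, cbind(reg, dup = reg[, 1])),
               "rank deficient.*dup")
})

test_that("SVD ROI reduction matches an eigendecomposition oracle", {
  set.seed(5)
  # all voxels share one time course: its standardized form comes back
  s_t <- rnorm(120)
  x <- matrix(rep(s_t, each = 10), 10)
  out <- extract_roi_timecourse(x, 1:10)
  expect_equal(out$values, as.numeric(scale(s_t)), tolerance = 1e-10)
  # exact rank-1 data a v': standardized v up to the sign rule
  a <- runif(15, 0.5, 2); v <- rnorm(200)
  out1 <- extract_roi_timecourse(a %o% v, 1:15)
  expect_gt(abs(cor(out1$values, v)), 1 - 1e-12)
  expect_gte(cor(out1$values, colMeans(a %o% v - rowMeans(a %o% v))), 0)
  # random ROI: first PC score from a brute-force eigendecomposition
  y <- matrix(rnorm(30 * 150), 30)
  yc <- y - rowMeans(y)
  ev <- eigen(crossprod(yc), symmetric = TRUE)
  pc1 <- ev$vectors[, 1]
  out2 <- extract_roi_timecourse(y, 1:30)
  expect_gt(abs(cor(out2$values, pc1)), 1 - 1e-10)
  # voxel-order invariance
  perm <- sample(30)
  out3 <- extract_roi_timecourse(y[perm, ], 1:30)
  expect_equal(out2$values, out3$values, tolerance = 1e-8)
  expect_error(extract_roi_timecourse(matrix(1, 5, 40), 1:5), "zero")
})

test_that("subject preprocessing yields clean standardized ROI courses", {
  co <- generate_cohort(tiny_sim_config(seed = 11L, n_per_group = 2L))
  s <- co$subjects[[1]]
  tcs <- preprocess_subject(s, co$motion[[1]], co$truth$roi_masks,
                            co$truth$nuisance$masks)
  expect_equal(dim(tcs), c(100L, 4L))
  expect_equal(colnames(tcs), names(co$truth$roi_masks))
  expect_equal(unname(colMeans(tcs)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(apply(tcs, 2, sd)), rep(1, 4), tolerance = 1e-10)
  expect_error(preprocess_subject(s, trim_motion(co$motion[[1]], 1),
                                  co$truth$roi_masks,
                                  co$truth$nuisance$masks),
               "lengths differ")
})
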