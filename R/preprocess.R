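#' Discard initial volumes of a BOLD series
#'
#' Resting-state acquisitions discard the first few volumes while the
#' longitudinal magnetization reaches steady state (here the emulated design
#' drops 3 of 300). The caller trims the motion trace consistently with
#' [trim_motion()].
#'
#' @param series a `volume_series`.
#' @param n number of leading volumes to remove (default 3).
#' @return A `volume_series` with `n` fewer volumes.
#' @export
discard_initial <- function(series, n = 3L) {
  T_ <- n_timepoints(series)
  if (!is_count(n, 0L)) stopf("n must be a non-negative integer")
  if (n >= T_) stopf("cannot discard %d of %d volumes", n, T_)
  if (n == 0L) return(series)
  new_volume_series(series$data[, -seq_len(n), drop = FALSE], series$grid,
                    series$tr_seconds)
}

#' Motion and tSNR quality control
#'
#' Computes the motion summary metrics and applies the exclusion thresholds:
#' * point-to-point translation: Euclidean norm of the change of the three
#'   translation parameters between consecutive volumes (mm); rotation
#'   analogously in degrees;
#' * cumulative translation: by default the maximum Euclidean displacement
#'   from the first retained volume (`cumulative = "max_displacement"`); the
#'   alternative reading, the summed point-to-point path length, is available
#'   via `cumulative = "path_length"`;
#' * RMS translation: pooled root-mean-square of the three demeaned
#'   translation series (demeaning makes the metric invariant to a constant
#'   offset of the parameters, which carries no motion information);
#' * tSNR over the whole brain when `series` is supplied
#'   (see [compute_tsnr()]).
#'
#' A subject is excluded when cumulative translation exceeds
#' `max_cumulative_mm` (3 mm), or mean point-to-point translation exceeds
#' `max_p2p_trans_mm` (0.15 mm), or mean point-to-point rotation exceeds
#' `max_p2p_rot_deg` (0.1 degrees).
#'
#' @param trace a `motion_trace`, aligned with the retained volumes.
#' @param series optional `volume_series` for tSNR (must match the trace
#'   length).
#' @param max_cumulative_mm,max_p2p_trans_mm,max_p2p_rot_deg thresholds.
#' @param cumulative `"max_displacement"` (default) or `"path_length"`.
#' @return A `qc_report` list: `cumulative_translation_mm`,
#'   `mean_p2p_translation_mm`, `mean_p2p_rotation_deg`,
#'   `rms_translation_mm`, `tsnr`, `excluded`, `reasons`.
#' @export
qc_motion <- function(trace, series = NULL,
                      max_cumulative_mm = 3,
                      max_p2p_trans_mm = 0.15,
                      max_p2p_rot_deg = 0.1,
                      cumulative = c("max_displacement", "path_length")) {
  cumulative <- match.arg(cumulative)
  tr_ <- trace$translations
  ro <- trace$rotations_deg
  if (!is.null(series) && n_timepoints(series) != nrow(tr_))
    stopf("motion trace (%d) and series (%d volumes) lengths differ",
          nrow(tr_), n_timepoints(series))
  p2p_t <- sqrt(rowSums(diff(tr_)^2))
  p2p_r <- sqrt(rowSums(diff(ro)^2))
  disp <- sqrt(rowSums(sweep(tr_, 2L, tr_[1L, ], `-`)^2))
  cum <- if (cumulative == "max_displacement") max(disp) else sum(p2p_t)
  rms <- sqrt(mean(sweep(tr_, 2L, colMeans(tr_), `-`)^2))
  tsnr <- if (is.null(series)) NA_real_ else compute_tsnr(series)
  reasons <- character()
  if (cum > max_cumulative_mm)
    reasons <- c(reasons, sprintf("cumulative translation %.3g mm > %g mm",
                                  cum, max_cumulative_mm))
  if (mean(p2p_t) > max_p2p_trans_mm)
    reasons <- c(reasons,
                 sprintf("mean point-to-point translation %.3g mm > %g mm",
                         mean(p2p_t), max_p2p_trans_mm))
  if (mean(p2p_r) > max_p2p_rot_deg)
    reasons <- c(reasons,
                 sprintf("mean point-to-point rotation %.3g deg > %g deg",
                         mean(p2p_r), max_p2p_rot_deg))
  structure(list(cumulative_translation_mm = cum,
                 mean_p2p_translation_mm = mean(p2p_t),
                 mean_p2p_rotation_deg = mean(p2p_r),
                 rms_translation_mm = rms,
                 tsnr = as.numeric(tsnr),
                 excluded = length(reasons) > 0L,
                 reasons = reasons),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> cum %.3g mm | p2p %.3g mm / %.3g deg | rms %.3g mm | tSNR %.3g\n",
              x$cumulative_translation_mm, x$mean_p2p_translation_mm,
              x$mean_p2p_rotation_deg, x$rms_translation_mm, x$tsnr))
  if (x$excluded) cat("  EXCLUDED:", paste(x$reasons, collapse = "; "), "\n")
  invisible(x)
}

#' Temporal signal-to-noise ratio
#'
#' Per-voxel temporal mean divided by temporal standard deviation, averaged
#' over the mask. Voxels with zero temporal SD are excluded from the average;
#' their count is attached as attribute `n_constant`.
#'
#' @param series a `volume_series`.
#' @param mask optional `roi_mask` or integer voxel indices; default whole
#'   brain.
#' @return Scalar tSNR with attribute `n_constant`.
#' @export
compute_tsnr <- function(series, mask = NULL) {
  if (n_timepoints(series) < 2L) stopf("tSNR needs at least 2 time points")
  vox <- if (is.null(mask)) seq_len(nrow(series$data))
         else if (inherits(mask, "roi_mask")) mask$voxels else as.integer(mask)
  x <- if (is.null(mask)) series$data else series$data[vox, , drop = FALSE]
  T_ <- ncol(x)
  mu <- rowMeans(x)
  # one-pass variance; avoids a voxel x time temporary on large series
  s <- sqrt(pmax(rowSums(x^2) - T_ * mu^2, 0) / (T_ - 1L))
  ok <- s > 0
  if (!any(ok)) stopf("tSNR undefined: every voxel in the mask is constant")
  structure(mean(mu[ok] / s[ok]), n_constant = sum(!ok))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Order-4 Butterworth band-pass (order configurable), applied
#' forward-backward (`signal::filtfilt`), so the effective magnitude
#' response is the squared single-pass response and the phase is zero. Each
#' column is demeaned before filtering (the DC component lies in the
#' stopband regardless).
#'
#' @param x numeric vector or time x k matrix.
#' @param low_hz,high_hz band edges in Hz (defaults 0.009 and 0.08, the
#'   conventional slow-fluctuation band).
#' @param tr_seconds sampling interval in seconds.
#' @param order Butterworth order of the single-pass prototype (default 4).
#' @return Filtered data, same shape as `x`.
#' @export
bandpass <- function(x, low_hz = 0.009, high_hz = 0.08, tr_seconds,
                     order = 4L) {
  nyq <- 1 / (2 * tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stopf("band edges must satisfy 0 < low (%g) < high (%g) < Nyquist (%g Hz)",
          low_hz, high_hz, nyq)
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  filt1 <- function(v) signal::filtfilt(bf, v - mean(v))
  if (is.matrix(x)) {
    out <- apply(x, 2L, filt1)
    dimnames(out) <- dimnames(x)
    out
  } else filt1(x)
}

# Analytic squared-magnitude response of the zero-phase (forward-backward)
# band-pass at frequency f_hz; used as the oracle in tests and for
# documentation of the filter's shape.
bandpass_gain <- function(f_hz, low_hz = 0.009, high_hz = 0.08, tr_seconds,
                          order = 4L) {
  nyq <- 1 / (2 * tr_seconds)
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  w <- pi * f_hz / nyq
  z <- exp(1i * w)
  h <- sum(bf$b * z^-(seq_along(bf$b) - 1)) /
    sum(bf$a * z^-(seq_along(bf$a) - 1))
  Mod(h)^2
}

#' Regress nuisance signals out of a time course
#'
#' Ordinary least squares of `tc` on `[intercept | regressors]`; returns the
#' residual, which is exactly orthogonal to every regressor column (and mean
#' zero). Rank deficiency of the design is an error naming the collinear
#' columns.
#'
#' @param tc numeric vector or time x k matrix.
#' @param regressors numeric time x q matrix.
#' @return Residual, same shape as `tc`.
#' @export
regress_nuisance <- function(tc, regressors) {
  regressors <- as.matrix(regressors)
  n <- if (is.matrix(tc)) nrow(tc) else length(tc)
  if (nrow(regressors) != n)
    stopf("time course (%d) and regressors (%d rows) lengths differ", n,
          nrow(regressors))
  X <- cbind(intercept = 1, regressors)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[seq.int(qrx$rank + 1L, ncol(X))]]
    if (is.null(dropped)) dropped <- as.character(
      qrx$pivot[seq.int(qrx$rank + 1L, ncol(X))])
    stopf("nuisance design is rank deficient; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  res <- qr.resid(qrx, as.matrix(tc))
  if (is.matrix(tc)) res else drop(res)
}

#' Extract an ROI-representative time course by SVD
#'
#' The representative course is the first right-singular vector of the
#' row-centered voxel x time ROI submatrix -- the time course of the ROI's
#' dominant spatiotemporal mode. The SVD sign indeterminacy is resolved so
#' that the correlation with the plain ROI mean time course is non-negative;
#' the output is scaled to zero mean, unit variance.
#'
#' @param series a `volume_series` (or a voxel x time matrix).
#' @param mask an `roi_mask` (or integer voxel indices).
#' @return An `roi_timecourse`: list with `name`, `values` (length-T numeric),
#'   `sign_flipped` flag.
#' @export
extract_roi_timecourse <- function(series, mask) {
  x <- if (inherits(series, "volume_series")) series$data else as.matrix(series)
  vox <- if (inherits(mask, "roi_mask")) mask$voxels else as.integer(mask)
  nm <- if (inherits(mask, "roi_mask")) mask$name else "roi"
  sub <- x[vox, , drop = FALSE]
  sub <- sub - rowMeans(sub)
  if (all(abs(sub) < .Machine$double.eps * 100))
    stopf("ROI '%s': submatrix is all zero after centering", nm)
  sv <- svd(sub, nu = 0L, nv = 1L)
  v <- sv$v[, 1L]
  mean_tc <- colMeans(sub)
  flip <- FALSE
  if (sd(mean_tc) > 0 && cor(v, mean_tc) < 0) { v <- -v; flip <- TRUE }
  v <- (v - mean(v)) / sd(v)
  structure(list(name = nm, values = v, sign_flipped = flip),
            class = "roi_timecourse")
}

#' Preprocess one subject's ROI time courses
#'
#' Applies the temporal pipeline to a (post-discard) subject: extract each
#' ROI's SVD-representative course, band-pass it, then regress out the
#' nuisance set (global gray-matter, white-matter and CSF mean signals from
#' the supplied tissue masks, plus the six motion parameters). By default the
#' nuisance regressors are band-passed to the same band before regression, so
#' the regression cannot reintroduce out-of-band variance; set
#' `bandpass_nuisance = FALSE` for raw regressors. Each returned course is
#' re-standardized to zero mean, unit variance.
#'
#' @param series `volume_series`, volumes already discarded.
#' @param trace `motion_trace` aligned with `series` (see [trim_motion()]).
#' @param roi_masks list of `roi_mask`.
#' @param tissue_masks list with integer voxel index vectors `gm`, `wm`,
#'   `csf`.
#' @param low_hz,high_hz band edges (Hz).
#' @param bandpass_nuisance filter the nuisance regressors too (default TRUE).
#' @return time x ROI matrix of cleaned, standardized ROI courses.
#' @export
preprocess_subject <- function(series, trace, roi_masks, tissue_masks,
                               low_hz = 0.009, high_hz = 0.08,
                               bandpass_nuisance = TRUE) {
  T_ <- n_timepoints(series)
  if (nrow(trace$translations) != T_)
    stopf("motion trace and series lengths differ (%d vs %d)",
          nrow(trace$translations), T_)
  tissue <- vapply(tissue_masks[c("gm", "wm", "csf")], function(v)
    colMeans(series$data[v, , drop = FALSE]), numeric(T_))
  nuis <- cbind(tissue, trans = trace$translations, rot = trace$rotations_deg)
  colnames(nuis) <- c("gm", "wm", "csf", paste0("trans_", c("x", "y", "z")),
                      paste0("rot_", c("x", "y", "z")))
  if (bandpass_nuisance)
    nuis <- bandpass(nuis, low_hz, high_hz, series$tr_seconds)
  out <- vapply(roi_masks, function(m) {
    tc <- extract_roi_timecourse(series, m)$values
    tc <- bandpass(tc, low_hz, high_hz, series$tr_seconds)
    tc <- regress_nuisance(tc, nuis)
    (tc - mean(tc)) / sd(tc)
  }, numeric(T_))
  colnames(out) <- unname(vapply(roi_masks, `[[`, character(1), "name"))
  out
}
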