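#' Rigid-body motion parameter trace
#'
#' Six parameters per volume: three translations (mm) and three rotations.
#' Rotations are stored in degrees internally; the on-disk format (SPM
#' `rp_*.txt` dialect, six whitespace-delimited columns) stores radians and
#' [read_motion()] converts on read.
#'
#' @param translations numeric `T x 3` matrix, mm.
#' @param rotations_deg numeric `T x 3` matrix, degrees.
#' @return A `motion_trace`.
#' @export
motion_trace <- function(translations, rotations_deg) {
  translations <- as.matrix(translations)
  rotations_deg <- as.matrix(rotations_deg)
  if (ncol(translations) != 3L || ncol(rotations_deg) != 3L ||
      nrow(translations) != nrow(rotations_deg))
    stopf("motion trace needs T x 3 translations and T x 3 rotations")
  structure(list(translations = translations, rotations_deg = rotations_deg),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d volumes; max |translation| %.3g mm, max |rotation| %.3g deg\n",
              nrow(x$translations), max(abs(x$translations)),
              max(abs(x$rotations_deg))))
  invisible(x)
}

# Random-walk motion, independent of the BOLD content (QC exercise only).
random_walk_motion <- function(n_volumes, step = c(trans_mm = 0.01,
                                                   rot_rad = 2e-4)) {
  tr_ <- apply(matrix(rnorm(n_volumes * 3L, sd = step[["trans_mm"]]),
                      n_volumes), 2L, cumsum)
  ro <- apply(matrix(rnorm(n_volumes * 3L, sd = step[["rot_rad"]]),
                     n_volumes), 2L, cumsum)
  tr_[1L, ] <- 0; ro[1L, ] <- 0
  motion_trace(tr_, ro * 180 / pi)
}

#' Drop the leading volumes of a motion trace
#'
#' Companion to [discard_initial()]: keeps motion rows aligned with the
#' retained volumes.
#'
#' @param trace a `motion_trace`.
#' @param n number of leading rows to drop.
#' @return A `motion_trace`.
#' @export
trim_motion <- function(trace, n) {
  if (n < 0 || n >= nrow(trace$translations))
    stopf("cannot drop %d of %d motion rows", n, nrow(trace$translations))
  if (n == 0L) return(trace)
  keep <- -seq_len(n)
  motion_trace(trace$translations[keep, , drop = FALSE],
               trace$rotations_deg[keep, , drop = FALSE])
}

#' Write / read a motion parameter file
#'
#' Six whitespace-delimited columns: translations x/y/z in mm, rotations
#' pitch/roll/yaw in radians (the SPM realignment-parameter dialect).
#'
#' @param trace a `motion_trace`.
#' @param path file path.
#' @return `read_motion()` returns a `motion_trace` (rotations converted to
#'   degrees); `write_motion()` returns `path` invisibly.
#' @export
write_motion <- function(trace, path) {
  m <- cbind(trace$translations, trace$rotations_deg * pi / 180)
  write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
              path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  m <- unname(as.matrix(read.table(path, header = FALSE)))
  if (ncol(m) != 6L) stopf("motion file must have 6 columns: %s", path)
  motion_trace(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE] * 180 / pi)
}
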