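#' Write / read a subject's 4D BOLD series as NIfTI
#'
#' The grid geometry is stored in the sform (axis-aligned affine); the
#' repetition time goes into `pixdim[4]`.
#'
#' @param series a `volume_series`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `read_bold_nifti()` returns a `volume_series`;
#'   `write_bold_nifti()` returns `path` invisibly.
#' @export
write_bold_nifti <- function(series, path) {
  dims <- series$grid$dims
  arr <- array(series$data, dim = c(dims, ncol(series$data)))
  img <- RNifti::asNifti(arr)
  # pixdim first: the pixdim setter rescales any existing xform
  img <- RNifti::`pixdim<-`(img, c(series$grid$vox_mm, series$tr_seconds))
  img <- RNifti::`sform<-`(img,
                           structure(grid_affine(series$grid), code = 4L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_bold_nifti
#' @export
read_bold_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  dims <- dim(img)
  if (length(dims) != 4L) stopf("expected a 4D NIfTI image: %s", path)
  grid <- grid_from_affine(structure(RNifti::xform(img), class = NULL),
                           dims[1:3])
  pd <- RNifti::pixdim(img)
  tr <- if (length(pd) >= 4L && pd[4] > 0) pd[4] else 1
  new_volume_series(matrix(as.numeric(img), prod(dims[1:3]), dims[4]),
                    grid, tr)
}

#' Write a synthetic cohort to disk
#'
#' Per subject: a 4D NIfTI image and a 6-column motion text file. Cohort
#' level: a tab-separated manifest (subject id, group, file paths) and a
#' ground-truth JSON (group labels, planted coupling matrices, system-network
#' assignment, and a note that all distributional choices are synthetic
#' stand-ins).
#'
#' @param cohort a `bold_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest data.frame.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- cohort$truth$subject_ids
  bold <- file.path(dir, paste0(ids, "_bold.nii.gz"))
  rp <- file.path(dir, paste0(ids, "_motion.txt"))
  for (s in seq_along(ids)) {
    write_bold_nifti(cohort$subjects[[s]], bold[s])
    write_motion(cohort$motion[[s]], rp[s])
  }
  manifest <- data.frame(subject_id = ids,
                         group = cohort$truth$group_labels,
                         bold_file = basename(bold),
                         motion_file = basename(rp),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- list(
    note = paste("Synthetic cohort: all distributional choices are",
                 "stand-ins, not estimates from empirical data."),
    group_labels = as.list(setNames(cohort$truth$group_labels, ids)),
    system_networks = cohort$truth$system_networks,
    planted_coupling = lapply(cohort$truth$planted_coupling, function(m)
      as.data.frame(m)),
    seed = cohort$truth$config$seed)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort manifest written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return List with `subjects` (list of `volume_series`), `motion` (list of
#'   `motion_trace`), `subject_ids`, `group_labels`.
#' @export
read_cohort <- function(dir) {
  manifest <- read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                         header = TRUE, stringsAsFactors = FALSE)
  subjects <- lapply(file.path(dir, manifest$bold_file), read_bold_nifti)
  motion <- lapply(file.path(dir, manifest$motion_file), read_motion)
  names(subjects) <- names(motion) <- manifest$subject_id
  list(subjects = subjects, motion = motion,
       subject_ids = manifest$subject_id, group_labels = manifest$group)
}

#' Write / read a per-subject time-course table (TSV)
#'
#' One column per ROI or network, header row carries the entity names.
#'
#' @param tc numeric matrix, time x entities, with column names.
#' @param path file path.
#' @return `read_timecourses()` returns the matrix.
#' @export
write_timecourses <- function(tc, path) {
  write.table(format(tc, digits = 17, scientific = TRUE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourses
#' @export
read_timecourses <- function(path) {
  as.matrix(read.table(path, sep = "\t", header = TRUE, check.names = FALSE))
}
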