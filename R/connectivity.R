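#' Fisher r-to-z transform
#'
#' `z = arctanh(r)`, the variance-stabilizing transform applied to every
#' Pearson correlation before it is used as a classification feature.
#' Correlations at or beyond `|r| = 1 - clip` (numerically degenerate pairs,
#' e.g. an ROI course identical to a network course) are clipped to that
#' bound so the feature stays finite; every clip is reported via a message.
#'
#' @param r numeric vector of correlations in `[-1, 1]`.
#' @param clip clipping margin (default `1e-7`).
#' @return `atanh` of the (possibly clipped) values.
#' @export
fisher_z <- function(r, clip = 1e-7) {
  if (any(!is.finite(r)) || any(abs(r) > 1 + 1e-12))
    stopf("correlations must be finite and within [-1, 1]")
  bound <- 1 - clip
  n_clip <- sum(abs(r) > bound)
  if (n_clip > 0) {
    message(sprintf("fisher_z: clipped %d correlation(s) at |r| = 1 - %g",
                    n_clip, clip))
    r <- pmin(pmax(r, -bound), bound)
  }
  atanh(r)
}

#' Define a connectivity feature family
#'
#' The four families of the design:
#' * `allROIs-NWs`: every ROI paired with every selected network;
#' * `NWs-NWs`: strict upper triangle of the network-network matrix;
#' * `allROIs-allROIs`: strict upper triangle of the ROI-ROI matrix;
#' * `separateROI-NWs`: one subcortical-cerebellar system's ROIs paired with
#'   every network (give `system`).
#'
#' @param name one of `"allROIs-NWs"`, `"NWs-NWs"`, `"allROIs-allROIs"`,
#'   `"separateROI-NWs"`.
#' @param system required for `separateROI-NWs`.
#' @return A `feature_family`.
#' @export
feature_family <- function(name = c("allROIs-NWs", "NWs-NWs",
                                    "allROIs-allROIs", "separateROI-NWs"),
                           system = NULL) {
  name <- match.arg(name)
  if (name == "separateROI-NWs") {
    if (is.null(system) || !system %in% roi_systems())
      stopf("separateROI-NWs needs a system in {%s}",
            paste(roi_systems(), collapse = ", "))
  } else system <- NULL
  structure(list(name = name, system = system,
                 label = if (is.null(system)) name
                         else sprintf("%s-NWs", system)),
            class = "feature_family")
}

# All seven families of the default analysis.
all_feature_families <- function(systems = roi_systems()) {
  fams <- c(list(feature_family("allROIs-NWs"),
                 feature_family("NWs-NWs"),
                 feature_family("allROIs-allROIs")),
            lapply(systems, function(s) feature_family("separateROI-NWs", s)))
  names(fams) <- vapply(fams, `[[`, character(1), "label")
  fams
}

#' Build a subjects x features Fisher-z connectivity matrix
#'
#' For each subject, the Pearson correlation of every entity pair prescribed
#' by the family is computed from the supplied time courses and Fisher
#' r-to-z transformed. Entities are ordered lexicographically by name, and
#' pair order is identical across subjects, so feature `j` means the same
#' edge for every subject. A zero-variance time course is an error naming
#' the entity.
#'
#' @param roi_tcs list (one per subject) of time x ROI matrices with column
#'   names; ROI columns must carry system labels via `roi_systems_of`.
#' @param nw_tcs list (one per subject) of time x network matrices with
#'   column names.
#' @param family a [feature_family()].
#' @param subject_ids,groups per-subject id and group-label vectors.
#' @param roi_systems_of named character vector mapping ROI name to system
#'   (needed for `separateROI-NWs`).
#' @return A `feature_matrix`: `values` (subjects x features), `family`,
#'   `subject_ids`, `groups`, `feature_labels`.
#' @export
build_feature_matrix <- function(roi_tcs, nw_tcs, family, subject_ids,
                                 groups, roi_systems_of = NULL) {
  n <- length(subject_ids)
  if (length(roi_tcs) != n || length(nw_tcs) != n || length(groups) != n)
    stopf("roi_tcs, nw_tcs, subject_ids and groups must agree in length")
  rows <- lapply(seq_len(n), function(s) {
    rt <- roi_tcs[[s]]; nt <- nw_tcs[[s]]
    if (nrow(rt) != nrow(nt))
      stopf("subject %s: ROI (%d) and network (%d) course lengths differ",
            subject_ids[s], nrow(rt), nrow(nt))
    if (nrow(rt) < 3L) stopf("need at least 3 time points")
    rt <- rt[, order(colnames(rt)), drop = FALSE]
    nt <- nt[, order(colnames(nt)), drop = FALSE]
    for (m in list(rt, nt)) {
      bad <- colnames(m)[apply(m, 2L, sd) == 0]
      if (length(bad))
        stopf("subject %s: zero-variance time course for %s",
              subject_ids[s], paste(bad, collapse = ", "))
    }
    fam_pairs(rt, nt, family, roi_systems_of)
  })
  labels <- names(rows[[1]])
  if (!all(vapply(rows, function(r) identical(names(r), labels), TRUE)))
    stopf("feature labels differ across subjects")
  values <- do.call(rbind, lapply(rows, unname))
  dimnames(values) <- list(subject_ids, labels)
  z <- fisher_z(as.numeric(values))
  values[] <- z
  structure(list(values = values, family = family,
                 subject_ids = subject_ids, groups = groups,
                 feature_labels = labels),
            class = "feature_matrix")
}

fam_pairs <- function(rt, nt, family, roi_systems_of) {
  upper_vec <- function(m) {
    cc <- cor(m)
    idx <- which(upper.tri(cc), arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    setNames(cc[idx],
             paste(colnames(m)[idx[, 1L]], colnames(m)[idx[, 2L]],
                   sep = "~"))
  }
  cross_vec <- function(a, b) {
    cc <- cor(a, b)
    out <- as.numeric(t(cc))   # row entity major, columns lexicographic
    names(out) <- as.character(t(outer(colnames(a), colnames(b), paste,
                                       sep = "~")))
    out
  }
  switch(family$name,
         "allROIs-NWs" = cross_vec(rt, nt),
         "NWs-NWs" = upper_vec(nt),
         "allROIs-allROIs" = upper_vec(rt),
         "separateROI-NWs" = {
           if (is.null(roi_systems_of))
             stopf("separateROI-NWs needs roi_systems_of")
           keep <- colnames(rt)[roi_systems_of[colnames(rt)] ==
                                  family$system]
           if (!length(keep))
             stopf("no ROI belongs to system '%s'", family$system)
           cross_vec(rt[, keep, drop = FALSE], nt)
         })
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d subjects x %d Fisher-z features\n",
              x$family$label, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Write / read a feature family TSV
#'
#' First columns `subject_id` and `group`, then one labeled z-feature per
#' column. Labels round-trip losslessly.
#'
#' @param fm a `feature_matrix`.
#' @param path file path.
#' @return `read_feature_matrix()` returns a `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(subject_id = fm$subject_ids, group = fm$groups,
                   check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.data.frame(fm$values, check.names = FALSE)
  vals[] <- lapply(vals, function(v) format(v, digits = 17,
                                            scientific = TRUE, trim = TRUE))
  df <- cbind(df, vals)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @param family the [feature_family()] the file holds (families are not
#'   self-describing beyond their labels).
#' @export
read_feature_matrix <- function(path, family) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(values) <- df$subject_id
  structure(list(values = values, family = family,
                 subject_ids = df$subject_id, groups = df$group,
                 feature_labels = colnames(values)),
            class = "feature_matrix")
}
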