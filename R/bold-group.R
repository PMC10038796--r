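#' Multi-subject BOLD time-series container
#'
#' Bundles one experimental group's voxel time series with its acquisition
#' metadata. Data are stored per subject as a voxel x timepoint matrix in
#' percent-signal-like units; all subjects of a group must share the voxel
#' count, timepoint count, repetition time (TR) and run structure.
#'
#' @param data a list with one voxel x timepoint numeric matrix per subject,
#'   or a 3-D array ordered subject x voxel x timepoint.
#' @param tr_seconds repetition time in seconds (sampling interval).
#' @param run_lengths integer vector of per-run timepoint counts; must sum to
#'   the number of timepoints. The runs are assumed concatenated in time.
#' @param subject_ids optional character labels, one per subject.
#' @param condition stimulus condition label (e.g. "AV", "A", "V").
#' @param population population label (e.g. "TD", "blind", "deaf").
#' @param geometry optional volumetric geometry: a list with `dim` (3-D grid
#'   size) and `mask_idx` (ascending linear indices of the voxels within that
#'   grid). Required for cluster-extent filtering and NIfTI export.
#' @return an object of class `bold_group`.
#' @export
bold_group <- function(data, tr_seconds, run_lengths, subject_ids = NULL,
                       condition = NA_character_, population = NA_character_,
                       geometry = NULL) {
  if (is.array(data) && length(dim(data)) == 3L) {
    dd <- dim(data)
    data <- lapply(seq_len(dd[1L]), function(s)
      matrix(data[s, , ], nrow = dd[2L], ncol = dd[3L]))
  }
  if (!is.list(data) || !length(data) || !all(vapply(data, is.matrix, TRUE)))
    .stopf("`data` must be a list of voxel x timepoint matrices (one per subject)")
  dims <- vapply(data, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    .stopf("all subjects must share voxel and timepoint counts; got voxels %s, timepoints %s",
           paste(unique(dims[1L, ]), collapse = "/"),
           paste(unique(dims[2L, ]), collapse = "/"))
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    .stopf("`tr_seconds` must be a positive scalar")
  run_lengths <- as.integer(run_lengths)
  if (any(run_lengths < 1L) || sum(run_lengths) != dims[2L, 1L])
    .stopf("`run_lengths` must be positive and sum to the timepoint count (%d), got sum %d",
           dims[2L, 1L], sum(run_lengths))
  if (is.null(subject_ids))
    subject_ids <- sprintf("sub-%02d", seq_along(data))
  if (length(subject_ids) != length(data))
    .stopf("need one subject id per subject")
  if (!is.null(geometry)) {
    if (!all(c("dim", "mask_idx") %in% names(geometry)))
      .stopf("`geometry` needs elements `dim` and `mask_idx`")
    if (length(geometry$mask_idx) != dims[1L, 1L])
      .stopf("geometry mask has %d voxels but data has %d",
             length(geometry$mask_idx), dims[1L, 1L])
  }
  names(data) <- subject_ids
  structure(list(data = data, tr_seconds = tr_seconds,
                 run_lengths = run_lengths, subject_ids = subject_ids,
                 condition = condition, population = population,
                 geometry = geometry),
            class = "bold_group")
}

#' @export
print.bold_group <- function(x, ...) {
  cat(sprintf("<bold_group> %d subjects x %d voxels x %d timepoints, TR %gs, %d run(s)\n",
              n_subjects(x), n_voxels(x), n_timepoints(x),
              x$tr_seconds, length(x$run_lengths)))
  cat(sprintf("  condition: %s  population: %s  geometry: %s\n",
              x$condition, x$population,
              if (is.null(x$geometry)) "none" else paste(x$geometry$dim, collapse = "x")))
  invisible(x)
}

#' @rdname bold_group
#' @param group a `bold_group`.
#' @export
n_subjects <- function(group) length(group$data)

#' @rdname bold_group
#' @export
n_voxels <- function(group) nrow(group$data[[1L]])

#' @rdname bold_group
#' @export
n_timepoints <- function(group) ncol(group$data[[1L]])

#' Restrict a group to a subset of voxels
#'
#' @param group a `bold_group`.
#' @param idx integer or logical voxel index into the group's voxel dimension.
#' @return a `bold_group` holding only the selected voxels; the geometry's
#'   mask indices are subset accordingly.
#' @export
subset_voxels <- function(group, idx) {
  if (is.logical(idx)) idx <- which(idx)
  group$data <- lapply(group$data, function(m) m[idx, , drop = FALSE])
  if (!is.null(group$geometry))
    group$geometry$mask_idx <- group$geometry$mask_idx[idx]
  group
}

## Per-run-demeaned, unit-norm rows for every subject: the correlation
## engine's working representation.
.prep_group <- function(group) {
  lapply(group$data, function(m) .row_unitize(.demean_runs(m, group$run_lengths)))
}
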