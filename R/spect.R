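# Absolute activity quantification on a calibrated SPECT study.

#' Quantitative SPECT study container
#'
#' @param activity 3-D activity volume (MBq per voxel, after calibration).
#' @param labels Congruent integer label volume ([region_codes()]).
#' @param voxel_mL Voxel volume in mL.
#' @param time_h Acquisition time post-injection (h).
#' @return Object of class `spect_study`.
#' @export
spect_study <- function(activity, labels, voxel_mL, time_h) {
  if (!identical(dim(activity), dim(labels))) {
    abort("Activity and label volumes must be congruent.")
  }
  if (voxel_mL <= 0) abort("`voxel_mL` must be > 0.")
  if (any(activity < 0)) abort("Activities must be >= 0.")
  structure(
    list(activity = activity, labels = labels, voxel_mL = voxel_mL,
         time_h = time_h),
    class = "spect_study"
  )
}

#' @export
print.spect_study <- function(x, ...) {
  cat("<spect_study>", paste(dim(x$activity), collapse = " x "),
      "voxels @", x$voxel_mL, "mL;", round(sum(x$activity), 1),
      "MBq total at", x$time_h, "h\n")
  invisible(x)
}

#' Convert a reconstructed count volume to activity
#'
#' Voxelwise division by the scalar camera calibration factor (counts per
#' MBq), determined in practice from a planar point-source scan.
#'
#' @param counts 3-D count volume.
#' @param calibration_factor Counts per MBq, `> 0`.
#' @return Activity volume (MBq per voxel).
#' @export
calibrate_spect <- function(counts, calibration_factor) {
  if (!is.numeric(calibration_factor) || length(calibration_factor) != 1L ||
      calibration_factor <= 0) {
    abort("`calibration_factor` must be a single positive number.")
  }
  counts / calibration_factor
}

#' Absolute organ activity from the label volume
#'
#' Integrates the activity over the labeled voxels; the segmented volume is
#' the voxel count times the voxel volume. The entire-liver convention
#' (`include_tumor = TRUE` with `region = "liver"`) merges the tumor voxels
#' into the liver, matching organ-level dose reporting where tumor-excluded
#' liver S-values are unavailable.
#'
#' @param study A [spect_study()].
#' @param region Region name.
#' @param include_tumor Merge tumor voxels into the region (used for the
#'   entire liver)?
#' @return One-row tibble: `region`, `activity_MBq`, `volume_mL`, `time_h`.
#' @export
organ_activity <- function(study, region, include_tumor = FALSE) {
  stopifnot(inherits(study, "spect_study"))
  codes <- region_code(region)
  if (include_tumor) codes <- union(codes, region_code("tumor"))
  vox <- study$labels %in% codes
  if (!any(vox)) abort(paste0("Region '", region, "' is absent from the label volume."))
  tibble(
    region = region,
    activity_MBq = sum(study$activity[vox]),
    volume_mL = sum(vox) * study$voxel_mL,
    time_h = study$time_h
  )
}

#' Volume-matched tumor segmentation
#'
#' Selects the `k = round(target_volume / voxel_volume)` highest-activity
#' voxels inside a rough boundary (e.g. the liver lobe containing the
#' tumor), so the recovered volume equals the reported tumor volume to
#' within one voxel. This realizes the fixed-threshold constraint exactly:
#' the implied threshold is any value between the k-th and (k+1)-th largest
#' voxel. Ties at the cut are broken by voxel index order, which leaves the
#' segmented activity unchanged.
#'
#' @param study A [spect_study()].
#' @param boundary Logical voxel mask of the search region.
#' @param target_volume_mL Reported tumor volume (mL), `> 0` and at most the
#'   boundary volume.
#' @return List with `mask` (logical volume) and `measurement` (one-row
#'   tibble like [organ_activity()]).
#' @export
tumor_segment_volume_matched <- function(study, boundary, target_volume_mL) {
  stopifnot(inherits(study, "spect_study"))
  if (!identical(dim(boundary), dim(study$activity))) {
    abort("`boundary` must be congruent with the study volumes.")
  }
  n_b <- sum(boundary)
  k <- round(target_volume_mL / study$voxel_mL)
  if (k < 1) abort("Target volume is below one voxel.")
  if (k > n_b) abort("Target volume exceeds the boundary volume.")
  idx <- which(boundary)
  vals <- study$activity[idx]
  ord <- order(vals, -idx, decreasing = TRUE) # ties -> lowest index first
  keep <- idx[ord[seq_len(k)]]
  mask <- array(FALSE, dim = dim(boundary))
  mask[keep] <- TRUE
  list(
    mask = mask,
    measurement = tibble(
      region = "tumor",
      activity_MBq = sum(study$activity[keep]),
      volume_mL = k * study$voxel_mL,
      time_h = study$time_h
    )
  )
}
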