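# Serialization of synthetic patient datasets to standard formats:
# NIfTI volumes, float TIFF planar images, CSV metadata, YAML kinetics.

need_pkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    abort(paste0("Package '", pkg, "' is required for dataset I/O."))
  }
}

#' Write a patient dataset to a directory
#'
#' SPECT activity and label volumes as NIfTI, planar views as 32-bit float
#' TIFF, the patient record and ground-truth kinetics as CSV, and scan/
#' geometry metadata as YAML. The round trip through [read_patient()] is
#' lossless apart from float32 precision of the images.
#'
#' @param patient A `patient_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_patient <- function(patient, dir) {
  need_pkg("RNifti"); need_pkg("tiff"); need_pkg("yaml")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vox <- patient$geometry$voxel_mm
  RNifti::writeNifti(RNifti::asNifti(patient$spect$activity,
                                     pixdim = rep(vox, 3)),
                     file.path(dir, "spect_activity.nii"))
  RNifti::writeNifti(RNifti::asNifti(patient$spect$labels * 1,
                                     pixdim = rep(vox, 3)),
                     file.path(dir, "spect_labels.nii"))
  # TIFF stores [0,1]; images are scaled by their max, recorded in meta.yaml.
  # Count images are integer-valued when Poisson noise was applied; the flag
  # lets the reader snap float32 values back to exact counts.
  int_counts <- all(vapply(patient$scans, function(s) {
    all(s$anterior == round(s$anterior)) && all(s$posterior == round(s$posterior))
  }, logical(1)))
  scales <- matrix(0, length(patient$scans), 2)
  for (k in seq_along(patient$scans)) {
    s <- patient$scans[[k]]
    scales[k, ] <- pmax(c(max(s$anterior), max(s$posterior)), 1e-12)
    tiff::writeTIFF(s$anterior / scales[k, 1],
                    file.path(dir, sprintf("scan%d_ant.tif", k)),
                    bits.per.sample = 32L)
    tiff::writeTIFF(s$posterior / scales[k, 2],
                    file.path(dir, sprintf("scan%d_post.tif", k)),
                    bits.per.sample = 32L)
  }
  utils::write.csv(patient$record, file.path(dir, "record.csv"),
                   row.names = FALSE)
  utils::write.csv(patient$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  meta <- list(
    scan_times_h = vapply(patient$scans, function(s) s$time_h, 0),
    image_scales = lapply(seq_len(nrow(scales)), function(k) as.numeric(scales[k, ])),
    integer_counts = int_counts,
    duration_s = vapply(patient$scans, function(s) s$duration_s, 0),
    tau_s = vapply(patient$scans, function(s) s$tau_s, 0),
    spect_time_h = patient$spect$time_h,
    voxel_mL = patient$spect$voxel_mL,
    geometry = list(shape = as.integer(patient$geometry$shape),
                    voxel_mm = patient$geometry$voxel_mm),
    regions = lapply(seq_len(nrow(patient$geometry$regions)), function(i) {
      as.list(patient$geometry$regions[i, ])
    })
  )
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a patient dataset written by [write_patient()]
#'
#' @param dir Directory written by [write_patient()].
#' @return A `patient_dataset`.
#' @export
read_patient <- function(dir) {
  need_pkg("RNifti"); need_pkg("tiff"); need_pkg("yaml")
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  regions <- dplyr::bind_rows(lapply(meta$regions, as_tibble))
  geom <- phantom_geometry(meta$geometry$shape, meta$geometry$voxel_mm,
                           regions, validate = FALSE)
  act <- array(as.numeric(RNifti::readNifti(file.path(dir, "spect_activity.nii"))),
               dim = meta$geometry$shape)
  lab <- array(as.integer(round(as.numeric(
    RNifti::readNifti(file.path(dir, "spect_labels.nii"))))),
    dim = meta$geometry$shape)
  spect <- spect_study(act, lab, meta$voxel_mL, meta$spect_time_h)
  n_scans <- length(meta$scan_times_h)
  scans <- lapply(seq_len(n_scans), function(k) {
    sc <- meta$image_scales[[k]]
    ant <- tiff::readTIFF(file.path(dir, sprintf("scan%d_ant.tif", k))) * sc[1]
    post <- tiff::readTIFF(file.path(dir, sprintf("scan%d_post.tif", k))) * sc[2]
    if (isTRUE(meta$integer_counts)) {
      ant <- round(ant)
      post <- round(post)
    }
    planar_scan_pair(ant, post, meta$scan_times_h[k], meta$duration_s[k],
                     meta$tau_s[k])
  })
  record <- as_tibble(utils::read.csv(file.path(dir, "record.csv")))
  truth <- as_tibble(utils::read.csv(file.path(dir, "truth.csv")))
  structure(
    list(record = record, scans = scans, spect = spect, truth = truth,
         geometry = geom),
    class = "patient_dataset"
  )
}
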