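# Assemble complete synthetic patient datasets: planar scan pairs at each
# time point, one SPECT study at t1, metadata and retained ground truth.

#' Anterior/posterior planar scan pair
#'
#' @param anterior,posterior Count images (matrices, same shape). The
#'   posterior image is stored as recorded by the camera, i.e. mirrored
#'   left-right relative to the anterior frame.
#' @param time_h Acquisition time post-injection (h).
#' @param duration_s Effective duration per pixel (s).
#' @param tau_s Dead-time constant used during acquisition (s).
#' @return Object of class `planar_scan_pair`.
#' @export
planar_scan_pair <- function(anterior, posterior, time_h, duration_s,
                             tau_s = 0) {
  if (!identical(dim(anterior), dim(posterior))) {
    abort("Anterior and posterior images must have the same shape.")
  }
  if (any(anterior < 0) || any(posterior < 0)) abort("Counts must be >= 0.")
  if (time_h < 0) abort("`time_h` must be >= 0.")
  if (duration_s <= 0) abort("`duration_s` must be > 0.")
  structure(
    list(anterior = anterior, posterior = posterior, time_h = time_h,
         duration_s = duration_s, tau_s = tau_s, dead_time_corrected = FALSE),
    class = "planar_scan_pair"
  )
}

#' @export
print.planar_scan_pair <- function(x, ...) {
  cat("<planar_scan_pair>", paste(dim(x$anterior), collapse = " x "),
      "px @", x$time_h, "h;", format(sum(x$anterior) + sum(x$posterior)),
      "total counts\n")
  invisible(x)
}

# Separable 3-D Gaussian blur, zero-padded; kernel normalized to unit sum.
gaussian_blur3 <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k <- k / sum(k)
  conv_vec <- function(v) {
    vp <- c(rep(0, r), v, rep(0, r))
    out <- numeric(length(v))
    for (i in seq_along(k)) out <- out + k[i] * vp[i:(i + length(v) - 1)]
    out
  }
  d <- dim(arr)
  arr <- aperm(apply(arr, c(2, 3), conv_vec), c(1, 2, 3))
  arr <- aperm(apply(arr, c(1, 3), conv_vec), c(2, 1, 3))
  arr <- aperm(apply(arr, c(1, 2), conv_vec), c(2, 3, 1))
  stopifnot(identical(dim(arr), d))
  arr
}

# Uniform per-region activity map (MBq/voxel) at a given time.
activity_volume <- function(labels, kin, time_h) {
  act <- array(0, dim = dim(labels))
  for (i in seq_len(nrow(kin))) {
    code <- REGION_CODES[[kin$region[i]]]
    vox <- labels == code
    n <- sum(vox)
    if (n == 0L) next
    act[vox] <- ground_truth_activity(kin[i, ], time_h) / n
  }
  act
}

#' Build one synthetic patient dataset
#'
#' Produces anterior/posterior planar count images at each scan time
#' (attenuated projection, global paralyzable dead-time loss, optional
#' Poisson noise and inter-scan couch shifts) and one SPECT study at the
#' first scan time (voxelized activity, optional Gaussian blur emulating
#' partial-volume losses, optional Poisson noise), together with the
#' patient record and the retained ground truth.
#'
#' @param kinetics One patient's rows from [sample_cohort()] or
#'   [patient_kinetics()].
#' @param geometry A [phantom_geometry()].
#' @param noise Apply Poisson counting noise (planar and SPECT) and random
#'   couch shifts for the later scans?
#' @param blur_fwhm_mm SPECT Gaussian blur FWHM in mm (0 disables; default
#'   12 mm, the resolution scale of a Re-188 SPECT system).
#' @param spect_counts_per_MBq SPECT sensitivity used only to set the Poisson
#'   noise level of the calibrated activity volume.
#' @param duration_s Effective planar dwell per pixel (s); about 40 s for a
#'   10 cm detector row at 15 cm/min bed speed.
#' @param shifts Optional list of integer couch shifts `c(dx, dz)` for scans
#'   2..n (anterior frame). Default: random in `[-2, 2]` when `noise = TRUE`,
#'   zero otherwise.
#' @param max_shift_px Bound for the random couch shifts.
#' @param seed Optional integer seed.
#' @return Object of class `patient_dataset` with elements `record`,
#'   `scans` (list of [planar_scan_pair()]), `spect` ([spect_study()]),
#'   `truth` (the kinetics rows), and `geometry`.
#' @export
build_patient <- function(kinetics, geometry = phantom_geometry(),
                          noise = TRUE, blur_fwhm_mm = 12,
                          spect_counts_per_MBq = 25, duration_s = 40,
                          shifts = NULL, max_shift_px = 2L, seed = NULL) {
  stopifnot(nrow(kinetics) >= 1L, length(unique(kinetics$patient_id)) == 1L)
  missing_regions <- setdiff(kinetics$region, geometry$regions$region)
  if (length(missing_regions)) {
    abort(paste("Kinetics reference regions absent from the phantom:",
                paste(missing_regions, collapse = ", ")))
  }
  if (!is.null(seed)) set.seed(seed)
  labels <- voxelize(geometry)
  times <- c(kinetics$t1_h[1], kinetics$t2_h[1], kinetics$t3_h[1])
  times <- times[!is.na(times)]
  tau <- kinetics$tau_s[1]
  cf <- kinetics$cal_cps_per_MBq[1]

  if (is.null(shifts)) {
    shifts <- lapply(seq_along(times)[-1], function(i) {
      if (noise) sample(seq(-max_shift_px, max_shift_px), 2, replace = TRUE)
      else c(0L, 0L)
    })
  }

  scans <- vector("list", length(times))
  for (k in seq_along(times)) {
    act <- activity_volume(labels, kinetics, times[k])
    ant <- project_planar(act, geometry, "anterior", TRUE, labels, cf)
    post <- project_planar(act, geometry, "posterior", TRUE, labels, cf)
    if (k > 1L) {
      s <- shifts[[k - 1L]]
      ant <- translate_image(ant, s)
      post <- mirror_lr(translate_image(mirror_lr(post), s))
    }
    ant_c <- apply_counting_model(ant, tau, duration_s, poisson = noise)
    post_c <- apply_counting_model(post, tau, duration_s, poisson = noise)
    scans[[k]] <- planar_scan_pair(ant_c, post_c, times[k], duration_s, tau)
  }

  act1 <- activity_volume(labels, kinetics, times[1])
  if (blur_fwhm_mm > 0) {
    act1 <- gaussian_blur3(act1, blur_fwhm_mm / 2.3548200450309493 / geometry$voxel_mm)
  }
  if (noise) {
    counts <- rpois(length(act1), act1 * spect_counts_per_MBq)
    act1 <- array(counts / spect_counts_per_MBq, dim = dim(act1))
  }
  voxel_mL <- geometry$voxel_mm^3 / 1000
  spect <- spect_study(act1, labels, voxel_mL, times[1])

  vols <- region_volumes(labels, geometry$voxel_mm)
  vol_of <- function(r) vols$volume_mL[vols$region == r]
  record <- tibble(
    patient_id = kinetics$patient_id[1],
    A0_MBq = kinetics$A0_MBq[1],
    t1_h = times[1],
    t2_h = if (length(times) >= 2) times[2] else NA_real_,
    t3_h = if (length(times) >= 3) times[3] else NA_real_,
    tumor_mL = vol_of("tumor"),
    liver_mL = vol_of("liver") + vol_of("tumor") # entire liver
  )
  structure(
    list(record = record, scans = scans, spect = spect,
         truth = kinetics, geometry = geometry,
         shifts = c(list(c(0L, 0L)), shifts)),
    class = "patient_dataset"
  )
}

#' @export
print.patient_dataset <- function(x, ...) {
  cat("<patient_dataset> patient", x$record$patient_id, "-",
      length(x$scans), "planar scan pairs at",
      paste(vapply(x$scans, function(s) s$time_h, 0), collapse = ", "),
      "h; SPECT at", x$spect$time_h, "h\n")
  invisible(x)
}

#' Build a whole synthetic cohort of patient datasets
#'
#' @param cohort Tibble from [sample_cohort()].
#' @param ... Passed to [build_patient()].
#' @param seed Optional seed controlling all image noise.
#' @return List of `patient_dataset` objects.
#' @export
build_cohort <- function(cohort, ..., seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(cohort$patient_id)
  lapply(ids, function(id) {
    build_patient(cohort[cohort$patient_id == id, ], ...)
  })
}

#' Rough planar boundaries from the phantom footprints
#'
#' For each active region, projects its label footprint onto the planar
#' (lateral x axial) frame and dilates it by a margin, standing in for the
#' manually drawn rough boundaries of the clinical workflow. The liver
#' boundary covers the entire liver (tumor included).
#'
#' @param patient A `patient_dataset`.
#' @param regions Regions to delineate.
#' @param dilate_px Dilation margin in pixels.
#' @return Named list of logical masks in the anterior frame.
#' @export
planar_boundaries <- function(patient, regions = ACTIVE_REGIONS,
                              dilate_px = 1L) {
  labels <- patient$spect$labels
  out <- list()
  for (r in regions) {
    codes <- if (r == "liver") region_code(c("liver", "tumor")) else region_code(r)
    mask3 <- array(labels %in% codes, dim = dim(labels))
    foot <- apply(mask3, c(1, 3), any)
    out[[r]] <- dilate_mask(foot, dilate_px)
  }
  out
}

# Binary square dilation by r pixels.
dilate_mask <- function(mask, r = 1L) {
  if (r <= 0L) return(mask)
  out <- mask
  for (dx in -r:r) for (dy in -r:r) {
    if (dx == 0L && dy == 0L) next
    out <- out | (translate_image(mask * 1, c(dx, dy)) > 0)
  }
  out
}
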