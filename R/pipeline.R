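# End-to-end hybrid planar/SPECT dosimetry for one patient or a cohort.

#' Run the hybrid planar/SPECT dosimetry chain on one patient
#'
#' Chains the full method: relative TACs from the serial planar pairs
#' (threshold ROIs, registration, dead-time correction, geometric mean),
#' mono-exponential fits, absolute activities at `t1` from the SPECT study
#' (volume-matched segmentation for the tumor, label volumes for organs,
#' entire-liver convention for the liver), rescaling, piecewise TIA
#' integration, TIACs, and S-factor doses (sphere model for the tumor,
#' mass-scaled organ model otherwise).
#'
#' @param patient A `patient_dataset`.
#' @param boundaries Optional named list of planar rough boundaries; default
#'   [planar_boundaries()].
#' @param regions Regions to quantify.
#' @param threshold_fraction Planar ROI threshold.
#' @param density_g_mL Tissue density for mass calculations.
#' @param s_table Optional organ S-factor reference table (see
#'   [organ_dose()]).
#' @param sphere_table Sphere S-factor series for the tumor.
#' @param constants [re188_constants()].
#' @param weighted Weight the fits by the Poisson-propagated uncertainties?
#' @return Object of class `patient_dosimetry`: list with `tacs`, `fits`,
#'   `activities`, `results` (per-region tibble with `T_eff_h`, `T_bio_h`,
#'   `activity_MBq`, `tia_MBq_h`, `tiac_h`, `normalized_mGy_per_MBq`,
#'   `absolute_Gy`), and `record`.
#' @export
run_patient_dosimetry <- function(patient, boundaries = NULL,
                                  regions = c("tumor", "liver", "lungs",
                                              "stomach", "spleen", "kidneys"),
                                  threshold_fraction = 0.4,
                                  density_g_mL = 1.03, s_table = NULL,
                                  sphere_table = sphere_s_table(),
                                  constants = re188_constants(),
                                  weighted = TRUE) {
  boundaries <- boundaries %||% planar_boundaries(patient, regions)
  tacs <- extract_relative_tacs(patient, boundaries, threshold_fraction)
  fits <- fit_tacs(tacs, weighted = weighted, constants = constants)

  spect <- patient$spect
  rec <- patient$record
  liver_lobe <- array(spect$labels %in% region_code(c("liver", "tumor")),
                      dim = dim(spect$labels))
  acts <- purrr::map_dfr(intersect(regions, fits$region), function(rg) {
    if (rg == "tumor") {
      tumor_segment_volume_matched(spect, liver_lobe, rec$tumor_mL)$measurement
    } else {
      organ_activity(spect, rg, include_tumor = (rg == "liver"))
    }
  })

  last_scan <- max(vapply(patient$scans, function(s) s$time_h, 0))
  t1 <- patient$scans[[1]]$time_h
  results <- purrr::map_dfr(seq_len(nrow(acts)), function(i) {
    rg <- acts$region[i]
    f <- fits$fit[[which(fits$region == rg)]]
    abs_tac <- rescale_to_absolute(f, acts$activity_MBq[i], t1)
    ti <- integrate_tia_tac(abs_tac, last_scan, constants = constants)
    coeff <- tiac(ti$tia_MBq_h, rec$A0_MBq)
    dose <- if (rg == "tumor") {
      tumor_dose_sphere(coeff, rec$A0_MBq, acts$volume_mL[i], density_g_mL,
                        sphere_table, constants = constants)
    } else {
      organ_dose(coeff, rec$A0_MBq,
                 mass_kg = acts$volume_mL[i] * density_g_mL / 1000,
                 region = rg, s_table = s_table, constants = constants)
    }
    tibble(
      patient_id = rec$patient_id, region = rg,
      T_eff_h = f$T_eff_h,
      T_bio_h = fits$T_bio_h[fits$region == rg],
      r_squared = f$r_squared,
      activity_MBq = acts$activity_MBq[i],
      volume_mL = acts$volume_mL[i],
      tia_MBq_h = ti$tia_MBq_h, tiac_h = coeff,
      normalized_mGy_per_MBq = dose$normalized_mGy_per_MBq,
      absolute_Gy = dose$absolute_Gy
    )
  })
  structure(
    list(tacs = tacs, fits = fits, activities = acts, results = results,
         record = rec),
    class = "patient_dosimetry"
  )
}

#' @export
print.patient_dosimetry <- function(x, ...) {
  cat("<patient_dosimetry> patient", x$record$patient_id, "\n")
  print(x$results[, c("region", "T_eff_h", "tiac_h",
                      "normalized_mGy_per_MBq", "absolute_Gy")])
  invisible(x)
}

#' Run the dosimetry chain over a cohort of patient datasets
#'
#' @param patients List of `patient_dataset` objects (see [build_cohort()]).
#' @param ... Passed to [run_patient_dosimetry()].
#' @return Tibble of stacked per-region results.
#' @export
run_cohort_dosimetry <- function(patients, ...) {
  purrr::map_dfr(patients, function(p) run_patient_dosimetry(p, ...)$results)
}

#' Tidy relative TACs for a cohort of patient datasets
#'
#' @param patients List of `patient_dataset` objects.
#' @param ... Passed to [extract_relative_tacs()].
#' @return Tibble: `patient_id`, `region`, `time_h`, `rate`, `sigma`.
#' @export
cohort_relative_tacs <- function(patients, ...) {
  purrr::map_dfr(patients, function(p) {
    dplyr::mutate(extract_relative_tacs(p, ...),
                  patient_id = p$record$patient_id, .before = 1)
  })
}
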