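# Conjugate-view planar quantification: threshold ROIs, geometric-mean count
# rates, paralyzable dead-time correction, translation registration, and
# relative time-activity curve extraction.

#' Threshold ROI inside a rough boundary
#'
#' Keeps the pixels inside the rough boundary whose value is at least
#' `threshold_fraction` times the maximum value inside the boundary
#' (inclusive comparison, so ties at the threshold are all kept).
#'
#' @param image 2-D count (or rate) image.
#' @param boundary Logical mask of the rough boundary, same shape.
#' @param threshold_fraction Fraction of the in-boundary maximum, in (0, 1).
#' @return Logical ROI mask.
#' @export
delineate_roi <- function(image, boundary, threshold_fraction = 0.4) {
  if (!identical(dim(image), dim(boundary))) {
    abort("`image` and `boundary` must have the same shape.")
  }
  if (!any(boundary)) abort("Rough boundary is empty.")
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    abort("`threshold_fraction` must be in (0, 1).")
  }
  mx <- max(image[boundary])
  if (mx <= 0) abort("All pixels inside the boundary are zero; no maximum to threshold against.")
  boundary & (image >= threshold_fraction * mx)
}

#' Geometric-mean count rate of an ROI on a conjugate-view pair
#'
#' The posterior image is mirrored left-right into the anterior frame before
#' masking. The rate is `sqrt(R_ant * R_post)` of the ROI-summed count rates;
#' its uncertainty is propagated from Poisson counting statistics as
#' `0.5 * GM * sqrt(1/N_ant + 1/N_post)`.
#'
#' @param pair A [planar_scan_pair()].
#' @param roi Logical ROI mask (anterior frame).
#' @param roi_post Optional separate ROI for the (mirrored) posterior view;
#'   defaults to `roi`.
#' @return One-row tibble with `rate` (cps), `sigma`, `n_ant`, `n_post`.
#' @export
geometric_mean_rate <- function(pair, roi, roi_post = NULL) {
  stopifnot(inherits(pair, "planar_scan_pair"))
  roi_post <- roi_post %||% roi
  post_m <- mirror_lr(pair$posterior)
  n_ant <- sum(pair$anterior[roi])
  n_post <- sum(post_m[roi_post])
  if (n_ant <= 0 || n_post <= 0) {
    abort("Zero counts in an ROI view; geometric mean undefined.")
  }
  r_ant <- n_ant / pair$duration_s
  r_post <- n_post / pair$duration_s
  gm <- sqrt(r_ant * r_post)
  tibble(
    rate = gm,
    sigma = 0.5 * gm * sqrt(1 / n_ant + 1 / n_post),
    n_ant = n_ant, n_post = n_post
  )
}

#' Invert paralyzable dead-time losses
#'
#' Solves `m = n * exp(-n * tau)` for the true rate `n` on the low-rate
#' branch (`n <= 1/tau`), using the principal Lambert W function. Observed
#' rates above the paralyzable maximum `1/(e * tau)` are unphysical and
#' raise an error; corrections larger than `max_correction` are flagged
#' with a warning.
#'
#' @param observed_rate Observed count rate(s), cps, `>= 0`.
#' @param tau_s Dead-time constant (s); `0` is the identity.
#' @param max_correction Warn when `n/m - 1` exceeds this cap.
#' @return True count rate(s), cps.
#' @export
correct_dead_time <- function(observed_rate, tau_s, max_correction = 0.3) {
  if (any(observed_rate < 0)) abort("Observed rates must be >= 0.")
  if (tau_s < 0) abort("`tau_s` must be >= 0.")
  if (tau_s == 0) return(observed_rate)
  if (any(observed_rate > 1 / (exp(1) * tau_s) * (1 + 1e-12))) {
    abort("Observed rate exceeds the paralyzable maximum 1/(e*tau).")
  }
  n <- vapply(observed_rate, function(m) {
    if (m == 0) return(0)
    -pracma::lambertWp(-m * tau_s) / tau_s
  }, numeric(1))
  rel <- n / pmax(observed_rate, .Machine$double.xmin) - 1
  if (any(observed_rate > 0 & rel > max_correction)) {
    warn(sprintf("Dead-time correction exceeds %.0f%% for some rates.",
                 100 * max_correction))
  }
  n
}

#' Estimate an integer-pixel translation by normalized cross-correlation
#'
#' Searches integer shifts within `max_shift` pixels and returns the one
#' maximizing the Pearson correlation between the fixed image and the
#' back-shifted moving image on their overlap. Ties are broken toward the
#' smallest shift magnitude, then row-major order.
#'
#' @param fixed,moving Images of identical shape.
#' @param max_shift Search half-width (pixels).
#' @return List with `shift` (integer `c(d1, d2)` such that
#'   `translate_image(fixed, shift)` matches `moving`) and `ncc`.
#' @export
register_translation <- function(fixed, moving, max_shift = 8L) {
  if (!identical(dim(fixed), dim(moving))) {
    abort("Images must have the same shape.")
  }
  if (sd(fixed) == 0 || sd(moving) == 0) {
    abort("Flat image: correlation undefined.")
  }
  best <- NULL
  for (d1 in -max_shift:max_shift) {
    for (d2 in -max_shift:max_shift) {
      r1 <- max(1, 1 + d1):min(nrow(fixed), nrow(fixed) + d1)
      c1 <- max(1, 1 + d2):min(ncol(fixed), ncol(fixed) + d2)
      f <- fixed[r1 - d1, c1 - d2]
      m <- moving[r1, c1]
      if (sd(f) == 0 || sd(m) == 0) next
      ncc <- stats::cor(as.vector(f), as.vector(m))
      cand <- list(shift = c(d1, d2), ncc = ncc)
      if (is.null(best) ||
          ncc > best$ncc + 1e-12 ||
          (abs(ncc - best$ncc) <= 1e-12 &&
           sum(cand$shift^2) < sum(best$shift^2))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) abort("No valid overlap found in the search window.")
  best
}

#' Register a later scan pair to the first scan
#'
#' Estimates the couch translation from the anterior views and resamples
#' both views back into the frame of the first scan (the posterior view is
#' mirrored into the anterior frame, shifted, and re-mirrored).
#'
#' @param moving,fixed [planar_scan_pair()] objects of identical shape.
#' @param max_shift Search half-width in pixels.
#' @return List with `pair` (the resampled moving pair) and `shift`.
#' @export
register_to_first <- function(moving, fixed, max_shift = 8L) {
  reg <- register_translation(fixed$anterior, moving$anterior, max_shift)
  s <- reg$shift
  ant <- translate_image(moving$anterior, -s)
  post <- mirror_lr(translate_image(mirror_lr(moving$posterior), -s))
  out <- planar_scan_pair(ant, post, moving$time_h, moving$duration_s,
                          moving$tau_s)
  list(pair = out, shift = s, ncc = reg$ncc)
}

#' Extract relative time-activity curves from a patient's planar scans
#'
#' Implements the conjugate-view workflow: threshold ROIs are delineated on
#' the first scan inside rough per-region boundaries, later scans are
#' rigidly (translation) registered to the first and the ROIs transferred,
#' every view is corrected for global dead-time losses, and the
#' geometric-mean count rate is recorded per region and time point. No
#' attenuation or scatter correction is applied, so the rates are relative:
#' only their time dependence carries information.
#'
#' @param patient A `patient_dataset` (or any list with `scans` like it).
#' @param boundaries Named list of rough boundary masks (anterior frame of
#'   the first scan). Defaults to [planar_boundaries()] footprints.
#' @param threshold_fraction ROI threshold as a fraction of the in-boundary
#'   maximum.
#' @param threshold_on Apply the threshold per view independently
#'   (`"view"`, default) or once on the geometric-mean image (`"gm"`).
#' @param max_shift Registration search half-width (pixels).
#' @return Tibble with `region`, `time_h`, `rate`, `sigma` (class
#'   `relative_tac`). Regions whose ROI has zero counts in a view are
#'   dropped with a warning naming the region.
#' @export
extract_relative_tacs <- function(patient, boundaries = NULL,
                                  threshold_fraction = 0.4,
                                  threshold_on = c("view", "gm"),
                                  max_shift = 8L) {
  threshold_on <- match.arg(threshold_on)
  scans <- patient$scans
  if (length(scans) < 2L) abort("At least two planar scan pairs are required.")
  boundaries <- boundaries %||% planar_boundaries(patient)
  if (is.null(names(boundaries)) || any(names(boundaries) == "")) {
    abort("`boundaries` must be a named list of masks.")
  }

  # register scans 2..n to the first
  aligned <- vector("list", length(scans))
  aligned[[1]] <- scans[[1]]
  for (k in seq_along(scans)[-1]) {
    aligned[[k]] <- register_to_first(scans[[k]], scans[[1]], max_shift)$pair
  }

  # per-scan, per-view dead-time correction factors from image-total rates
  dt_factor <- function(pair, img) {
    m <- sum(img) / pair$duration_s
    if (pair$tau_s == 0 || m == 0) return(1)
    correct_dead_time(m, pair$tau_s) / m
  }

  first <- aligned[[1]]
  post1 <- mirror_lr(first$posterior)
  rows <- list()
  failed <- character()
  for (rn in names(boundaries)) {
    b <- boundaries[[rn]]
    res <- tryCatch({
      if (threshold_on == "view") {
        roi_a <- delineate_roi(first$anterior, b, threshold_fraction)
        roi_p <- delineate_roi(post1, b, threshold_fraction)
      } else {
        gm_img <- sqrt(pmax(first$anterior, 0) * pmax(post1, 0))
        roi_a <- roi_p <- delineate_roi(gm_img, b, threshold_fraction)
      }
      purrr::map_dfr(aligned, function(pair) {
        g <- geometric_mean_rate(pair, roi_a, roi_p)
        fa <- dt_factor(pair, pair$anterior)
        fp <- dt_factor(pair, mirror_lr(pair$posterior))
        f <- sqrt(fa * fp)
        tibble(region = rn, time_h = pair$time_h,
               rate = g$rate * f, sigma = g$sigma * f)
      })
    }, error = function(e) {
      failed <<- c(failed, sprintf("%s (%s)", rn, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[rn]] <- res
  }
  if (length(failed)) {
    warn(paste0("TAC extraction failed for region(s): ",
                paste(failed, collapse = "; ")))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("relative_tac", class(out))
  out
}
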