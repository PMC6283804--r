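# Forward models for whole-body planar acquisition: parallel projection with
# depth-dependent attenuation, and a counting model (paralyzable dead time +
# Poisson noise).

#' Project a 3-D activity map into a planar expected-count-rate image
#'
#' Line-integral projection along the anterior-posterior axis (array dim 2).
#' With attenuation enabled, each voxel is attenuated by the material between
#' it and the detector plus half its own thickness; under this mid-voxel
#' convention the product of the anterior and posterior attenuation factors
#' for any voxel equals the transmission through the full column, so the
#' conjugate-view geometric mean is exactly depth-independent.
#'
#' The posterior view is returned as a camera would record it, i.e. mirrored
#' left-right relative to the anterior frame.
#'
#' @param activity 3-D activity array (MBq per voxel), same grid as `geom`.
#' @param geom A [phantom_geometry()].
#' @param direction `"anterior"` or `"posterior"`.
#' @param attenuation Apply attenuation along the projection path?
#' @param labels Label volume used to build the attenuation map; defaults to
#'   [voxelize()] of `geom`.
#' @param cal_cps_per_MBq Scalar camera sensitivity (counts/s per MBq).
#' @return Matrix of expected count rates (cps), dims lateral x axial.
#' @export
project_planar <- function(activity, geom, direction = c("anterior", "posterior"),
                           attenuation = TRUE, labels = NULL,
                           cal_cps_per_MBq = 1) {
  direction <- match.arg(direction)
  stopifnot(inherits(geom, "phantom_geometry"))
  if (!identical(dim(activity), as.integer(geom$shape)) &&
      !identical(dim(activity), geom$shape)) {
    abort("`activity` does not share the phantom grid.")
  }
  nx <- dim(activity)[1]; ny <- dim(activity)[2]; nz <- dim(activity)[3]
  img <- matrix(0, nx, nz)
  if (attenuation) {
    if (is.null(labels)) labels <- voxelize(geom)
    mu <- attenuation_map(geom, labels)
    d_cm <- geom$voxel_mm / 10
    js <- if (direction == "anterior") seq_len(ny) else rev(seq_len(ny))
    acc <- matrix(0, nx, nz) # path length x mu up to the near face
    for (j in js) {
      half <- mu[, j, ] * d_cm / 2
      img <- img + activity[, j, ] * exp(-(acc + half))
      acc <- acc + mu[, j, ] * d_cm
    }
  } else {
    for (j in seq_len(ny)) img <- img + activity[, j, ]
  }
  img <- img * cal_cps_per_MBq
  if (direction == "posterior") img <- mirror_lr(img)
  img
}

#' Mirror a planar image left-right
#'
#' Maps between the posterior camera frame and the anterior frame (dim 1 is
#' the lateral axis).
#' @param img Matrix.
#' @return Mirrored matrix.
#' @export
mirror_lr <- function(img) img[nrow(img):1, , drop = FALSE]

#' Apply the counting model to an expected-rate image
#'
#' A global paralyzable dead-time loss factor `exp(-n * tau)` (with `n` the
#' image-total true count rate) scales all pixels, then counts are drawn as
#' independent Poisson variables with mean `duration * rate`.
#'
#' @param expected_rates Matrix of true count rates (cps), all `>= 0`.
#' @param tau_s Paralyzable dead-time constant (s), `>= 0`.
#' @param duration_s Effective acquisition duration per pixel (s), `> 0`.
#' @param seed Optional integer seed for reproducible draws.
#' @param poisson If `FALSE`, return the (non-integer) expected counts after
#'   dead-time losses instead of Poisson draws.
#' @return Matrix of observed counts.
#' @export
apply_counting_model <- function(expected_rates, tau_s = 0, duration_s = 1,
                                 seed = NULL, poisson = TRUE) {
  if (any(expected_rates < 0)) abort("Expected rates must be non-negative.")
  if (tau_s < 0) abort("`tau_s` must be >= 0.")
  if (duration_s <= 0) abort("`duration_s` must be > 0.")
  n_total <- sum(expected_rates)
  loss <- exp(-n_total * tau_s)
  lambda <- expected_rates * loss * duration_s
  if (!poisson) return(lambda)
  if (!is.null(seed)) set.seed(seed)
  counts <- rpois(length(lambda), lambda)
  matrix(counts, nrow = nrow(expected_rates), ncol = ncol(expected_rates))
}

#' Translate an image by an integer pixel shift, zero-filling
#'
#' @param img Matrix.
#' @param shift Integer vector `c(d1, d2)`: content moves by `d1` rows and
#'   `d2` columns.
#' @return Shifted matrix.
#' @export
translate_image <- function(img, shift) {
  shift <- as.integer(round(shift))
  out <- matrix(0, nrow(img), ncol(img))
  src_r <- seq_len(nrow(img)) - shift[1]
  src_c <- seq_len(ncol(img)) - shift[2]
  ok_r <- src_r >= 1 & src_r <= nrow(img)
  ok_c <- src_c >= 1 & src_c <= ncol(img)
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}
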