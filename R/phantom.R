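# Digital ellipsoid phantom: geometry, voxelization and attenuation map.
#
# Coordinates: voxel indices are 0-based internally; world coordinates are in
# mm at voxel centres, with the origin at the centre of the grid. Axis 1 is
# left-right (lateral), axis 2 is anterior-posterior (projection axis), axis 3
# is caudal-cranial.

REGION_CODES <- c(
  background = 0L, body = 1L, liver = 2L, tumor = 3L,
  lungs = 4L, stomach = 5L, spleen = 6L, kidneys = 7L
)

ACTIVE_REGIONS <- c("tumor", "liver", "lungs", "stomach", "spleen", "kidneys")

#' Integer label code for a region name
#' @param region Region name, one of `names(region_codes())`.
#' @return Integer code.
#' @export
region_code <- function(region) {
  region <- match.arg(region, names(REGION_CODES), several.ok = TRUE)
  unname(REGION_CODES[region])
}

#' Region label dictionary
#' @return Named integer vector mapping region names to label codes.
#' @export
region_codes <- function() REGION_CODES

#' Default phantom region table
#'
#' One ellipsoid per region: centre (mm), semi-axes (mm), and a linear
#' attenuation coefficient (1/cm) at the imaging photon energy (155 keV;
#' about 0.15/cm for soft tissue, lower for lung). The tumor ellipsoid
#' lies fully inside the liver ellipsoid; all other active regions have
#' disjoint anterior-posterior projection footprints so their planar
#' time-activity curves are uncontaminated.
#'
#' @return A tibble with columns `region`, `cx_mm`, `cy_mm`, `cz_mm`,
#'   `a_mm`, `b_mm`, `c_mm`, `mu_cm`.
#' @export
phantom_regions <- function() {
  tibble(
    region = c("body", "liver", "tumor", "lungs", "stomach", "spleen", "kidneys"),
    cx_mm = c(0, -50, -30, 0, 90, 100, -90),
    cy_mm = c(0, 10, 10, 0, 20, 0, -30),
    cz_mm = c(0, -60, -50, 80, -80, -10, -150),
    a_mm = c(150, 100, 30, 95, 35, 35, 32),
    b_mm = c(90, 60, 23, 55, 25, 25, 22),
    c_mm = c(220, 48, 22.5, 70, 30, 30, 38),
    mu_cm = c(0.15, 0.15, 0.15, 0.04, 0.15, 0.15, 0.15)
  )
}

#' Construct a digital phantom geometry
#'
#' @param shape Integer vector of length 3, grid size in voxels
#'   (lateral, anterior-posterior, axial).
#' @param voxel_mm Isotropic voxel size in mm.
#' @param regions Region table as returned by [phantom_regions()].
#' @param validate If `TRUE`, check that the tumor ellipsoid is fully
#'   contained in the liver ellipsoid.
#' @return An object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(shape = c(40L, 24L, 56L), voxel_mm = 8,
                             regions = phantom_regions(), validate = TRUE) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0L), voxel_mm > 0)
  req <- c("region", "cx_mm", "cy_mm", "cz_mm", "a_mm", "b_mm", "c_mm", "mu_cm")
  if (!all(req %in% names(regions))) {
    abort("`regions` must have columns region, cx_mm..cz_mm, a_mm..c_mm, mu_cm.")
  }
  if (any(regions$mu_cm < 0)) abort("Attenuation coefficients must be >= 0.")
  if (anyDuplicated(regions$region)) abort("Region names must be unique.")
  geom <- structure(
    list(shape = shape, voxel_mm = voxel_mm, regions = as_tibble(regions)),
    class = "phantom_geometry"
  )
  if (validate && all(c("tumor", "liver") %in% regions$region)) {
    if (!tumor_inside_liver(regions)) {
      abort("Tumor ellipsoid is not fully contained in the liver ellipsoid.")
    }
  }
  geom
}

# Dense sampling of the tumor ellipsoid surface, checked against the liver
# quadratic form.
tumor_inside_liver <- function(regions) {
  tu <- regions[regions$region == "tumor", ]
  li <- regions[regions$region == "liver", ]
  th <- seq(0, pi, length.out = 60)
  ph <- seq(0, 2 * pi, length.out = 120)
  g <- expand.grid(th = th, ph = ph)
  x <- tu$cx_mm + tu$a_mm * sin(g$th) * cos(g$ph)
  y <- tu$cy_mm + tu$b_mm * sin(g$th) * sin(g$ph)
  z <- tu$cz_mm + tu$c_mm * cos(g$th)
  q <- ((x - li$cx_mm) / li$a_mm)^2 + ((y - li$cy_mm) / li$b_mm)^2 +
    ((z - li$cz_mm) / li$c_mm)^2
  all(q <= 1 + 1e-9)
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat("<phantom_geometry> grid", paste(x$shape, collapse = " x "),
      "voxels @", x$voxel_mm, "mm;", nrow(x$regions), "regions\n")
  invisible(x)
}

voxel_centres <- function(n, voxel_mm) {
  (seq_len(n) - 0.5) * voxel_mm - n * voxel_mm / 2
}

#' Voxelize a phantom into a region label volume
#'
#' Labels are mutually exclusive. Regions are painted in the order body,
#' lungs, stomach, spleen, kidneys, liver, tumor, so the tumor takes
#' precedence over the liver and organs take precedence over the body.
#'
#' @param geom A [phantom_geometry()].
#' @return Integer array of region codes (see [region_codes()]).
#' @export
voxelize <- function(geom) {
  stopifnot(inherits(geom, "phantom_geometry"))
  x <- voxel_centres(geom$shape[1], geom$voxel_mm)
  y <- voxel_centres(geom$shape[2], geom$voxel_mm)
  z <- voxel_centres(geom$shape[3], geom$voxel_mm)
  labels <- array(REGION_CODES[["background"]], dim = geom$shape)
  paint_order <- c("body", "lungs", "stomach", "spleen", "kidneys", "liver", "tumor")
  for (rn in paint_order) {
    row <- geom$regions[geom$regions$region == rn, ]
    if (nrow(row) == 0L) next
    qx <- ((x - row$cx_mm) / row$a_mm)^2
    qy <- ((y - row$cy_mm) / row$b_mm)^2
    qz <- ((z - row$cz_mm) / row$c_mm)^2
    inside <- outer(outer(qx, qy, "+"), qz, "+") <= 1
    labels[inside] <- REGION_CODES[[rn]]
  }
  labels
}

#' Attenuation coefficient map (1/cm) from a label volume
#'
#' @param geom A [phantom_geometry()].
#' @param labels Label volume from [voxelize()].
#' @return Numeric array of linear attenuation coefficients.
#' @export
attenuation_map <- function(geom, labels = voxelize(geom)) {
  mu <- array(0, dim = dim(labels))
  for (i in seq_len(nrow(geom$regions))) {
    code <- REGION_CODES[[geom$regions$region[i]]]
    mu[labels == code] <- geom$regions$mu_cm[i]
  }
  mu
}

#' Region volumes from voxel membership
#'
#' @param labels Label volume.
#' @param voxel_mm Voxel size in mm.
#' @return Tibble with `region`, `n_voxels`, `volume_mL`.
#' @export
region_volumes <- function(labels, voxel_mm) {
  voxel_mL <- voxel_mm^3 / 1000
  counts <- table(factor(labels, levels = REGION_CODES,
                         labels = names(REGION_CODES)))
  tibble(
    region = names(counts),
    n_voxels = as.integer(counts),
    volume_mL = as.numeric(counts) * voxel_mL
  )
}
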