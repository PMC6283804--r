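# Shared fixtures: small phantoms and fully specified kinetics built in code.

# Uniform-attenuator phantom: one body ellipsoid so large that every voxel
# is attenuating tissue; used for closed-form conjugate-view checks.
slab_geometry <- function(shape = c(9L, 16L, 9L), voxel_mm = 10, mu_cm = 0.15) {
  regions <- tibble::tibble(
    region = "body", cx_mm = 0, cy_mm = 0, cz_mm = 0,
    a_mm = 1e4, b_mm = 1e4, c_mm = 1e4, mu_cm = mu_cm
  )
  phantom_geometry(shape, voxel_mm, regions, validate = FALSE)
}

# Kinetics with tumor and liver sharing one half-life, so that every planar
# ROI (the tumor sits inside the liver and their projections mix) decays as
# a single exponential and exact identifiability holds.
exact_kinetics <- function(T_shared = 12.6, A0 = 2000,
                           scan_times = c(3, 24, 48), tau = 0) {
  patient_kinetics(
    uptake_fractions = c(0.05, 0.40, 0.03, 0.02, 0.01, 0.01),
    T_eff_h = c(T_shared, T_shared, 12.0, 10.9, 14.7, 12.8),
    A0_MBq = A0, scan_times_h = scan_times, tau_s = tau
  )
}

noiseless_patient <- function(kin = exact_kinetics(), ...) {
  build_patient(kin, noise = FALSE, blur_fwhm_mm = 0, ...)
}

# One-voxel shell volume of an ellipsoid (Thomsen surface approximation
# times the voxel size), the tolerance for voxelized-vs-analytic volumes.
surface_shell_mL <- function(row, voxel_mm) {
  p <- 1.6075
  s <- 4 * pi * ((row$a_mm^p * row$b_mm^p + row$a_mm^p * row$c_mm^p +
                    row$b_mm^p * row$c_mm^p) / 3)^(1 / p)
  s * voxel_mm / 1000
}

# Independent truncated-normal mean via numerical quadrature of the
# truncated density (oracle for the cohort sampler).
truncnorm_mean_quadrature <- function(mean, sd, lo, hi) {
  z <- stats::integrate(function(x) stats::dnorm(x, mean, sd), lo, hi)$value
  stats::integrate(function(x) x * stats::dnorm(x, mean, sd), lo, hi)$value / z
}

# Piecewise TAC used as the quadrature oracle for the analytic TIA.
piecewise_tac <- function(A_t1, T_eff, t1, t3, T_phys) {
  force(list(A_t1, T_eff, t1, t3, T_phys))
  function(t) {
    lam_e <- log(2) / T_eff
    lam_p <- log(2) / T_phys
    A3 <- A_t1 * exp(-lam_e * (t3 - t1))
    ifelse(t < t1, A_t1 * t / t1,
           ifelse(t <= t3, A_t1 * exp(-lam_e * (t - t1)),
                  A3 * exp(-lam_p * (t - t3))))
  }
}

tia_quadrature <- function(A_t1, T_eff, t1, t3, T_phys, horizon = 2000) {
  f <- piecewise_tac(A_t1, T_eff, t1, t3, T_phys)
  a <- stats::integrate(f, 0, t1)$value
  b <- stats::integrate(f, t1, t3)$value
  c_ <- stats::integrate(f, t3, horizon, rel.tol = 1e-10)$value
  # analytic remainder of the physical tail beyond the horizon
  lam_p <- log(2) / T_phys
  rem <- f(horizon) / lam_p
  a + b + c_ + rem
}
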