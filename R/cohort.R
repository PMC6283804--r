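# Synthetic patient cohorts: population kinetics, sampling, ground truth.

#' Default population parameters for cohort sampling
#'
#' Per-region effective half-life distributions (truncated normal) and uptake
#' fraction distributions at the first scan time. Half-life means/SDs follow
#' the reference-protocol population values observed for Re-188 Lipiodol
#' (tumor 12.5 +/- 1.9 h, liver 12.6 +/- 1.7 h, lungs 12.0 +/- 1.9 h,
#' stomach 10.9 +/- 1.9 h, spleen 14.7 +/- 2.3 h, kidneys 12.8 +/- 2.5 h),
#' truncated to (2 h, 17 h]. Tumor uptake is log-uniform on 1-30% of the
#' injected activity; organ uptake ranges are fixed, physiologically sensible
#' choices (see the methods vignette).
#'
#' @param teff_lo_h,teff_hi_h Truncation bounds for the half-life draws.
#' @return Tibble with one row per region.
#' @export
cohort_population <- function(teff_lo_h = 2, teff_hi_h = 17) {
  tibble(
    region = c("tumor", "liver", "lungs", "stomach", "spleen", "kidneys"),
    teff_mean_h = c(12.5, 12.6, 12.0, 10.9, 14.7, 12.8),
    teff_sd_h = c(1.9, 1.7, 1.9, 1.9, 2.3, 2.5),
    teff_lo_h = teff_lo_h,
    teff_hi_h = teff_hi_h,
    uptake_dist = c("loguniform", "uniform", "uniform", "uniform", "uniform", "uniform"),
    uptake_lo = c(0.01, 0.25, 0.01, 0.01, 0.005, 0.005),
    uptake_hi = c(0.30, 0.55, 0.04, 0.03, 0.02, 0.02)
  )
}

#' Draw from a truncated normal via the inverse CDF
#'
#' @param n Number of draws.
#' @param mean,sd Mean and SD of the parent normal. `sd = 0` returns the mean
#'   (which must lie inside the bounds).
#' @param lo,hi Truncation bounds, draws lie in `(lo, hi]`.
#' @return Numeric vector of length `n`.
#' @export
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  stopifnot(n >= 0, sd >= 0, lo < hi)
  if (sd == 0) {
    if (mean <= lo || mean > hi) {
      abort("Degenerate distribution: mean lies outside the truncation bounds.")
    }
    return(rep(mean, n))
  }
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  if (p_hi - p_lo < 1e-12) {
    abort("Truncation bounds exclude essentially all probability mass.")
  }
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}

#' Sample ground-truth kinetics for a synthetic cohort
#'
#' Each patient receives, per region, an effective half-life drawn from a
#' truncated normal and an uptake fraction (fraction of the injected activity
#' in the region at the first scan time). Injected activities are drawn
#' log-uniformly over the administered-activity range of the study
#' (1296-7162 MBq by default). Scan times default to \{3, 24, 48\} h with
#' optional uniform jitter of +/-1, +/-1, +/-4 h; a configurable fraction of
#' patients is imaged at only two time points.
#'
#' @param n_patients Number of patients (`>= 1`).
#' @param params Population table, see [cohort_population()].
#' @param seed Optional integer seed; identical seeds give identical cohorts.
#' @param constants [re188_constants()].
#' @param A0_range_MBq Injected-activity range (MBq).
#' @param scan_times_h Nominal scan times post-injection (hours, length 2 or 3).
#' @param jitter Apply scan-time jitter?
#' @param jitter_h Half-widths of the uniform jitter per scan time.
#' @param two_scan_fraction Fraction of patients with only two scan times
#'   (the third time is dropped).
#' @param tau_s Camera paralyzable dead-time constant (s).
#' @param cal_cps_per_MBq Planar camera sensitivity (counts/s per MBq).
#' @param slow_fraction,T_slow_h Optional bi-exponential ground truth: a
#'   fraction `slow_fraction` of each region's activity clears with half-life
#'   `T_slow_h` (defaults to the physical half-life) instead of the region
#'   effective half-life. `slow_fraction = 0` gives mono-exponential truth.
#' @param physical_after_h Optional two-phase ground truth for the
#'   scan-interval study: regions clear with their effective half-life up to
#'   this time post-injection and follow pure physical decay afterwards
#'   (emulating a fast-clearing free-radionuclide component that is gone by
#'   the second scan). `NULL` keeps the single-phase model.
#' @return Tibble with one row per patient x region: `patient_id`, `region`,
#'   `uptake_fraction`, `T_eff_h`, plus per-patient columns `A0_MBq`, `t1_h`,
#'   `t2_h`, `t3_h`, `tau_s`, `cal_cps_per_MBq`, `slow_fraction`, `T_slow_h`,
#'   `T_phys_h`.
#' @export
sample_cohort <- function(n_patients, params = cohort_population(), seed = NULL,
                          constants = re188_constants(),
                          A0_range_MBq = c(1296, 7162),
                          scan_times_h = c(3, 24, 48),
                          jitter = FALSE, jitter_h = c(1, 1, 4),
                          two_scan_fraction = 0,
                          tau_s = 1e-6, cal_cps_per_MBq = 6,
                          slow_fraction = 0, T_slow_h = NULL,
                          physical_after_h = NULL) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    abort("`n_patients` must be >= 1.")
  }
  n_patients <- as.integer(n_patients)
  stopifnot(all(is.finite(params$teff_mean_h)), all(is.finite(params$teff_sd_h)))
  if (any(params$teff_hi_h > constants$T_phys_h + 1e-9)) {
    abort("Effective half-life truncation must not exceed the physical half-life.")
  }
  if (length(scan_times_h) < 2L || is.unsorted(scan_times_h, strictly = TRUE)) {
    abort("`scan_times_h` must be at least two strictly increasing times.")
  }
  if (slow_fraction < 0 || slow_fraction >= 1) {
    abort("`slow_fraction` must be in [0, 1).")
  }
  if (!is.null(seed)) set.seed(seed)
  T_slow_h <- T_slow_h %||% constants$T_phys_h

  nr <- nrow(params)
  draws <- vector("list", nr)
  for (i in seq_len(nr)) {
    p <- params[i, ]
    teff <- rtrunc_norm(n_patients, p$teff_mean_h, p$teff_sd_h,
                        p$teff_lo_h, p$teff_hi_h)
    u <- switch(p$uptake_dist,
      loguniform = exp(runif(n_patients, log(p$uptake_lo), log(p$uptake_hi))),
      uniform = runif(n_patients, p$uptake_lo, p$uptake_hi),
      abort(paste0("Unknown uptake distribution: ", p$uptake_dist))
    )
    draws[[i]] <- tibble(
      patient_id = seq_len(n_patients), region = p$region,
      uptake_fraction = u, T_eff_h = teff
    )
  }
  out <- dplyr::arrange(dplyr::bind_rows(draws), .data$patient_id)

  # renormalize any patient whose uptake fractions sum above 1 (not expected
  # under the defaults, but required by the invariant)
  tot <- tapply(out$uptake_fraction, out$patient_id, sum)
  over <- names(tot)[tot > 1]
  if (length(over)) {
    idx <- out$patient_id %in% as.integer(over)
    out$uptake_fraction[idx] <- out$uptake_fraction[idx] /
      tot[as.character(out$patient_id[idx])]
  }

  A0 <- exp(runif(n_patients, log(A0_range_MBq[1]), log(A0_range_MBq[2])))
  times <- matrix(rep(scan_times_h, each = n_patients), nrow = n_patients)
  if (jitter) {
    for (k in seq_along(scan_times_h)) {
      times[, k] <- times[, k] + runif(n_patients, -jitter_h[k], jitter_h[k])
    }
  }
  t3 <- if (length(scan_times_h) >= 3L) times[, 3] else rep(NA_real_, n_patients)
  if (two_scan_fraction > 0 && length(scan_times_h) >= 3L) {
    drop <- runif(n_patients) < two_scan_fraction
    t3[drop] <- NA_real_
  }
  per_patient <- tibble(
    patient_id = seq_len(n_patients),
    A0_MBq = A0, t1_h = times[, 1], t2_h = times[, 2], t3_h = t3,
    tau_s = tau_s, cal_cps_per_MBq = cal_cps_per_MBq,
    slow_fraction = slow_fraction, T_slow_h = T_slow_h,
    physical_after_h = physical_after_h %||% NA_real_,
    T_phys_h = constants$T_phys_h
  )
  dplyr::left_join(out, per_patient, by = "patient_id")
}

#' Ground-truth region activity at arbitrary times
#'
#' Evaluates the generative time-activity model for one cohort row:
#' `A(t) = f * A0 * [(1 - w) * 2^(-(t - t1)/T_eff) + w * 2^(-(t - t1)/T_slow)]`
#' where `w` is the slow (bi-exponential) fraction, zero by default. With a
#' two-phase model (`physical_after_h` set), the curve follows the effective
#' half-life up to the break time and pure physical decay afterwards.
#'
#' @param kin One row of a [sample_cohort()] tibble.
#' @param times_h Times post-injection (h).
#' @return Activity in MBq at each time.
#' @export
ground_truth_activity <- function(kin, times_h) {
  stopifnot(nrow(kin) == 1L)
  brk <- kin$physical_after_h %||% NA_real_
  base <- function(tt) {
    dt <- tt - kin$t1_h
    w <- kin$slow_fraction %||% 0
    if (is.na(w)) w <- 0
    fast <- 2^(-dt / kin$T_eff_h)
    slow <- if (w > 0) 2^(-dt / kin$T_slow_h) else 0
    kin$uptake_fraction * kin$A0_MBq * ((1 - w) * fast + w * slow)
  }
  if (is.na(brk)) return(base(times_h))
  ifelse(times_h <= brk, base(times_h),
         base(brk) * 2^(-(times_h - brk) / kin$T_phys_h))
}

#' Manually specify one patient's ground-truth kinetics
#'
#' Convenience constructor producing the same row format as
#' [sample_cohort()], for fully controlled test scenarios.
#'
#' @param regions Character vector of region names.
#' @param uptake_fractions,T_eff_h Per-region values (recycled).
#' @param A0_MBq Injected activity (MBq).
#' @param scan_times_h Two or three scan times (h).
#' @param tau_s,cal_cps_per_MBq Camera model parameters.
#' @param slow_fraction,T_slow_h Optional bi-exponential component.
#' @param physical_after_h Optional two-phase break time (see
#'   [sample_cohort()]).
#' @param constants [re188_constants()].
#' @return Tibble with one row per region.
#' @export
patient_kinetics <- function(regions = ACTIVE_REGIONS,
                             uptake_fractions, T_eff_h,
                             A0_MBq = 2000, scan_times_h = c(3, 24, 48),
                             tau_s = 0, cal_cps_per_MBq = 6,
                             slow_fraction = 0, T_slow_h = NULL,
                             physical_after_h = NULL,
                             constants = re188_constants()) {
  n <- length(regions)
  uptake_fractions <- rep_len(uptake_fractions, n)
  T_eff_h <- rep_len(T_eff_h, n)
  if (any(uptake_fractions <= 0) || sum(uptake_fractions) > 1) {
    abort("Uptake fractions must be positive and sum to at most 1.")
  }
  if (any(T_eff_h <= 0) || any(T_eff_h > constants$T_phys_h + 1e-9)) {
    abort("Effective half-lives must lie in (0, T_phys].")
  }
  tibble(
    patient_id = 1L, region = regions,
    uptake_fraction = uptake_fractions, T_eff_h = T_eff_h,
    A0_MBq = A0_MBq,
    t1_h = scan_times_h[1], t2_h = scan_times_h[2],
    t3_h = if (length(scan_times_h) >= 3L) scan_times_h[3] else NA_real_,
    tau_s = tau_s, cal_cps_per_MBq = cal_cps_per_MBq,
    slow_fraction = slow_fraction,
    T_slow_h = T_slow_h %||% constants$T_phys_h,
    physical_after_h = physical_after_h %||% NA_real_,
    T_phys_h = constants$T_phys_h
  )
}
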