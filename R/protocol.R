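# Scan-protocol sparsification study: TIACs from time-point subsets and
# single-scan protocols, percent differences against the three-point
# reference, rank-sum tests, and box-plot summaries.

#' Specify an imaging protocol
#'
#' Either a subset of the patient's scan times (at least two), from which
#' the kinetics are refit, or a single-scan rule combining the SPECT
#' activity at `t1` with an assumed half-life (the physical half-life, or a
#' population effective half-life).
#'
#' @param times_h Scan-time subset (h) for a subset protocol.
#' @param assumed For a single-scan protocol: `"physical"`, `"population"`,
#'   or a numeric half-life in hours.
#' @param name Optional display name; derived from the inputs by default.
#' @return Object of class `protocol_spec`.
#' @export
protocol_spec <- function(times_h = NULL, assumed = NULL, name = NULL) {
  if (is.null(times_h) == is.null(assumed)) {
    abort("Give exactly one of `times_h` (subset) or `assumed` (single-scan).")
  }
  if (!is.null(times_h)) {
    if (length(times_h) < 2L || is.unsorted(times_h, strictly = TRUE)) {
      abort("Subset protocols need at least two strictly increasing times.")
    }
    type <- "subset"
    name <- name %||% paste0("{", paste(times_h, collapse = ","), "}")
  } else {
    if (is.character(assumed)) {
      assumed <- match.arg(assumed, c("physical", "population"))
    } else if (!is.numeric(assumed) || assumed <= 0) {
      abort("`assumed` must be 'physical', 'population', or a positive number.")
    }
    type <- "single"
    name <- name %||% paste0("{t1}+", if (is.character(assumed)) {
      if (assumed == "physical") "Tphys" else "Teff"
    } else paste0(assumed, "h"))
  }
  structure(list(type = type, times_h = times_h, assumed = assumed,
                 name = name),
            class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("<protocol_spec>", x$name, "\n")
  invisible(x)
}

#' The standard protocol set of the sparsification study
#'
#' @param scan_times_h The full three-point schedule.
#' @return Named list of [protocol_spec()] objects: the three two-point
#'   subsets and the two single-scan rules.
#' @export
standard_protocols <- function(scan_times_h = c(3, 24, 48)) {
  t <- scan_times_h
  ps <- list(
    protocol_spec(times_h = t[c(1, 2)]),
    protocol_spec(times_h = t[c(1, 3)]),
    protocol_spec(times_h = t[c(2, 3)]),
    protocol_spec(assumed = "physical"),
    protocol_spec(assumed = "population")
  )
  setNames(ps, vapply(ps, function(p) p$name, ""))
}

#' TIAC of one region under an imaging protocol
#'
#' Subset protocols refit the mono-exponential on the matching relative-TAC
#' samples, rescale with the SPECT activity at `t1` (the fitted curve is
#' evaluated at `t1`, extrapolating when `t1` is not in the subset), and
#' integrate with the physical-decay tail attached at the subset's last
#' time. Single-scan protocols use the SPECT activity directly with the
#' assumed half-life from `t1` to infinity (plus the linear rise).
#'
#' @param tac Tibble of one region's samples: `time_h`, `rate`, optionally
#'   `sigma`.
#' @param spect_activity_MBq Absolute activity at `t1_h`.
#' @param A0_MBq Injected activity (MBq).
#' @param protocol A [protocol_spec()].
#' @param t1_h SPECT time (h); defaults to the earliest TAC sample time.
#' @param population_T_eff_h Population effective half-life used by the
#'   `"population"` single-scan rule (12.6 h, the liver population value).
#' @param constants [re188_constants()].
#' @param time_tol_h Matching tolerance between protocol times and sample
#'   times.
#' @return One-row tibble: `protocol`, `T_eff_h`, `tia_MBq_h`, `tiac_h`.
#' @export
tiac_under_protocol <- function(tac, spect_activity_MBq, A0_MBq, protocol,
                                t1_h = NULL, population_T_eff_h = 12.6,
                                constants = re188_constants(),
                                time_tol_h = 1e-6) {
  stopifnot(inherits(protocol, "protocol_spec"))
  t1_h <- t1_h %||% min(tac$time_h)
  if (protocol$type == "subset") {
    idx <- vapply(protocol$times_h, function(tt) {
      j <- which(abs(tac$time_h - tt) <= time_tol_h)
      if (length(j) != 1L) {
        abort(sprintf("Scan time %g h required by protocol %s is missing.",
                      tt, protocol$name))
      }
      j
    }, integer(1))
    sub <- tac[idx, ]
    fit <- fit_monoexp(sub$time_h, sub$rate,
                       if ("sigma" %in% names(sub)) sub$sigma else NULL)
    abs_tac <- rescale_to_absolute(fit, spect_activity_MBq, t1_h)
    res <- integrate_tia(abs_tac$A_t1_MBq, abs_tac$T_eff_h, t1_h,
                         last_scan_h = max(sub$time_h), constants = constants)
    T_used <- fit$T_eff_h
  } else {
    T_used <- if (is.numeric(protocol$assumed)) {
      protocol$assumed
    } else if (protocol$assumed == "physical") {
      constants$T_phys_h
    } else {
      population_T_eff_h
    }
    res <- integrate_tia(spect_activity_MBq, T_used, t1_h,
                         last_scan_h = NULL, constants = constants,
                         tail_half_life_h = T_used)
  }
  tibble(protocol = protocol$name, T_eff_h = T_used,
         tia_MBq_h = res$tia_MBq_h, tiac_h = tiac(res$tia_MBq_h, A0_MBq))
}

#' Percent difference against a reference
#'
#' `100 * (x - ref) / ref`, the comparison metric of the protocol study.
#'
#' @param x,ref Numeric (vectorized); `ref` must be non-zero.
#' @return Percent differences.
#' @export
percent_difference <- function(x, ref) {
  if (any(ref == 0)) abort("Reference value must be non-zero.")
  100 * (x - ref) / ref
}

#' Compare imaging protocols across a cohort
#'
#' For every patient/region, computes the TIAC under each protocol and under
#' the full three-point reference, and the percent difference between them.
#'
#' @param tacs Tidy relative TACs: `patient_id`, `region`, `time_h`, `rate`,
#'   optionally `sigma`.
#' @param spect Tibble with `patient_id`, `region`, `activity_MBq` (SPECT at
#'   `t1`) and `A0_MBq`.
#' @param protocols List of [protocol_spec()]s (default [standard_protocols()]
#'   on each patient's own times).
#' @param regions Regions to compare (tumor, liver, lungs by default — the
#'   regions of interest of the therapy).
#' @param population_T_eff_h,constants See [tiac_under_protocol()].
#' @return Tibble: `patient_id`, `region`, `protocol`, `tiac_h`,
#'   `tiac_ref_h`, `pct_diff`.
#' @export
compare_protocols <- function(tacs, spect, protocols = NULL,
                              regions = c("tumor", "liver", "lungs"),
                              population_T_eff_h = 12.6,
                              constants = re188_constants()) {
  stopifnot(all(c("patient_id", "region", "time_h", "rate") %in% names(tacs)))
  stopifnot(all(c("patient_id", "region", "activity_MBq", "A0_MBq") %in% names(spect)))
  tacs <- tacs[tacs$region %in% regions, ]
  out <- list()
  for (pid in unique(tacs$patient_id)) {
    ptac <- tacs[tacs$patient_id == pid, ]
    times <- sort(unique(ptac$time_h))
    if (length(times) < 3L) next # reference requires the full schedule
    prots <- protocols %||% standard_protocols(times)
    ref_spec <- protocol_spec(times_h = times, name = "reference")
    for (rg in intersect(regions, unique(ptac$region))) {
      rtac <- ptac[ptac$region == rg, ]
      srow <- spect[spect$patient_id == pid & spect$region == rg, ]
      if (nrow(srow) != 1L) next
      ref <- tiac_under_protocol(rtac, srow$activity_MBq, srow$A0_MBq,
                                 ref_spec, t1_h = times[1],
                                 population_T_eff_h, constants)
      for (p in prots) {
        r <- tiac_under_protocol(rtac, srow$activity_MBq, srow$A0_MBq, p,
                                 t1_h = times[1], population_T_eff_h,
                                 constants)
        out[[length(out) + 1L]] <- tibble(
          patient_id = pid, region = rg, protocol = p$name,
          tiac_h = r$tiac_h, tiac_ref_h = ref$tiac_h,
          pct_diff = percent_difference(r$tiac_h, ref$tiac_h)
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' The statistic is `U = #\{(x, y): x > y\} + 0.5 * #ties`. The two-sided p
#' value is computed by exact enumeration of all assignments of the pooled
#' sample when `n_x + n_y <= exact_threshold` (ties handled exactly), and by
#' the normal approximation with tie correction and continuity correction
#' otherwise.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_threshold Combined-size limit for exact enumeration.
#' @return One-row tibble: `statistic` (U), `p.value`, `method`, `n_x`, `n_y`.
#' @export
ranksum_test <- function(x, y, exact_threshold = 12L) {
  if (!length(x) || !length(y)) abort("Both samples must be non-empty.")
  m <- length(x); n <- length(y)
  u_stat <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u <- u_stat(x, y)
  if (m + n <= exact_threshold) {
    pooled <- c(x, y)
    combos <- combn(m + n, m)
    us <- apply(combos, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
    p <- min(1, 2 * min(mean(us <= u + 1e-12), mean(us >= u - 1e-12)))
    method <- "exact enumeration"
  } else {
    N <- m + n
    ties <- table(c(x, y))
    mu <- m * n / 2
    sig2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation with tie correction"
  }
  tibble(statistic = u, p.value = p, method = method, n_x = m, n_y = n)
}

#' Box-plot summary statistics
#'
#' Median and quartiles (linear interpolation between order statistics by
#' default), whiskers at the most extreme data within `whisker_k` times the
#' inter-quartile range beyond the quartiles, and the outliers beyond the
#' whiskers.
#'
#' @param values Numeric, length `>= 1`.
#' @param whisker_k Whisker reach in IQR units.
#' @param quantile_type Quantile convention passed to [stats::quantile()].
#' @return One-row tibble: `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`, `n_outliers`, and list-column `outliers`.
#' @export
boxplot_summary <- function(values, whisker_k = 1.5, quantile_type = 7) {
  if (!length(values)) abort("`values` must be non-empty.")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = quantile_type, names = FALSE)
  iqr <- q[3] - q[1]
  lo_lim <- q[1] - whisker_k * iqr
  hi_lim <- q[3] + whisker_k * iqr
  inside <- values >= lo_lim & values <= hi_lim
  out <- values[!inside]
  tibble(
    median = q[2], q1 = q[1], q3 = q[3],
    whisker_low = min(values[inside]),
    whisker_high = max(values[inside]),
    n_outliers = length(out),
    outliers = list(sort(out))
  )
}
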