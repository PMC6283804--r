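# Mono-exponential pharmacokinetics: weighted fits of time-activity samples,
# effective/biological half-life conversion, rescaling of relative curves to
# absolute activity using the SPECT measurement.

#' Fit a mono-exponential time-activity curve
#'
#' Minimizes `sum w_i (y_i - a * 2^(-t_i / T_eff))^2` with weights
#' `w_i = 1/sigma_i^2` (equal weights when `sigma` is absent). The fit is
#' performed in linear space so the weights keep their meaning; the
#' log-linear (weighted) least-squares solution is used only to initialize.
#' With exactly two points the closed form
#' `T_eff = ln(2) * (t2 - t1) / ln(y1 / y2)` is returned.
#'
#' @param times_h Sample times (h), strictly increasing, length `>= 2`.
#' @param values Positive rates or activities.
#' @param sigma Optional positive uncertainties (same length).
#' @return Object of class `monoexp_fit` with elements `a`, `T_eff_h`,
#'   `cov` (2x2, for `a` and `T_eff_h`), `r_squared`, `n_points`, `data`.
#' @export
fit_monoexp <- function(times_h, values, sigma = NULL) {
  n <- length(times_h)
  if (n < 2L) abort("At least two samples are required.")
  if (length(values) != n) abort("`times_h` and `values` lengths differ.")
  if (is.unsorted(times_h, strictly = TRUE)) {
    abort("Sample times must be strictly increasing.")
  }
  if (any(values <= 0)) abort("Values must be positive.")
  if (!is.null(sigma)) {
    if (length(sigma) != n || any(sigma <= 0)) {
      abort("`sigma` must be positive and match the sample length.")
    }
  }
  if (max(values) == min(values)) {
    abort("Constant samples: no decay to fit (T_eff would be infinite).")
  }
  w <- if (is.null(sigma)) rep(1, n) else 1 / sigma^2
  ln2 <- log(2)

  if (n == 2L) {
    if (values[2] >= values[1]) {
      abort("Non-decaying two-point data: T_eff would be non-positive or infinite.")
    }
    T_eff <- ln2 * (times_h[2] - times_h[1]) / log(values[1] / values[2])
    a <- values[1] * 2^(times_h[1] / T_eff)
    fit <- list(a = a, T_eff_h = T_eff,
                cov = matrix(NA_real_, 2, 2,
                             dimnames = list(c("a", "T_eff_h"), c("a", "T_eff_h"))),
                r_squared = 1, n_points = 2L,
                data = tibble(time_h = times_h, value = values,
                              sigma = sigma %||% NA_real_))
    class(fit) <- "monoexp_fit"
    return(fit)
  }

  # log-linear weighted initializer: var(log y) ~ sigma^2 / y^2
  w_log <- w * values^2
  init <- lm(log(values) ~ times_h, weights = w_log)
  slope <- coef(init)[[2]]
  if (slope >= 0) abort("Non-decaying data: fitted half-life would be negative.")
  start <- list(a = exp(coef(init)[[1]]), T_eff = -ln2 / slope)

  df <- data.frame(t = times_h, y = values, w = w)
  nls_fit <- minpack.lm::nlsLM(
    y ~ a * exp(-ln2 * t / T_eff),
    data = df, start = start, weights = w,
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                         maxiter = 500)
  )
  est <- coef(nls_fit)
  if (est[["T_eff"]] <= 0) abort("Fit converged to a non-positive half-life.")
  yhat <- est[["a"]] * exp(-ln2 * times_h / est[["T_eff"]])
  ybar <- sum(w * values) / sum(w)
  ss_res <- sum(w * (values - yhat)^2)
  ss_tot <- sum(w * (values - ybar)^2)
  cv <- tryCatch(vcov(nls_fit), error = function(e) matrix(NA_real_, 2, 2))
  dimnames(cv) <- list(c("a", "T_eff_h"), c("a", "T_eff_h"))
  fit <- list(
    a = est[["a"]], T_eff_h = est[["T_eff"]], cov = cv,
    r_squared = 1 - ss_res / ss_tot, n_points = as.integer(n),
    data = tibble(time_h = times_h, value = values,
                  sigma = sigma %||% NA_real_)
  )
  class(fit) <- "monoexp_fit"
  fit
}

#' @export
print.monoexp_fit <- function(x, ...) {
  cat(sprintf("<monoexp_fit> a = %.6g, T_eff = %.4f h, R^2 = %.4f (n = %d)\n",
              x$a, x$T_eff_h, x$r_squared, x$n_points))
  invisible(x)
}

#' Evaluate a fitted mono-exponential
#' @param object A `monoexp_fit`.
#' @param times_h Times (h) at which to evaluate.
#' @param ... Unused.
#' @return Fitted values.
#' @export
predict.monoexp_fit <- function(object, times_h, ...) {
  object$a * 2^(-times_h / object$T_eff_h)
}

#' @method tidy monoexp_fit
#' @export
tidy.monoexp_fit <- function(x, ...) {
  se <- sqrt(diag(x$cov))
  tibble(
    term = c("a", "T_eff_h"),
    estimate = c(x$a, x$T_eff_h),
    std.error = as.numeric(se)
  )
}

#' @method glance monoexp_fit
#' @export
glance.monoexp_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, n = x$n_points,
         a = x$a, T_eff_h = x$T_eff_h)
}

#' Fit mono-exponentials to a tidy table of relative TACs
#'
#' @param tacs Tibble with columns `region`, `time_h`, `rate` and optionally
#'   `sigma` (as from [extract_relative_tacs()]).
#' @param weighted Use `1/sigma^2` weights when `sigma` is present?
#' @param constants [re188_constants()]; used to derive the biological
#'   half-life and to warn when a fitted `T_eff` exceeds the physical one.
#' @return Tibble with one row per region: `a`, `T_eff_h`, `T_bio_h`,
#'   `r_squared`, `n_points`, and a list-column `fit`.
#' @export
fit_tacs <- function(tacs, weighted = TRUE, constants = re188_constants()) {
  stopifnot(all(c("region", "time_h", "rate") %in% names(tacs)))
  has_sigma <- weighted && "sigma" %in% names(tacs)
  grp <- split(tacs, tacs$region)
  purrr::map_dfr(grp, function(g) {
    g <- g[order(g$time_h), ]
    f <- fit_monoexp(g$time_h, g$rate, if (has_sigma) g$sigma else NULL)
    if (f$T_eff_h > constants$T_phys_h) {
      warn(sprintf("Region %s: fitted T_eff (%.2f h) exceeds the physical half-life.",
                   g$region[1], f$T_eff_h))
    }
    T_bio <- if (f$T_eff_h > constants$T_phys_h) NA_real_
             else effective_to_biological(f$T_eff_h, constants)
    tibble(region = g$region[1], a = f$a, T_eff_h = f$T_eff_h,
           T_bio_h = T_bio, r_squared = f$r_squared,
           n_points = f$n_points, fit = list(f))
  })
}

#' Convert an effective half-life to a biological half-life
#'
#' The decay rates add: `1/T_eff = 1/T_phys + 1/T_bio`, so
#' `T_bio = 1 / (1/T_eff - 1/T_phys)`. An effective half-life equal to the
#' physical one means no biological clearance (`T_bio = Inf`); a larger one
#' is unphysical for a closed system and raises an error.
#'
#' @param T_eff_h Effective half-life (h), in `(0, T_phys]`.
#' @param constants [re188_constants()].
#' @return Biological half-life (h), possibly `Inf`.
#' @export
effective_to_biological <- function(T_eff_h, constants = re188_constants()) {
  Tp <- constants$T_phys_h
  if (any(T_eff_h <= 0)) abort("`T_eff_h` must be positive.")
  if (any(T_eff_h > Tp + 1e-12)) {
    abort("`T_eff_h` exceeds the physical half-life; unphysical for a closed system.")
  }
  ifelse(abs(T_eff_h - Tp) <= 1e-12, Inf, 1 / (1 / T_eff_h - 1 / Tp))
}

#' Convert a biological half-life to an effective half-life
#' @inheritParams effective_to_biological
#' @param T_bio_h Biological half-life (h), positive; `Inf` means no
#'   biological clearance.
#' @return Effective half-life (h).
#' @export
biological_to_effective <- function(T_bio_h, constants = re188_constants()) {
  if (any(T_bio_h <= 0)) abort("`T_bio_h` must be positive.")
  1 / (1 / T_bio_h + 1 / constants$T_phys_h)
}

#' Rescale a relative TAC fit to absolute activity
#'
#' Anchors the fitted relative curve to the absolute SPECT activity at the
#' SPECT time: the returned curve satisfies `A(t1) = A_spect` exactly, with
#' the shape of the fitted exponential. By default the relative value at
#' `t1` is the fitted curve evaluated at `t1` (not the raw first sample).
#'
#' @param fit A `monoexp_fit` of the relative TAC.
#' @param spect_activity_MBq Absolute activity at `t1_h` from SPECT.
#' @param t1_h SPECT acquisition time (h).
#' @param rel_at_t1 Relative value at `t1` used for the scale; defaults to
#'   `predict(fit, t1_h)`. Pass the raw first sample for sensitivity checks.
#' @return Object of class `absolute_tac` with elements `a_MBq`, `T_eff_h`,
#'   `t1_h`, `A_t1_MBq`.
#' @export
rescale_to_absolute <- function(fit, spect_activity_MBq, t1_h,
                                rel_at_t1 = NULL) {
  stopifnot(inherits(fit, "monoexp_fit"))
  if (spect_activity_MBq < 0) abort("SPECT activity must be >= 0.")
  rel_at_t1 <- rel_at_t1 %||% predict(fit, t1_h)
  if (rel_at_t1 <= 0) abort("Relative activity at t1 must be positive.")
  if (spect_activity_MBq == 0) {
    warn("SPECT activity is zero; the absolute TAC is identically zero.")
  }
  structure(
    list(
      a_MBq = fit$a * spect_activity_MBq / rel_at_t1,
      T_eff_h = fit$T_eff_h,
      t1_h = t1_h,
      A_t1_MBq = spect_activity_MBq,
      fit = fit
    ),
    class = "absolute_tac"
  )
}

#' Evaluate an absolute TAC
#' @param object An `absolute_tac`.
#' @param times_h Times post-injection (h).
#' @param ... Unused.
#' @return Activity in MBq.
#' @export
predict.absolute_tac <- function(object, times_h, ...) {
  object$a_MBq * 2^(-times_h / object$T_eff_h)
}

#' @export
print.absolute_tac <- function(x, ...) {
  cat(sprintf("<absolute_tac> A(t1=%.2f h) = %.3f MBq, T_eff = %.4f h\n",
              x$t1_h, x$A_t1_MBq, x$T_eff_h))
  invisible(x)
}
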