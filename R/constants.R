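#' Physical constants of the therapeutic radionuclide
#'
#' Bundles the decay properties used throughout the dose calculations:
#' the physical half-life and the mean beta energy emitted per decay,
#' which drives the default local-deposition S-factors. Defaults describe
#' Re-188 (physical half-life 17 h, mean beta energy 0.763 MeV).
#'
#' @param T_phys_h Physical half-life in hours.
#' @param mean_beta_MeV Mean beta energy per decay in MeV.
#' @return An object of class `nuclide_constants`.
#' @examples
#' re188_constants()
#' @export
re188_constants <- function(T_phys_h = 17, mean_beta_MeV = 0.763) {
  if (!is.numeric(T_phys_h) || length(T_phys_h) != 1L || T_phys_h <= 0) {
    abort("`T_phys_h` must be a single positive number.")
  }
  if (!is.numeric(mean_beta_MeV) || length(mean_beta_MeV) != 1L || mean_beta_MeV <= 0) {
    abort("`mean_beta_MeV` must be a single positive number.")
  }
  structure(
    list(T_phys_h = T_phys_h, mean_beta_MeV = mean_beta_MeV),
    class = "nuclide_constants"
  )
}

#' @export
print.nuclide_constants <- function(x, ...) {
  cat("<nuclide_constants>  T_phys =", x$T_phys_h, "h,  mean beta energy =",
      x$mean_beta_MeV, "MeV\n")
  invisible(x)
}

# Joules deposited per MBq.h per MeV of mean beta energy
MEV_J <- 1.602176634e-13
DECAYS_PER_MBQ_H <- 3.6e9
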