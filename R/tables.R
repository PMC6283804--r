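# Packaged clinical reference tables for the Re-188 Lipiodol study cohort.

#' Clinical cohort: patient records
#'
#' The 14 treatment records (13 patients, one treated twice) of the Re-188
#' Lipiodol radioembolization cohort: administered activity, planar scan
#' times post-injection (four treatments were imaged at only two time
#' points), and tumor/liver volumes.
#'
#' @return Tibble with `patient_id`, `age_y`, `sex`, `A0_MBq`, `t1_h`,
#'   `t2_h`, `t3_h`, `tumor_mL`, `liver_mL`.
#' @export
lipiodol_patients <- function() {
  path <- system.file("extdata", "table1_patients.csv", package = "redosim",
                      mustWork = TRUE)
  as_tibble(utils::read.csv(path, colClasses = c(patient_id = "character")))
}

#' Clinical cohort: normalized absorbed doses
#'
#' Per-treatment normalized absorbed doses (mGy per MBq injected) for the
#' tumor and the organs at risk. `NA` marks regions that could not be
#' quantified for that treatment.
#'
#' @param tidy Return long format (`patient_id`, `region`,
#'   `normalized_mGy_per_MBq`) instead of the wide table?
#' @return Tibble.
#' @export
lipiodol_normalized_doses <- function(tidy = TRUE) {
  path <- system.file("extdata", "table2_normalized_doses.csv",
                      package = "redosim", mustWork = TRUE)
  wide <- as_tibble(utils::read.csv(path,
                                    colClasses = c(patient_id = "character")))
  if (!tidy) return(wide)
  tidyr::pivot_longer(wide, -"patient_id", names_to = "region",
                      values_to = "normalized_mGy_per_MBq")
}

#' Cohort dose summary of the packaged clinical tables
#'
#' Convenience wrapper joining the packaged normalized doses with the
#' packaged injected activities and recomputing all cohort summary rows
#' (normalized and absolute mean/SD/min/max per region).
#'
#' @return A [summarize_dose_table()] result.
#' @export
lipiodol_dose_summary <- function() {
  summarize_dose_table(lipiodol_normalized_doses(), lipiodol_patients())
}
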