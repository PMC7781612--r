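#' Demographics of the 20-patient stroke cohort the pipeline is designed for
#'
#' The published participant table of the subacute stroke cohort whose study
#' design (sample size, lesion heterogeneity, usable fMRI volumes) the
#' synthetic generator emulates: per-subject handedness, lesion site and
#' side, lesion volume in cm^3, stroke type (ischemic/hemorrhagic), sex,
#' days post-stroke, age, and arm-motor Fugl-Meyer score (0-66).
#'
#' @return A tibble with 20 rows.
#' @export
#' @examples
#' demo <- cohort_demographics()
#' mean(demo$lesion_volume_cm3)
cohort_demographics <- function() {
  path <- system.file("extdata", "stroke_cohort_demographics.tsv",
                      package = "lesionfc", mustWork = TRUE)
  tibble::as_tibble(read.delim(path, sep = "\t", check.names = FALSE))
}
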