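#' Published reference cohort: normalized organ doses
#'
#' Normalized absorbed doses for the organs at risk (Gy/GBq) and normalized
#' effective doses (mSv/MBq) of the eight evaluable patients of a published
#' first-in-human Lu-177-DOTA-zoledronate dosimetry cohort (metastatic
#' castration-resistant prostate cancer with skeletal metastases; patient 5
#' of the original nine was excluded for corrupted SPECT data, so patient
#' numbers skip 5). These printed per-patient values are inputs for the
#' planning arithmetic -- MTA, limiting organ, therapeutic indices, cohort
#' statistics -- which this package recomputes from them; the underlying
#' image data are not public.
#'
#' @return A tibble with `patient` (character, "1", "2", "3", "4", "6",
#'   "7", "8", "9") and columns `red_marrow`, `kidneys`, `bone_surfaces`
#'   (Gy/GBq), `effective_dose` (mSv/MBq).
#' @seealso [zol_reference_tumor_doses()]
#' @export
zol_reference_doses <- function() {
  tibble::tibble(
    patient = c("1", "2", "3", "4", "6", "7", "8", "9"),
    red_marrow = c(0.326, 0.346, 0.564, 0.499, 0.301, 0.206, 0.226, 0.375),
    kidneys = c(0.063, 0.097, 0.054, 0.053, 0.078, 0.094, 0.250, 0.691),
    bone_surfaces = c(1.080, 1.180, 1.980, 1.780, 1.040, 0.635, 0.641, 1.220),
    effective_dose = c(0.143, 0.130, 0.216, 0.177, 0.109, 0.095, 0.106, 0.158)
  )
}

#' Published reference cohort: normalized tumor doses
#'
#' Per-lesion normalized absorbed doses (Gy/GBq) of the same published
#' cohort as [zol_reference_doses()]: five lesions per patient (four for
#' patient 9), 39 in total.
#'
#' @return A tibble with `patient`, `lesion` (1--5) and `dose_Gy_per_GBq`.
#' @export
zol_reference_tumor_doses <- function() {
  doses <- list(
    "1" = c(5.02, 2.37, 5.37, 6.98, 2.53),
    "2" = c(5.15, 3.70, 1.72, 0.92, 1.56),
    "3" = c(3.63, 3.00, 1.65, 1.66, 4.10),
    "4" = c(2.85, 3.86, 2.25, 5.91, 4.39),
    "6" = c(2.03, 2.52, 2.79, 3.54, 4.36),
    "7" = c(8.05, 8.94, 3.69, 6.57, 4.26),
    "8" = c(6.13, 3.44, 1.17, 3.26, 2.84),
    "9" = c(7.94, 11.26, 9.27, 3.51)
  )
  purrr::imap(doses, ~ tibble::tibble(patient = .y,
                                      lesion = seq_along(.x),
                                      dose_Gy_per_GBq = .x)) |>
    purrr::list_rbind()
}
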