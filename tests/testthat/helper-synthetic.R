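# Shared fixtures: noiseless synthetic patients and recovery comparison.

noiseless_patient <- function(seed = 1, ...) {
  generate_patient(patient_params(noise_sigma = 0, seed = seed, ...))
}

# Relative recovery error of pipeline cumulated activities vs the
# generator's closed-form ground truth, per region (lesion curves are
# concentration x volume).
recovery_errors <- function(p, regions = NULL) {
  ss <- suppressWarnings(build_source_set(p$bundle))
  curves <- dplyr::bind_rows(ss$curves, ss$tumor_curves)
  if (!is.null(regions)) {
    curves <- curves[curves$region %in% regions, ]
  }
  cum <- suppressWarnings(cumulated_activity(curves))
  cmp <- dplyr::inner_join(cum, p$truth$cumulated, by = "region")
  les <- p$bundle$lesions
  les$region <- paste0("tumor:", les$id)
  cmp <- dplyr::left_join(cmp, les[c("region", "volume_mL")], by = "region")
  scale <- ifelse(is.na(cmp$volume_mL), 1, cmp$volume_mL)
  err <- setNames(cmp$cumulated * scale / cmp$cumulated_MBq_h - 1, cmp$region)
  if (!is.null(regions)) err <- err[regions]
  err
}

# Toy S-value matrix from the worked cross-fire example: marrow receives
# dose from the cortical surface and from itself.
toy_smat <- function() {
  s_matrix(
    tibble::tibble(
      source = c("cortical_surface", "red_marrow"),
      target = c("red_marrow", "red_marrow"),
      s_value_Gy_per_MBq_h = c(2e-6, 1e-5)),
    tibble::tibble(region = c("cortical_surface", "red_marrow"),
                   mass_g = c(4000, 1500))
  )
}
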