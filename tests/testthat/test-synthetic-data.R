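test_that("generated curves match the study magnitudes in %IA/g", {
  p <- noiseless_patient(1)
  a <- p$truth$injected_activity_MBq
  ph <- phantom_constants()
  # skeleton peak near 9.6e-3 %IA/g around 2 h (5500 g bone, leg-complete)
  sk <- dplyr::filter(p$bundle$curves, region == "skeleton")
  sk_full <- scale_for_legs(sk$value)
  peak_ia_g <- max(sk_full) / a / ph$total_bone_mass_g * 100
  expect_gt(peak_ia_g, 0.0075)
  expect_lt(peak_ia_g, 0.0115)
  # blood-derived marrow near 1.4e-3 %IA/g at 1.5 h
  bl <- dplyr::filter(p$bundle$curves, region == "blood")
  conc_1p5 <- bl$value[bl$time_h == 1.5]
  marrow_ia_g <- red_marrow_activity(conc_1p5) / a / ph$red_marrow_mass_g * 100
  expect_gt(marrow_ia_g, 1.1e-3)
  expect_lt(marrow_ia_g, 1.7e-3)
  # lesion concentration near 2.1e-2 %IA/g at 6 h (density 1.92 g/mL)
  t1 <- dplyr::filter(p$bundle$curves, region == "tumor:1")
  les_ia_g <- t1$value[t1$time_h == 6] / ph$tumor_density_g_mL / a * 100
  expect_gt(les_ia_g, 1.5e-2)
  expect_lt(les_ia_g, 2.7e-2)
})

test_that("with zero noise every <=2-exponential region recovers within 1%", {
  err <- recovery_errors(noiseless_patient(1))
  strict <- err[setdiff(names(err), "remainder")]
  expect_true(all(abs(strict) < 0.01))
  expect_lt(abs(err["remainder"]), 0.10)
})

test_that("a zero skeleton fraction produces an identically zero skeleton curve", {
  p <- generate_patient(patient_params(
    noise_sigma = 0, seed = 2,
    skeleton = list(f = 0, k_u = 3.1, k_b = 0.00166)))
  sk <- dplyr::filter(p$bundle$curves, region == "skeleton")
  expect_true(all(sk$value == 0))
  expect_equal(
    dplyr::filter(p$truth$cumulated, region == "skeleton")$cumulated_MBq_h, 0)
})

test_that("the same seed reproduces bit-identical bundles", {
  p1 <- generate_patient(patient_params(noise_sigma = 0.05, seed = 77))
  p2 <- generate_patient(patient_params(noise_sigma = 0.05, seed = 77))
  expect_identical(p1$bundle, p2$bundle)
  expect_identical(p1$truth$cumulated, p2$truth$cumulated)
  p3 <- generate_patient(patient_params(noise_sigma = 0.05, seed = 78))
  expect_false(identical(p1$bundle$curves$value, p3$bundle$curves$value))
})

test_that("at every time the total body covers the summed compartments", {
  p <- noiseless_patient(9)
  wide <- tidyr::pivot_wider(
    dplyr::filter(p$bundle$curves, region != "blood",
                  !grepl("^tumor", region)),
    id_cols = "time_h", names_from = "region", values_from = "value")
  les <- p$bundle$lesions
  tumor_total <- rep(0, nrow(wide))
  for (i in seq_len(nrow(les))) {
    cc <- dplyr::filter(p$bundle$curves,
                        region == paste0("tumor:", les$id[i]))
    tumor_total <- tumor_total + cc$value * les$volume_mL[i]
  }
  # skeleton/total are emitted leg-truncated by the same factor, so the
  # inequality survives the field-of-view scaling of the other terms
  expect_true(all(
    wide$total_body + 1e-9 >=
      wide$skeleton + 0.664 * (wide$kidneys + wide$bladder_content +
                                 tumor_total)))
})

test_that("the lognormal noise multiplier is mean-corrected (unbiased)", {
  ratios <- c()
  for (seed in 1:20) {
    noisy <- generate_patient(patient_params(noise_sigma = 0.05, seed = seed))
    clean <- generate_patient(patient_params(noise_sigma = 0, seed = seed))
    keep <- clean$bundle$curves$value > 0
    ratios <- c(ratios,
                noisy$bundle$curves$value[keep] / clean$bundle$curves$value[keep])
  }
  expect_equal(mean(ratios), 1, tolerance = 3 * 0.05 / sqrt(length(ratios)))
})

test_that("with 5% noise the skeleton and marrow integrals recover within 10% (median)", {
  # smoke-scale replicate run; the full 200-replicate study lives in the
  # acceptance suite
  errs <- sapply(1:25, function(i) {
    p <- generate_patient(patient_params(noise_sigma = 0.05, seed = 3000 + i))
    abs(recovery_errors(p, c("skeleton", "red_marrow")))
  })
  expect_lt(median(errs[1, ]), 0.10)
  expect_lt(median(errs[2, ]), 0.10)
})

test_that("cohorts derive deterministic per-patient seeds and respect n", {
  c1 <- generate_cohort(3, master_seed = 5)
  c2 <- generate_cohort(3, master_seed = 5)
  expect_identical(lapply(c1, function(p) p$bundle),
                   lapply(c2, function(p) p$bundle))
  c3 <- generate_cohort(3, master_seed = 6)
  expect_false(identical(c1[[1]]$bundle$curves$value,
                         c3[[1]]$bundle$curves$value))
  expect_length(generate_cohort(1, master_seed = 2), 1)
  expect_error(generate_cohort(0), ">= 1")
})

test_that("invalid kinetic parameters are rejected", {
  expect_error(patient_params(skeleton = list(f = 0.9, k_u = 3, k_b = 0),
                              kidneys = list(f = 0.2, k_u = 3, k_b = 0.1)),
               "sum")
  expect_error(patient_params(blood = list(b1 = 1e-4, k1 = -1,
                                           b2 = 1e-6, k2 = 0.1)),
               "> 0")
  expect_error(patient_params(noise_sigma = -0.1), ">= 0")
})

test_that("the high-kidney preset raises the kidney residence time markedly", {
  lo <- noiseless_patient(8)
  hi <- generate_patient(patient_params(noise_sigma = 0, seed = 8,
                                        high_kidney = TRUE))
  k <- function(p) dplyr::filter(p$truth$cumulated,
                                 region == "kidneys")$cumulated_MBq_h
  expect_gt(k(hi) / k(lo), 3)
})
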