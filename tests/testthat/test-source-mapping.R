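test_that("the blood-to-marrow conversion follows the 1500 g / 1.05 g/mL model", {
  expect_equal(red_marrow_activity(0.07), 100)
  expect_equal(red_marrow_activity(0), 0)
  expect_equal(red_marrow_activity(0.001, phantom_constants(rmblr = 0.36)),
               0.36 * 0.001 * 1500 / 1.05)
  expect_error(red_marrow_activity(-0.1), ">= 0")
})

test_that("marrow activity is linear in blood concentration and in the RMBLR", {
  withr::with_seed(11, {
    for (i in 1:10) {
      conc <- stats::runif(1, 0, 1)
      r <- stats::runif(1, 0.1, 2)
      a <- stats::runif(1, 0.5, 3)
      expect_equal(red_marrow_activity(a * conc, phantom_constants(rmblr = r)),
                   a * red_marrow_activity(conc, phantom_constants(rmblr = r)))
      expect_equal(red_marrow_activity(conc, phantom_constants(rmblr = a * r)),
                   a * red_marrow_activity(conc, phantom_constants(rmblr = r)))
    }
  })
})

test_that("leg scaling multiplies by 1/(1 - 0.336) and round-trips", {
  expect_equal(scale_for_legs(66.4), 100)
  expect_equal(scale_for_legs(0), 0)
  expect_equal(scale_for_legs(1000), 1000 / 0.664)
  expect_equal(scale_for_legs(123.4) * (1 - 0.336), 123.4, tolerance = 1e-12)
})

test_that("the skeleton partition is 80/20 and conserves the total exactly", {
  expect_equal(unname(split_skeleton(100)), c(80, 20))
  expect_equal(unname(split_skeleton(0)), c(0, 0))
  parts <- split_skeleton(57.3)
  expect_equal(unname(parts), c(45.84, 11.46))
  expect_identical(sum(split_skeleton(123.456789)), 123.456789)
})

test_that("tumor activity/mass and kidney mass use the stated densities", {
  tm <- tumor_activity_and_mass(2, 1)
  expect_equal(tm$activity_MBq, 2)
  expect_equal(tm$mass_g, 1.92)
  tm2 <- tumor_activity_and_mass(0.5, 10.4)
  expect_equal(tm2$activity_MBq, 5.2)
  expect_equal(tm2$mass_g, 19.968)
  expect_error(tumor_activity_and_mass(1, 0), "> 0")
  expect_equal(kidney_mass(100), 106)
  expect_equal(kidney_mass(283.5), 300.51)
  expect_error(kidney_mass(0), "> 0")
})

test_that("the remainder curve subtracts pointwise and clamps at zero with a warning", {
  tb <- tibble::tibble(time_h = c(1, 2, 3), value = c(100, 100, 100))
  s1 <- tibble::tibble(time_h = c(1, 2, 3), value = c(60, 60, 120))
  s2 <- tibble::tibble(time_h = c(1, 2, 3), value = c(30, 30, 30))
  expect_warning(rem <- remainder_curve(tb, list(s1, s2)), "clamped")
  expect_equal(rem$value, c(10, 10, 0))
  expect_equal(rem$clamped, c(FALSE, FALSE, TRUE))
  bad <- tibble::tibble(time_h = c(1, 2), value = c(1, 1))
  expect_error(remainder_curve(tb, list(bad)), "time grid")
})

test_that("build_source_set errors name the missing region", {
  p <- noiseless_patient(3)
  broken <- p$bundle
  broken$curves <- dplyr::filter(broken$curves, region != "blood")
  expect_error(build_source_set(broken), "blood")
})

test_that("with zero lesion uptake the source set is identical whether tumors are re-included", {
  p <- generate_patient(patient_params(
    noise_sigma = 0, seed = 5,
    lesions = tibble::tibble(volume_mL = 10, conc_scale_per_MBq_mL = 0,
                             k_u = 0.8, k_b = 3e-4)))
  off <- build_source_set(p$bundle, tumors_in_bone = FALSE)
  on <- build_source_set(p$bundle, tumors_in_bone = TRUE)
  expect_equal(off$curves, on$curves)
})

test_that("re-including lesions adds exactly the summed lesion activity to the skeleton curve", {
  p <- noiseless_patient(5)
  off <- build_source_set(p$bundle, tumors_in_bone = FALSE)
  on <- build_source_set(p$bundle, tumors_in_bone = TRUE)
  les <- p$bundle$lesions
  grid <- imaging_schedule()
  tumor_total <- rep(0, length(grid))
  for (i in seq_len(nrow(les))) {
    cc <- dplyr::filter(p$bundle$curves, region == paste0("tumor:", les$id[i]))
    tumor_total <- tumor_total + cc$value * les$volume_mL[i]
  }
  sk_off <- dplyr::filter(off$curves, region == "skeleton")$value
  sk_on <- dplyr::filter(on$curves, region == "skeleton")$value
  expect_equal(sk_on - sk_off, tumor_total, tolerance = 1e-12)
})

test_that("the noiseless remainder matches the generator's soft-tissue pool within 10%", {
  err <- recovery_errors(noiseless_patient(2), "remainder")
  expect_lt(abs(err), 0.10)
})

test_that("source residence times cover the six MIRD regions and normalize correctly", {
  p <- noiseless_patient(4)
  ss <- build_source_set(p$bundle)
  rt <- source_residence_times(ss)
  expect_setequal(rt$region,
                  c("cortical_surface", "trabecular_surface", "red_marrow",
                    "kidneys", "bladder_content", "remainder"))
  expect_equal(rt$residence_h,
               rt$cumulated_MBq_h / p$truth$injected_activity_MBq)
  # cortical + trabecular reconstitute the leg-scaled skeleton integral
  skel <- sum(rt$cumulated_MBq_h[rt$region %in%
                                   c("cortical_surface", "trabecular_surface")])
  truth <- dplyr::filter(p$truth$cumulated, region == "skeleton")$cumulated_MBq_h
  expect_equal(skel, truth, tolerance = 1e-6)
})
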