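test_that("an identity-like S matrix returns the residence time as dose", {
  sm <- s_matrix(
    tibble::tibble(source = "kidneys", target = "kidneys",
                   s_value_Gy_per_MBq_h = 1),
    tibble::tibble(region = "kidneys", mass_g = 299))
  res <- organ_doses(tibble::tibble(region = "kidneys", residence_h = 0.5), sm)
  expect_equal(tidy(res)$dose_Gy_per_GBq, 500)
})

test_that("the toy cross-fire example gives 0.026 Gy/GBq with 76.9% from bone", {
  rt <- tibble::tibble(region = c("cortical_surface", "red_marrow"),
                       residence_h = c(10, 0.6))
  res <- organ_doses(rt, toy_smat())
  expect_equal(tidy(res)$dose_Gy_per_GBq, 0.026)
  fr <- dose_contributions(res, "red_marrow")
  expect_equal(fr$fraction[fr$source == "cortical_surface"], 20 / 26)
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-12)
})

test_that("patient mass scaling halves the self-term at double mass, cross terms fixed", {
  rt <- tibble::tibble(region = c("cortical_surface", "red_marrow"),
                       residence_h = c(10, 0.6))
  ref <- organ_doses(rt, toy_smat())
  scaled <- organ_doses(rt, toy_smat(), patient_masses = c(red_marrow = 3000))
  self <- function(r) dplyr::filter(r$contributions, source == "red_marrow")$dose_Gy_per_GBq
  cross <- function(r) dplyr::filter(r$contributions, source == "cortical_surface")$dose_Gy_per_GBq
  expect_equal(self(scaled), self(ref) / 2)
  expect_equal(cross(scaled), cross(ref))
  expect_error(organ_doses(rt, toy_smat(), patient_masses = c(red_marrow = -1)),
               "positive")
})

test_that("doses are linear in residence times and conserve contributions", {
  sm <- default_s_matrix()
  withr::with_seed(99, {
    regions <- sm$sources
    rt <- tibble::tibble(region = regions,
                         residence_h = stats::runif(length(regions), 0, 50))
    base <- organ_doses(rt, sm)
    # conservation: target dose equals the sum of its contributions exactly
    sums <- base$contributions |>
      dplyr::group_by(target) |>
      dplyr::summarise(s = sum(dose_Gy_per_GBq))
    expect_equal(
      sums$s[match(base$doses$target, sums$target)],
      base$doses$dose_Gy_per_GBq)
    for (i in 1:5) {
      c_ <- stats::runif(1, 0.1, 10)
      j <- sample(length(regions), 1)
      rt2 <- rt
      rt2$residence_h[j] <- rt$residence_h[j] * c_
      d2 <- organ_doses(rt2, sm)
      delta <- d2$doses$dose_Gy_per_GBq - base$doses$dose_Gy_per_GBq
      contrib_j <- dplyr::filter(base$contributions, source == regions[j])
      expected <- contrib_j$dose_Gy_per_GBq[match(base$doses$target,
                                                  contrib_j$target)]
      expected[is.na(expected)] <- 0
      expect_equal(delta, (c_ - 1) * expected, tolerance = 1e-12)
    }
  })
})

test_that("unknown source regions are rejected as configuration errors", {
  expect_error(
    organ_doses(tibble::tibble(region = "liver", residence_h = 1),
                default_s_matrix()),
    "liver")
})

test_that("zero total dose yields flagged zero fractions", {
  rt <- tibble::tibble(region = c("cortical_surface", "red_marrow"),
                       residence_h = c(0, 0))
  res <- organ_doses(rt, toy_smat())
  expect_warning(fr <- dose_contributions(res, "red_marrow"), "zero")
  expect_true(all(fr$fraction == 0))
  expect_true(all(fr$zero_dose))
})

test_that("the sphere model reproduces the unit construction and the 1/m law", {
  flat <- sphere_table(tibble::tibble(mass_g = c(1, 100), phi = c(1, 1)),
                       delta_Gy_g_per_MBq_h = 50)
  expect_equal(sphere_dose(2, 50, flat), 2000)
  expect_equal(sphere_dose(1, 20, flat), 2 * sphere_dose(1, 40, flat))
  expect_error(sphere_dose(1, 0, flat), "> 0")
})

test_that("the absorbed fraction interpolates log-log and clamps at the ends", {
  tab <- sphere_table(tibble::tibble(mass_g = c(1, 100), phi = c(0.9, 0.99)),
                      delta_Gy_g_per_MBq_h = 1)
  # log-log midpoint of (1, 0.9) and (100, 0.99)
  expect_equal(sphere_dose(1, 10, tab) * 10 / 1000, sqrt(0.9 * 0.99),
               tolerance = 1e-9)
  expect_equal(sphere_dose(1, 0.01, tab) * 0.01 / 1000, 0.9)
  expect_equal(sphere_dose(1, 1e5, tab) * 1e5 / 1000, 0.99)
})

test_that("sphere tables reject non-monotone absorbed fractions", {
  expect_error(
    sphere_table(tibble::tibble(mass_g = c(1, 10), phi = c(0.99, 0.9))),
    "non-decreasing")
})

test_that("effective dose is the tissue-weighted sum", {
  expect_equal(effective_dose(c(A = 0.14), c(A = 1)), 0.14)
  expect_equal(effective_dose(c(A = 0, B = 0), c(A = 0.5, B = 0.5)), 0)
  expect_equal(effective_dose(c(A = 1, B = 2), c(A = 0.12, B = 0.05)), 0.22)
  expect_error(effective_dose(c(A = 1), c(A = -0.1)), ">= 0")
  expect_error(effective_dose(c(A = 1, B = 1), c(A = 0.9, B = 0.2)), "<= 1")
})

test_that("swapping the S matrix rescales doses linearly and nothing else", {
  rt <- tibble::tibble(region = c("cortical_surface", "red_marrow"),
                       residence_h = c(10, 0.6))
  sm <- toy_smat()
  sm2 <- sm
  sm2$values$s_value_Gy_per_MBq_h <- sm$values$s_value_Gy_per_MBq_h * 3
  expect_equal(tidy(organ_doses(rt, sm2))$dose_Gy_per_GBq,
               3 * tidy(organ_doses(rt, sm))$dose_Gy_per_GBq)
})

test_that("the packaged illustrative matrix is labelled synthetic and self-consistent", {
  sm <- default_s_matrix()
  expect_match(sm$provenance, "illustrative|synthetic")
  expect_true(all(sm$values$s_value_Gy_per_MBq_h >= 0))
  both <- intersect(sm$sources, sm$targets)
  for (r in both) {
    expect_gt(sm$values$s_value_Gy_per_MBq_h[
      sm$values$source == r & sm$values$target == r], 0)
  }
})
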