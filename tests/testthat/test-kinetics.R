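test_that("a noiseless single exponential is recovered exactly", {
  t <- imaging_schedule()
  d <- tibble::tibble(time_h = t, value = 100 * exp(-0.1 * t))
  fit <- fit_exponential(d, max_terms = 2)
  expect_equal(nrow(fit$terms), 1L)
  expect_equal(fit$terms$amplitude, 100, tolerance = 1e-6)
  expect_equal(fit$terms$rate_per_h, 0.1, tolerance = 1e-6)
  expect_equal(integrate_model(fit), 1000, tolerance = 1e-6)
})

test_that("a noiseless biexponential at the imaging schedule is recovered within 1%", {
  t <- imaging_schedule()
  d <- tibble::tibble(time_h = t,
                      value = 80 * (exp(-0.01 * t) - exp(-0.5 * t)))
  fit <- fit_exponential(d, max_terms = 2)
  expect_equal(nrow(fit$terms), 2L)
  expect_equal(sort(fit$terms$rate_per_h), c(0.01, 0.5), tolerance = 0.01)
  expect_equal(sort(fit$terms$amplitude), c(-80, 80), tolerance = 0.01)
  # closed-form integral of the generating model as the oracle
  expect_equal(integrate_model(fit), 80 / 0.01 - 80 / 0.5, tolerance = 0.01)
})

test_that("the all-zero curve yields the flagged zero model and integrates to 0", {
  d <- tibble::tibble(time_h = imaging_schedule(), value = rep(0, 5))
  expect_warning(fit <- fit_exponential(d), "zero")
  expect_true(fit$flags$zero_curve)
  expect_equal(nrow(fit$terms), 0L)
  expect_equal(integrate_model(fit), 0)
})

test_that("fitting fails informatively on fewer than 2 samples", {
  expect_error(fit_exponential(tibble::tibble(time_h = 1, value = 5)),
               "at least 2")
})

test_that("the terminal-rate floor is enforced for measured curves", {
  lam <- lu177_constants()$lambda_phys
  t <- imaging_schedule()
  # slower-than-physical decay cannot be represented; fitted terminal rate
  # must sit at (or above) the floor
  d <- tibble::tibble(time_h = t, value = 100 * exp(-lam * 0.5 * t))
  fit <- fit_exponential(d)
  expect_gte(min(fit$terms$rate_per_h), lam * (1 - 1e-3) * (1 - 1e-9))
})

test_that("closed-form integration matches the hand value and linearity", {
  m <- list(terms = tibble::tibble(amplitude = c(80, -80),
                                   rate_per_h = c(0.01, 0.5)))
  expect_equal(integrate_model(m), 7840)
  expect_error(
    integrate_model(list(terms = tibble::tibble(amplitude = 1,
                                                rate_per_h = 0))),
    "positive")
})

test_that("closed-form integral agrees with adaptive quadrature on random models", {
  withr::with_seed(421, {
    for (i in 1:25) {
      k <- sample(1:3, 1)
      rates <- sort(exp(stats::runif(k, log(0.005), log(3))), decreasing = TRUE)
      amps <- stats::runif(k, 1, 100)
      if (k > 1 && stats::runif(1) < 0.5) amps[1] <- -amps[1] * 0.8  # uptake term
      m <- list(terms = tibble::tibble(amplitude = amps, rate_per_h = rates))
      f <- function(tt) drop(exp(-outer(tt, rates)) %*% amps)
      quad <- stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value
      expect_equal(integrate_model(m), quad, tolerance = 1e-3)
    }
  })
})

test_that("the hybrid policy reproduces the trapezoid-plus-tail arithmetic", {
  cst <- lu177_constants()
  d <- tibble::tibble(time_h = c(1.5, 170), value = c(10, 10))
  out <- cumulated_activity(d, policy = "hybrid", constants = cst)
  expected <- 0.5 * 1.5 * 10 +            # linear rise from (0, 0)
    0.5 * (10 + 10) * (170 - 1.5) +       # trapezoid over the samples
    10 / cst$lambda_phys                  # physical-decay tail
  expect_equal(out$cumulated, expected)
  expect_equal(out$method, "hybrid")
})

test_that("cumulated activity under the fit policy equals A0/lambda on exact data", {
  t <- imaging_schedule()
  d <- tibble::tibble(region = "skeleton", time_h = t,
                      value = 50 * exp(-0.05 * t))
  out <- cumulated_activity(d, policy = "fit")
  expect_equal(out$cumulated, 50 / 0.05, tolerance = 1e-6)
  zero <- cumulated_activity(tibble::tibble(time_h = t, value = rep(0, 5)))
  expect_equal(zero$cumulated, 0)
})

test_that("scaling all samples by c > 0 scales the cumulated activity by exactly c", {
  t <- blood_schedule()
  y <- 2 * exp(-0.9 * t) + 0.05 * exp(-0.08 * t)
  base <- cumulated_activity(tibble::tibble(time_h = t, value = y))
  for (c_ in c(0.25, 7, 1e3)) {
    scaled <- cumulated_activity(tibble::tibble(time_h = t, value = c_ * y))
    expect_equal(scaled$cumulated, c_ * base$cumulated, tolerance = 1e-9)
  }
})

test_that("fits are deterministic: identical inputs give identical models", {
  withr::with_seed(7, {
    t <- imaging_schedule()
    y <- 30 * (exp(-0.02 * t) - exp(-0.9 * t)) * exp(stats::rnorm(5, 0, 0.05))
  })
  d <- tibble::tibble(time_h = t, value = y)
  f1 <- fit_exponential(d)
  f2 <- fit_exponential(d)
  expect_identical(f1$terms, f2$terms)
  expect_identical(f1$rss, f2$rss)
})

test_that("normalized cumulated activity is the plain ratio with guarded input", {
  expect_equal(normalized_cumulated_activity(5780, 5780), 1)
  expect_equal(normalized_cumulated_activity(0, 100), 0)
  expect_equal(normalized_cumulated_activity(7840, 5780), 7840 / 5780)
  expect_error(normalized_cumulated_activity(10, 0), "positive")
  expect_error(normalized_cumulated_activity(-1, 10), ">= 0")
})

test_that("tidy and glance expose the fitted terms and summary", {
  t <- imaging_schedule()
  fit <- fit_exponential(tibble::tibble(time_h = t, value = 10 * exp(-0.1 * t)))
  td <- tidy(fit)
  expect_named(td, c("term", "amplitude", "rate_per_h"))
  gl <- glance(fit)
  expect_equal(gl$cumulated, integrate_model(fit))
  expect_false(gl$fallback)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
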