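#' Study sampling schedules
#'
#' Nominal post-injection sampling times: five SPECT imaging time points
#' (1.5, 6, 24, 48, 170 h) for organs, and eight venous blood samples
#' (5, 15, 30 min, 1.5, 6, 24, 48, 170 h) for the blood-based red-marrow
#' model.
#'
#' @return Numeric vector of times in hours post-injection.
#' @examples
#' imaging_schedule()
#' blood_schedule()
#' @export
imaging_schedule <- function() c(1.5, 6, 24, 48, 170)

#' @rdname imaging_schedule
#' @export
blood_schedule <- function() c(5 / 60, 15 / 60, 30 / 60, 1.5, 6, 24, 48, 170)

#' Build a time-activity curve table
#'
#' A time-activity curve (TAC) is represented as a plain tibble with one row
#' per sample: `region`, `time_h`, `value`, `mode`. `mode` is `"activity"`
#' (MBq) for organ curves or `"concentration"` (MBq/mL) for blood and lesion
#' curves, and must be constant within a region. Values are measured
#' activities, i.e. *not* corrected for physical decay.
#'
#' @param region Region identifier (e.g. `"skeleton"`, `"blood"`,
#'   `"tumor:1"`).
#' @param time_h Sampling times, hours post-injection, strictly increasing,
#'   all `>= 0`.
#' @param value Activity (MBq) or concentration (MBq/mL), all `>= 0`.
#' @param mode `"activity"` or `"concentration"`.
#'
#' @return A tibble with columns `region`, `time_h`, `value`, `mode`.
#' @examples
#' tac_curve("skeleton", imaging_schedule(), c(2500, 2450, 2200, 2000, 1100))
#' @export
tac_curve <- function(region, time_h, value, mode = c("activity", "concentration")) {
  mode <- match.arg(mode)
  out <- tibble::tibble(region = region, time_h = as.numeric(time_h),
                        value = as.numeric(value), mode = mode)
  validate_tac(out)
  out
}

validate_tac <- function(data, min_samples = 1) {
  need <- c("time_h", "value")
  if (!all(need %in% names(data))) {
    abort("A time-activity curve needs `time_h` and `value` columns.")
  }
  if (nrow(data) < min_samples) {
    abort(sprintf("A time-activity curve needs at least %d samples, got %d.",
                  min_samples, nrow(data)))
  }
  if (any(!is.finite(data$time_h)) || any(data$time_h < 0)) {
    abort("Sampling times must be finite and >= 0 hours.")
  }
  if (is.unsorted(data$time_h, strictly = TRUE)) {
    abort("Sampling times must be strictly increasing within a curve.")
  }
  if (any(!is.finite(data$value)) || any(data$value < 0)) {
    abort("Activity values must be finite and >= 0.")
  }
  if ("mode" %in% names(data) && length(unique(data$mode)) > 1) {
    abort("`mode` must be constant within one curve.")
  }
  invisible(data)
}

# ---- variable-projection machinery -----------------------------------------

# Weighted linear solve of amplitudes for fixed rates; returns Inf rss on
# rank deficiency or numeric trouble. `sw` is sqrt(weights), `ysw` the
# pre-weighted response (hot path: called thousands of times per fit).
varpro_solve <- function(rates, t, sw, ysw) {
  k <- length(rates)
  X <- exp(-outer(t, rates)) * sw
  fit <- .lm.fit(X, ysw)
  if (fit$rank < k) return(list(rss = Inf, amps = rep(NA_real_, k)))
  amps <- numeric(k)
  amps[fit$pivot] <- fit$coefficients
  if (any(!is.finite(amps))) return(list(rss = Inf, amps = amps))
  list(rss = sum(fit$residuals^2), amps = amps)
}

# Constraint check: all rates above the floor, adjacent rates separated by
# at least a factor 1.3 (a near-duplicate pair is unidentifiable and can
# integrate to anything through cancelling amplitudes), amplitudes bounded
# by a generous multiple of the data scale (blocks the same cancellation
# pathology at larger separations), at most one negative amplitude (a fast
# uptake term), positive slowest-term amplitude, and non-negativity of the
# model on a grid covering [0, 2 * t_max].
exp_model_feasible <- function(amps, rates, t_max, lambda_min, amp_cap = Inf) {
  if (any(!is.finite(amps)) || any(!is.finite(rates))) return(FALSE)
  if (any(rates < lambda_min * (1 - 1e-9))) return(FALSE)
  if (length(rates) > 1) {
    r <- sort(rates)
    if (any(r[-1] / r[-length(r)] < 1.3)) return(FALSE)
  }
  if (max(abs(amps)) > amp_cap) return(FALSE)
  neg <- amps < 0
  if (sum(neg) > 1) return(FALSE)
  if (amps[which.min(rates)] <= 0) return(FALSE)
  if (!any(neg)) return(TRUE)  # all-positive models are non-negative everywhere
  tt <- seq(0, 2 * t_max, length.out = 129)
  vals <- drop(exp(-outer(tt, rates)) %*% amps)
  all(vals >= -1e-9 * max(abs(amps)))
}

# Deterministic multi-start fit of a k-term model. Rates are parameterized
# as lambda_min + exp(theta) so the terminal-rate floor is built in.
fit_k_terms <- function(t, y, w, k, lambda_min, lambda_max) {
  t_max <- max(t)
  sw <- sqrt(w)
  ysw <- y * sw
  # A measured curve first sampled at 1.5 h (organs) or 5 min (blood)
  # cannot plausibly start far above its observed maximum; capping
  # amplitudes at 5x the data maximum blocks un-identifiable fast terms
  # that spike in the unobserved 0 -> t1 window (legitimate shapes in this
  # domain stay below ~3.5x).
  amp_cap <- 5 * max(abs(y))
  penalty <- sum(ysw^2) + 1
  # the constrained objective: infeasible models (cancelling amplitude
  # blow-ups, negative excursions) are pushed above any feasible RSS so the
  # simplex refinement stays in the physically meaningful region.
  obj <- function(theta) {
    rates <- lambda_min + exp(theta)
    if (any(rates > 1e4)) return(1e300)
    sol <- varpro_solve(rates, t, sw, ysw)
    if (!is.finite(sol$rss)) return(1e300)
    if (!exp_model_feasible(sol$amps, rates, t_max, lambda_min, amp_cap)) {
      return(sol$rss + penalty)
    }
    sol$rss
  }
  finish <- function(theta) {
    rates <- lambda_min + exp(theta)
    sol <- varpro_solve(rates, t, sw, ysw)
    list(amps = sol$amps, rates = rates, rss = sol$rss)
  }

  grid <- exp(seq(log(max(lambda_min * 1.01, 1e-6)), log(lambda_max),
                  length.out = if (k == 1) 40 else 24))
  theta_of <- function(r) log(pmax(r - lambda_min, 1e-10))

  if (k == 1) {
    rss_grid <- vapply(grid, function(r) obj(theta_of(r)), numeric(1))
    i <- which.min(rss_grid)
    lo <- theta_of(grid[max(1, i - 1)])
    hi <- theta_of(grid[min(length(grid), i + 1)])
    if (lo >= hi) { lo <- lo - 1; hi <- hi + 1 }
    opt <- optimize(obj, lower = lo, upper = hi, tol = 1e-12)
    # polish with a short Nelder-Mead pass in case the bracket was off
    pol <- optim(opt$minimum, obj, method = "Brent",
                 lower = opt$minimum - 2, upper = opt$minimum + 2)
    best <- finish(pol$par)
    cand <- list(best)
  } else {
    starts <- list()
    if (k == 2) {
      idx <- utils::combn(seq_along(grid), 2)
      starts <- lapply(seq_len(ncol(idx)), function(j) grid[idx[, j]])
      # peel-off starts: pair the best single rate with each faster rate
      r1_grid <- vapply(grid, function(r) obj(theta_of(r)), numeric(1))
      r1 <- grid[which.min(r1_grid)]
      fast <- grid[grid > r1 * 3]
      starts <- c(starts, lapply(fast, function(rf) c(r1, rf)))
    } else {
      sub <- grid[seq(1, length(grid), by = 2)]
      idx <- utils::combn(seq_along(sub), 3)
      starts <- lapply(seq_len(ncol(idx)), function(j) sub[idx[, j]])
    }
    rss_start <- vapply(starts, function(r) obj(theta_of(r)), numeric(1))
    keep <- order(rss_start)[seq_len(min(6, length(starts)))]
    cand <- lapply(keep, function(j) {
      th <- theta_of(starts[[j]])
      o <- optim(th, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 1500))
      # one restart from the optimum; Nelder-Mead benefits from it
      o <- optim(o$par, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 1500))
      finish(o$par)
    })
  }

  feas <- purrr::keep(cand, ~ is.finite(.x$rss) &&
                        exp_model_feasible(.x$amps, .x$rates, t_max,
                                           lambda_min, amp_cap))
  if (length(feas) == 0) return(NULL)
  feas[[which.min(vapply(feas, `[[`, numeric(1), "rss"))]]
}

# Small-sample-corrected information criterion. The usual AICc correction
# 2p(p+1)/(n-p-1) diverges when n = p + 1 (a 2-term model on the 5-point
# imaging schedule); the denominator is floored at 1 so the penalty stays
# finite and the richer model is only chosen on a decisive RSS improvement.
# The RSS is floored at the double-precision noise level of the data so
# that among models that all fit to machine precision the smallest wins.
aicc_score <- function(n, p, rss, y_scale) {
  rss <- max(rss, (1e-9 * y_scale)^2 * n)
  n * log(rss / n) + 2 * p + 2 * p * (p + 1) / max(n - p - 1, 1)
}

#' Fit a constrained sum of exponentials to a time-activity curve
#'
#' Fits models \eqn{A(t) = \sum_i A_i e^{-\lambda_i t}} with 1 to
#' `max_terms` terms by weighted least squares and selects among them with a
#' small-sample-corrected information criterion. Rates are found by a
#' deterministic log-spaced multi-start search refined by Nelder-Mead;
#' amplitudes are profiled out linearly (variable projection), so the fit is
#' bit-reproducible: there is no random state.
#'
#' Constraints reflect the physics of a measured (not decay-corrected)
#' curve: every rate must satisfy \eqn{\lambda_i \ge \lambda_{phys}(1 -
#' 10^{-3})} (biological clearance cannot be negative), at most one
#' amplitude may be negative (a fast uptake term), and the model must be
#' non-negative on a grid covering twice the sampled interval. Three terms
#' are only attempted with at least 7 samples.
#'
#' @param data Tibble with `time_h` and `value` columns, one region.
#' @param max_terms Maximum number of exponential terms (1--3).
#' @param constants [lu177_constants()]; supplies the terminal-rate floor.
#' @param weighting Residual weighting: `"relative"` (default; weights
#'   1/value^2, the maximum-likelihood choice under multiplicative
#'   lognormal measurement error, which keeps the late, small samples that
#'   dominate the integral's tail statistically visible), `"none"`
#'   (unweighted), or `"inverse"` (weights 1/value). Zero-value samples get
#'   the smallest positive sample's weight.
#' @param decay_corrected Set `TRUE` if the curve was decay-corrected, which
#'   drops the terminal-rate floor to (effectively) zero.
#'
#' @return An object of class `exp_fit`: a list with `terms` (tibble of
#'   `amplitude` and `rate_per_h`), `n`, `rss`, `criterion`, `flags`
#'   (`zero_curve`, `fallback`), `constraint_record`, and the data used.
#'   [tidy()] and [glance()] methods are provided, and
#'   [integrate_model()] returns the closed-form time integral.
#' @examples
#' d <- tibble::tibble(time_h = imaging_schedule(),
#'                     value = 100 * exp(-0.1 * imaging_schedule()))
#' fit <- fit_exponential(d)
#' tidy(fit)
#' integrate_model(fit) # ~ 100 / 0.1
#' @export
fit_exponential <- function(data, max_terms = 2,
                            constants = lu177_constants(),
                            weighting = c("relative", "none", "inverse"),
                            decay_corrected = FALSE) {
  weighting <- match.arg(weighting)
  validate_tac(data, min_samples = 2)
  if (!is.numeric(max_terms) || max_terms < 1 || max_terms > 3) {
    abort("`max_terms` must be 1, 2 or 3.")
  }
  t <- data$time_h
  y <- data$value
  n <- length(y)

  new_fit <- function(terms, rss, crit, zero = FALSE, fallback = FALSE,
                      record = character()) {
    structure(
      list(terms = terms, n = n, rss = rss, criterion = crit,
           weighting = weighting,
           flags = list(zero_curve = zero, fallback = fallback),
           constraint_record = record,
           data = tibble::tibble(time_h = t, value = y)),
      class = "exp_fit"
    )
  }
  empty_terms <- tibble::tibble(amplitude = numeric(), rate_per_h = numeric())

  if (all(y == 0)) {
    warn("All samples are zero: returning the zero model.")
    return(new_fit(empty_terms, rss = 0, crit = NA_real_, zero = TRUE))
  }

  # for value-based weights, samples below 1e-4 of the curve maximum are
  # treated as sitting at the detection floor: unbounded weights on
  # near-zero tail values would otherwise destroy the conditioning of the
  # weighted solve (and no real gamma counter resolves 4 decades below peak)
  v_floor <- pmax(y, 1e-4 * max(y))
  w <- switch(weighting,
              none = rep(1, n),
              inverse = 1 / v_floor,
              relative = 1 / v_floor^2)
  lambda_min <- if (decay_corrected) 1e-8 else constants$lambda_phys * (1 - 1e-3)
  lambda_max <- max(8 / min(t[t > 0]), 20 * lambda_min)

  ks <- seq_len(max_terms)
  ks <- ks[2 * ks <= n]          # free parameters cannot exceed samples
  ks <- ks[ks < 3 | n >= 7]      # 3 terms need at least 7 samples
  fits <- purrr::compact(purrr::map(
    ks, function(k) {
      f <- fit_k_terms(t, y, w, k, lambda_min, lambda_max)
      if (is.null(f)) return(NULL)
      list(k = k, f = f,
           crit = aicc_score(n, 2 * k, f$rss, max(abs(y) * sqrt(w))))
    }
  ))
  if (length(fits) == 0) {
    warn("No feasible exponential model found: fallback flag set; use the hybrid integration policy.")
    return(new_fit(empty_terms, rss = NA_real_, crit = NA_real_, fallback = TRUE))
  }
  crits <- vapply(fits, `[[`, numeric(1), "crit")
  best <- fits[[which.min(crits)]]
  ord <- order(best$f$rates)
  record <- c(
    sprintf("terminal_rate_floor=%.6g", lambda_min),
    if (any(best$f$amps < 0)) "uptake_term_present",
    if (any(abs(best$f$rates - lambda_min) / lambda_min < 1e-6)) "rate_at_floor"
  )
  new_fit(
    tibble::tibble(amplitude = best$f$amps[ord], rate_per_h = best$f$rates[ord]),
    rss = best$f$rss, crit = best$crit, record = record
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit: %d term(s), n = %d, rss = %.4g>\n",
              nrow(x$terms), x$n, x$rss))
  if (nrow(x$terms)) print(x$terms)
  if (x$flags$zero_curve) cat("flag: zero curve\n")
  if (x$flags$fallback) cat("flag: fallback (no feasible model)\n")
  invisible(x)
}

#' @export
predict.exp_fit <- function(object, time_h = object$data$time_h, ...) {
  if (nrow(object$terms) == 0) return(rep(0, length(time_h)))
  drop(exp(-outer(time_h, object$terms$rate_per_h)) %*% object$terms$amplitude)
}

#' @describeIn fit_exponential Tidy the fitted terms: one row per
#'   exponential term with `amplitude` and `rate_per_h`.
#' @param x An `exp_fit` object.
#' @param ... Unused.
#' @method tidy exp_fit
#' @export
tidy.exp_fit <- function(x, ...) {
  dplyr::mutate(x$terms, term = dplyr::row_number(), .before = 1)
}

#' @describeIn fit_exponential One-row model summary: number of terms,
#'   residual sum of squares, information criterion, flags, and the
#'   closed-form cumulated activity.
#' @method glance exp_fit
#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(
    n_terms = nrow(x$terms), n = x$n, rss = x$rss, criterion = x$criterion,
    zero_curve = x$flags$zero_curve, fallback = x$flags$fallback,
    cumulated = if (x$flags$fallback) NA_real_ else integrate_model(x)
  )
}

#' Closed-form time integral of a fitted exponential model
#'
#' For \eqn{A(t) = \sum_i A_i e^{-\lambda_i t}} the integral from 0 to
#' infinity is \eqn{\sum_i A_i / \lambda_i}; applied to a measured activity
#' curve this is the cumulated activity (MBq h). The zero model integrates
#' to 0.
#'
#' @param model An `exp_fit` object (or any list with a `terms` tibble).
#' @return Cumulated activity in MBq h (or MBq h/mL for concentration
#'   curves).
#' @examples
#' m <- list(terms = tibble::tibble(amplitude = 100, rate_per_h = 0.1))
#' integrate_model(m) # 1000
#' @export
integrate_model <- function(model) {
  terms <- model$terms
  if (is.null(terms)) abort("`model` must have a `terms` component.")
  if (nrow(terms) == 0) return(0)
  if (any(terms$rate_per_h <= 0)) {
    abort("All rates must be positive to integrate to infinity.")
  }
  sum(terms$amplitude / terms$rate_per_h)
}

# Trapezoid over the samples, linear rise from (0, 0) to the first sample,
# physical-decay tail from the last sample.
hybrid_cumulated <- function(t, y, lambda_phys) {
  rise <- 0.5 * t[1] * y[1]
  n <- length(t)
  trap <- if (n > 1) sum(0.5 * diff(t) * (head(y, -1) + tail(y, -1))) else 0
  rise + trap + y[n] / lambda_phys
}

#' Cumulated activity of one or more time-activity curves
#'
#' Dispatch wrapper around fitting and integration. Policy `"fit"` fits a
#' constrained sum of exponentials ([fit_exponential()]) and integrates it
#' in closed form; policy `"hybrid"` uses a linear rise from (0, 0) to the
#' first sample, the trapezoid rule over the sampled interval, and a
#' physical-decay tail \eqn{A_{last}/\lambda_{phys}} from the last sample.
#' If the fit sets its fallback flag under policy `"fit"`, the hybrid rule
#' is used for that curve and recorded in the `method` column.
#'
#' @param data Tibble with `time_h` and `value`; an optional `region`
#'   column groups multiple curves.
#' @param policy `"fit"` or `"hybrid"`.
#' @inheritParams fit_exponential
#'
#' @return A tibble with one row per region: `region`, `cumulated`
#'   (MBq h, or MBq h/mL for concentration curves), `method`, `n_terms`.
#' @examples
#' d <- tibble::tibble(time_h = c(1.5, 170), value = c(10, 10))
#' cumulated_activity(d, policy = "hybrid")
#' @export
cumulated_activity <- function(data, policy = c("fit", "hybrid"),
                               max_terms = 2, constants = lu177_constants(),
                               weighting = c("relative", "none", "inverse"),
                               decay_corrected = FALSE) {
  policy <- match.arg(policy)
  weighting <- match.arg(weighting)
  if (!"region" %in% names(data)) data$region <- "curve"
  one <- function(d, region) {
    validate_tac(d, min_samples = if (policy == "fit") 2 else 1)
    if (policy == "hybrid" || all(d$value == 0)) {
      if (all(d$value == 0)) {
        return(tibble::tibble(region = region, cumulated = 0,
                              method = "zero", n_terms = 0L))
      }
      return(tibble::tibble(
        region = region,
        cumulated = hybrid_cumulated(d$time_h, d$value, constants$lambda_phys),
        method = "hybrid", n_terms = NA_integer_))
    }
    fit <- fit_exponential(d, max_terms = max_terms, constants = constants,
                           weighting = weighting,
                           decay_corrected = decay_corrected)
    if (fit$flags$fallback) {
      tibble::tibble(
        region = region,
        cumulated = hybrid_cumulated(d$time_h, d$value, constants$lambda_phys),
        method = "hybrid_fallback", n_terms = NA_integer_)
    } else {
      tibble::tibble(region = region, cumulated = integrate_model(fit),
                     method = "fit", n_terms = nrow(fit$terms))
    }
  }
  data |>
    dplyr::group_by(.data$region) |>
    dplyr::group_map(~ one(.x, .y$region)) |>
    purrr::list_rbind()
}

#' Normalized cumulated activity (residence time)
#'
#' Divides cumulated activity by the injected activity, giving the
#' time-integrated activity coefficient in hours -- the input of the
#' MIRD dose engine.
#'
#' @param cumulated Cumulated activity, MBq h (vectorized).
#' @param injected Injected activity, MBq; must be positive.
#' @return Residence time(s), hours.
#' @examples
#' normalized_cumulated_activity(5780, 5780) # 1 h
#' @export
normalized_cumulated_activity <- function(cumulated, injected) {
  if (!is.numeric(injected) || length(injected) != 1 ||
      !is.finite(injected) || injected <= 0) {
    abort("`injected` must be a single positive activity in MBq.")
  }
  if (any(cumulated < 0)) abort("`cumulated` must be >= 0.")
  cumulated / injected
}
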