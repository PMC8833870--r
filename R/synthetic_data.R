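# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Kinetic parameters for a synthetic patient
#'
#' Defines the generating model of the synthetic-patient bundle. Each organ
#' compartment follows an uptake-washout curve
#' \eqn{A(t) = A_{inj} f (1 - e^{-k_u t}) e^{-(\lambda_{phys} + k_b) t}}
#' (measured activity: physical decay included, biological loss \eqn{k_b});
#' blood concentration is biexponential times physical decay; a soft-tissue
#' remainder pool starts at the injected activity and drains with fast and
#' slow components; lesion concentration curves share the uptake-washout
#' form. The defaults emulate a bone-avid Lu-177 bisphosphonate in a
#' heavily metastasized skeleton: skeletal uptake peaking near
#' 9.6e-3 %IA/g (5500 g bone) around 2 h with slow biological loss, blood
#' clearing fast (marrow ~1.4e-3 %IA/g at 1.5 h, ~1e-4 at 24 h), lesions
#' peaking near 2.1e-2 %IA/g around 6 h with negligible washout, low renal
#' uptake (a `high_kidney = TRUE` preset mimics the occasional patient with
#' elevated kidney retention), and an injected activity drawn from
#' N(5780, 329) MBq truncated positive.
#'
#' @param injected_activity_MBq Injected activity; `NA` (default) draws
#'   from the truncated normal above using `seed`.
#' @param blood List `b1`, `k1`, `b2`, `k2`: concentration per injected MBq
#'   (1/mL) and biological rates (1/h) of the fast and slow blood phases.
#' @param skeleton,kidneys,bladder Lists `f` (uptake fraction of injected
#'   activity), `k_u` (uptake rate, 1/h), `k_b` (biological loss, 1/h).
#' @param remainder List `p` (pool fractions, summing to 1 with organ
#'   fractions accounted inside the pool drain) and `q` (drain rates, 1/h).
#' @param lesions Tibble with `volume_mL`, `conc_scale_per_MBq_mL` (peak
#'   concentration scale per injected MBq, 1/mL), `k_u`, `k_b`.
#' @param kidney_volume_mL CT kidney volume.
#' @param noise_sigma Lognormal noise sigma per sample (mean-corrected so
#'   noisy curves are unbiased); 0 disables noise.
#' @param high_kidney Use the elevated-kidney-uptake preset.
#' @param jitter_schedule Sample at times jittered within the protocol
#'   windows instead of the nominal schedule (off by default, for
#'   reproducibility).
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   same parameters and seed.
#' @param constants [lu177_constants()].
#' @return A list of class `patient_params`.
#' @export
patient_params <- function(injected_activity_MBq = NA_real_,
                           blood = list(b1 = 1.60e-4, k1 = 2.0,
                                        b2 = 7.8e-6, k2 = 0.08),
                           skeleton = list(f = 0.535, k_u = 3.1, k_b = 0.00166),
                           kidneys = list(f = 0.02, k_u = 3.1, k_b = 0.15),
                           bladder = list(f = 0.10, k_u = 1.5, k_b = 0.30),
                           remainder = list(p = c(0.85, 0.15),
                                            q = c(1.2, 0.04)),
                           lesions = tibble::tibble(
                             volume_mL = c(20, 12, 8, 30, 15),
                             conc_scale_per_MBq_mL = c(4.18e-4, 5.0e-4,
                                                       3.3e-4, 2.5e-4, 4.6e-4),
                             k_u = c(0.8, 0.8, 1.2, 0.6, 0.9),
                             k_b = c(3e-4, 3e-4, 1e-3, 3e-4, 5e-4)),
                           kidney_volume_mL = 300,
                           noise_sigma = 0.05,
                           high_kidney = FALSE,
                           jitter_schedule = FALSE,
                           seed = 1L,
                           constants = lu177_constants()) {
  if (high_kidney) kidneys <- list(f = 0.12, k_u = 2.0, k_b = 0.01)
  fr <- c(skeleton$f, kidneys$f, bladder$f)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    abort("Organ uptake fractions must lie in [0, 1] and sum to at most 1.")
  }
  rates <- c(blood$k1, blood$k2, skeleton$k_u, kidneys$k_u, bladder$k_u,
             remainder$q, lesions$k_u)
  if (any(rates <= 0)) abort("All kinetic rates must be > 0.")
  if (any(c(skeleton$k_b, kidneys$k_b, bladder$k_b, lesions$k_b) < 0)) {
    abort("Biological loss rates must be >= 0.")
  }
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  if (abs(sum(remainder$p) - 1) > 1e-9) {
    abort("Remainder pool fractions must sum to 1 (whole injection starts in soft tissue).")
  }
  structure(
    list(injected_activity_MBq = injected_activity_MBq, blood = blood,
         skeleton = skeleton, kidneys = kidneys, bladder = bladder,
         remainder = remainder, lesions = tibble::as_tibble(lesions),
         kidney_volume_mL = kidney_volume_mL, noise_sigma = noise_sigma,
         jitter_schedule = jitter_schedule, seed = as.integer(seed),
         constants = constants),
    class = "patient_params"
  )
}

# uptake-washout compartment: fraction of injected activity over time and
# its exact 0-to-infinity integral (per MBq injected).
uw_frac <- function(t, f, k_u, k_b, lambda) {
  f * (1 - exp(-k_u * t)) * exp(-(lambda + k_b) * t)
}
uw_integral <- function(f, k_u, k_b, lambda) {
  L <- lambda + k_b
  f * (1 / L - 1 / (L + k_u))
}

#' Generate a synthetic patient bundle with ground truth
#'
#' Evaluates the generating model of [patient_params()] at the protocol
#' schedules (five imaging time points for organs and lesions, eight blood
#' samples), applies mean-corrected multiplicative lognormal noise, and
#' emulates the torso-limited field of view by scaling the emitted skeleton
#' and total-body curves by (1 - leg bone fraction) -- the pipeline undoes
#' this with [scale_for_legs()]. The ground truth holds the exact
#' closed-form cumulated activities of every region (full, leg-complete
#' values), the oracle for recovery testing.
#'
#' @param params [patient_params()].
#' @param phantom [phantom_constants()] (supplies the leg bone fraction and
#'   the blood-to-marrow conversion used for the marrow truth).
#' @return A list with elements `bundle` (see [build_source_set()] for the
#'   layout) and `truth` (list with `cumulated` tibble of exact MBq h per
#'   region, `blood_conc_integral_MBq_h_per_mL`, and the parameters).
#' @examples
#' p <- generate_patient(patient_params(noise_sigma = 0, seed = 7))
#' p$truth$cumulated
#' @export
generate_patient <- function(params = patient_params(),
                             phantom = phantom_constants()) {
  stopifnot(inherits(params, "patient_params"))
  lambda <- params$constants$lambda_phys

  with_local_seed(params$seed, {
    a_inj <- params$injected_activity_MBq
    if (is.na(a_inj)) {
      repeat {
        a_inj <- rnorm(1, 5780, 329)
        if (a_inj > 0) break
      }
    }

    t_img <- imaging_schedule()
    t_blood <- blood_schedule()
    if (params$jitter_schedule) {
      win_img <- c(0.5, 1, 3, 3, 24)
      t_img <- sort(t_img + stats::runif(5, -win_img, win_img))
      win_bl <- c(2, 5, 5, 30, 60, 180, 180, 24 * 60) / 60
      t_blood <- sort(t_blood + stats::runif(8, -win_bl, win_bl))
    }

    sk <- params$skeleton; ki <- params$kidneys; bl <- params$bladder
    re <- params$remainder; bd <- params$blood

    skeleton <- a_inj * uw_frac(t_img, sk$f, sk$k_u, sk$k_b, lambda)
    kidneys <- a_inj * uw_frac(t_img, ki$f, ki$k_u, ki$k_b, lambda)
    bladder <- a_inj * uw_frac(t_img, bl$f, bl$k_u, bl$k_b, lambda)
    rem_pool <- a_inj * drop(exp(-outer(t_img, re$q + lambda)) %*% re$p)
    blood_conc <- a_inj *
      (bd$b1 * exp(-(bd$k1 + lambda) * t_blood) +
         bd$b2 * exp(-(bd$k2 + lambda) * t_blood))

    lesions <- params$lesions
    lesions$id <- seq_len(nrow(lesions))
    lesion_conc <- purrr::pmap(lesions, function(volume_mL, conc_scale_per_MBq_mL,
                                                 k_u, k_b, id) {
      a_inj * uw_frac(t_img, conc_scale_per_MBq_mL, k_u, k_b, lambda)
    })
    lesion_activity <- Reduce(`+`, purrr::map2(lesion_conc, lesions$volume_mL, `*`),
                              rep(0, length(t_img)))
    total <- skeleton + kidneys + bladder + rem_pool + lesion_activity

    noisy <- function(v) {
      s <- params$noise_sigma
      if (s == 0) return(v)
      v * exp(rnorm(length(v), 0, s) - s^2 / 2)
    }
    fov <- 1 - phantom$leg_bone_fraction  # torso-limited field of view

    curves <- dplyr::bind_rows(
      tibble::tibble(region = "skeleton", time_h = t_img,
                     value = noisy(skeleton * fov), mode = "activity"),
      tibble::tibble(region = "kidneys", time_h = t_img,
                     value = noisy(kidneys), mode = "activity"),
      tibble::tibble(region = "bladder_content", time_h = t_img,
                     value = noisy(bladder), mode = "activity"),
      tibble::tibble(region = "total_body", time_h = t_img,
                     value = noisy(total * fov), mode = "activity"),
      tibble::tibble(region = "blood", time_h = t_blood,
                     value = noisy(blood_conc), mode = "concentration"),
      purrr::list_rbind(purrr::map2(
        lesions$id, lesion_conc,
        ~ tibble::tibble(region = paste0("tumor:", .x), time_h = t_img,
                         value = noisy(.y), mode = "concentration")))
    )

    bundle <- list(
      patient_id = sprintf("synthetic-%d", params$seed),
      injected_activity_MBq = a_inj,
      kidney_volume_mL = params$kidney_volume_mL,
      curves = curves,
      lesions = lesions[c("id", "volume_mL")]
    )

    # exact cumulated activities (leg-complete), per region
    blood_int <- a_inj * (bd$b1 / (bd$k1 + lambda) + bd$b2 / (bd$k2 + lambda))
    marrow_int <- blood_int * phantom$rmblr *
      phantom$red_marrow_mass_g / phantom$red_marrow_density_g_mL
    rem_pool_int <- a_inj * sum(re$p / (re$q + lambda))
    sk_int <- a_inj * uw_integral(sk$f, sk$k_u, sk$k_b, lambda)
    ki_int <- a_inj * uw_integral(ki$f, ki$k_u, ki$k_b, lambda)
    bl_int <- a_inj * uw_integral(bl$f, bl$k_u, bl$k_b, lambda)
    lesion_int <- purrr::pmap_dbl(lesions, function(volume_mL,
                                                    conc_scale_per_MBq_mL,
                                                    k_u, k_b, id) {
      a_inj * volume_mL * uw_integral(conc_scale_per_MBq_mL, k_u, k_b, lambda)
    })

    truth_cum <- tibble::tibble(
      region = c("skeleton", "kidneys", "bladder_content", "red_marrow",
                 "remainder", "total_body", paste0("tumor:", lesions$id)),
      cumulated_MBq_h = c(sk_int, ki_int, bl_int, marrow_int,
                          rem_pool_int - marrow_int,
                          sk_int + ki_int + bl_int + rem_pool_int + sum(lesion_int),
                          lesion_int)
    )

    list(bundle = bundle,
         truth = list(cumulated = truth_cum,
                      blood_conc_integral_MBq_h_per_mL = blood_int / 1,
                      injected_activity_MBq = a_inj,
                      params = params))
  })
}

#' Generate a synthetic cohort
#'
#' Draws `n` patients whose kinetic parameters are jittered lognormally
#' around the defaults (coefficient of variation `variability` on uptake
#' fractions, rates and lesion scales) with per-patient seeds derived
#' deterministically from `master_seed`.
#'
#' @param n Number of patients, `>= 1`.
#' @param master_seed Integer master seed.
#' @param variability Lognormal CV of the parameter jitter (0 disables it).
#' @param noise_sigma Per-sample measurement noise sigma, passed through.
#' @param high_kidney Logical, recycled over patients: which patients use
#'   the elevated-kidney preset.
#' @param ... Further arguments to [patient_params()].
#' @return A list of `n` elements, each as returned by [generate_patient()].
#' @export
generate_cohort <- function(n, master_seed = 1L, variability = 0.15,
                            noise_sigma = 0.05, high_kidney = FALSE, ...) {
  if (!is.numeric(n) || n < 1) abort("`n` must be >= 1.")
  n <- as.integer(n)
  high_kidney <- rep_len(high_kidney, n)
  with_local_seed(master_seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    jit <- function(x, v) x * exp(rnorm(length(x), 0, v) - v^2 / 2)
    lapply(seq_len(n), function(i) {
      v <- variability
      base <- patient_params(noise_sigma = noise_sigma, seed = seeds[i],
                             high_kidney = high_kidney[i], ...)
      les <- base$lesions
      les$conc_scale_per_MBq_mL <- jit(les$conc_scale_per_MBq_mL, v)
      les$volume_mL <- jit(les$volume_mL, v)
      p <- patient_params(
        blood = purrr::map(base$blood, jit, v = v),
        skeleton = list(f = min(jit(base$skeleton$f, v), 0.8),
                        k_u = jit(base$skeleton$k_u, v),
                        k_b = jit(base$skeleton$k_b, v)),
        kidneys = purrr::map(base$kidneys, jit, v = v),
        bladder = purrr::map(base$bladder, jit, v = v),
        lesions = les,
        kidney_volume_mL = jit(base$kidney_volume_mL, v),
        noise_sigma = noise_sigma, seed = seeds[i], ...)
      generate_patient(p)
    })
  })
}
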