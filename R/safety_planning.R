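#' Maximum tolerated injected activity
#'
#' For each organ with a dose limit, the per-organ maximum tolerated
#' activity is limit (Gy) / normalized dose (Gy/GBq), in GBq; the planning
#' MTA is the minimum over organs and the limiting organ the one attaining
#' it. Organs with zero dose would tolerate unlimited activity; they are
#' excluded from the minimum with a warning and flagged (`unbounded`).
#' Dosed organs without a limit are ignored with a note. Ties are broken in
#' the fixed order red marrow, kidneys, bone surfaces, then alphabetically.
#'
#' @param doses Named numeric vector, or tibble with `organ`/`target` and a
#'   dose column, of normalized absorbed doses in Gy/GBq.
#' @param limits [dose_limits()].
#' @return List of class `mta_result`: `mta_GBq`, `limiting_organ`,
#'   `per_organ` (tibble `organ`, `dose_Gy_per_GBq`, `limit_Gy`, `mta_GBq`,
#'   `unbounded`).
#' @examples
#' max_tolerated_activity(c(red_marrow = 0.206, kidneys = 0.094,
#'                          bone_surfaces = 0.635))$mta_GBq # 9.71
#' @export
max_tolerated_activity <- function(doses, limits = dose_limits()) {
  if (is.data.frame(doses)) {
    organ_col <- intersect(c("organ", "target", "region"), names(doses))[1]
    dose_col <- setdiff(names(doses), organ_col)[1]
    doses <- setNames(doses[[dose_col]], doses[[organ_col]])
  }
  if (length(doses) == 0) abort("`doses` must be a non-empty map organ -> Gy/GBq.")
  if (any(doses < 0)) abort("Doses must be >= 0.")
  no_limit <- setdiff(names(doses), names(limits))
  if (length(no_limit)) {
    rlang::inform(sprintf("No dose limit for: %s; ignored in MTA.",
                          paste(no_limit, collapse = ", ")))
  }
  organs <- intersect(names(limits), names(doses))
  if (length(organs) == 0) abort("No dosed organ has a dose limit.")

  per <- tibble::tibble(
    organ = organs,
    dose_Gy_per_GBq = unname(doses[organs]),
    limit_Gy = unname(limits[organs])
  ) |>
    dplyr::mutate(mta_GBq = .data$limit_Gy / .data$dose_Gy_per_GBq,
                  unbounded = !is.finite(.data$mta_GBq))
  if (any(per$unbounded)) {
    warn(sprintf("Zero dose for %s: unlimited per-organ MTA, excluded from the minimum.",
                 paste(per$organ[per$unbounded], collapse = ", ")))
  }
  finite <- dplyr::filter(per, !.data$unbounded)
  if (nrow(finite) == 0) {
    abort("All organ doses are zero: the MTA is undefined.")
  }
  tie_order <- c("red_marrow", "kidneys", "bone_surfaces")
  finite <- finite[order(finite$mta_GBq,
                         match(finite$organ, tie_order, nomatch = 99),
                         finite$organ), ]
  structure(
    list(mta_GBq = finite$mta_GBq[1], limiting_organ = finite$organ[1],
         per_organ = per),
    class = "mta_result"
  )
}

#' @export
print.mta_result <- function(x, ...) {
  cat(sprintf("<mta_result> MTA = %.3f GBq, limiting organ: %s\n",
              x$mta_GBq, x$limiting_organ))
  print(x$per_organ)
  invisible(x)
}

#' Therapeutic index
#'
#' Ratio of the mean tumor absorbed dose to an organ-at-risk absorbed dose
#' (both normalized, Gy/GBq).
#'
#' @param mean_tumor_dose Mean lesion dose, Gy/GBq.
#' @param organ_dose Organ-at-risk dose, Gy/GBq, `> 0`.
#' @return The ratio (vectorized).
#' @examples
#' therapeutic_index(6.30, 0.206) # 30.6
#' @export
therapeutic_index <- function(mean_tumor_dose, organ_dose) {
  if (any(organ_dose <= 0)) abort("`organ_dose` must be > 0.")
  mean_tumor_dose / organ_dose
}

#' Sensitivity of the red-marrow dose to the RMBLR
#'
#' The blood-derived marrow self-activity scales linearly with the RMBLR
#' while cross-fire terms do not, so changing the ratio from `rmblr_ref` to
#' `rmblr_new` rescales only the self-dose fraction `self_fraction`:
#' \deqn{D_{new} = D (1 - f) + D f \, r_{new}/r_{ref},}
#' \deqn{\Delta\% = -100 f (1 - r_{new}/r_{ref}).}
#' With a 30% self-contribution, moving the RMBLR from 1.0 to 0.36 lowers
#' the marrow dose by 19.2%.
#'
#' @param total_marrow_dose Total normalized marrow dose, Gy/GBq.
#' @param self_fraction Fraction of that dose from marrow self-irradiation,
#'   in \[0, 1\].
#' @param rmblr_ref,rmblr_new Reference and alternative RMBLR, `> 0` (ref).
#' @return List with `new_dose_Gy_per_GBq` and `pct_change`.
#' @examples
#' rmblr_sensitivity(0.355, 0.30, 1.0, 0.36)$pct_change # -19.2
#' @export
rmblr_sensitivity <- function(total_marrow_dose, self_fraction,
                              rmblr_ref = 1.0, rmblr_new = 0.36) {
  if (self_fraction < 0 || self_fraction > 1) {
    abort("`self_fraction` must lie in [0, 1].")
  }
  if (rmblr_ref <= 0) abort("`rmblr_ref` must be > 0.")
  if (rmblr_new < 0) abort("`rmblr_new` must be >= 0.")
  ratio <- rmblr_new / rmblr_ref
  new_dose <- total_marrow_dose * (1 - self_fraction) +
    total_marrow_dose * self_fraction * ratio
  list(new_dose_Gy_per_GBq = new_dose,
       pct_change = -100 * self_fraction * (1 - ratio))
}

#' Cohort summary statistics
#'
#' Median (midpoint of the two central values for even n), arithmetic
#' mean, and standard deviation. Clinical dosimetry report tables commonly
#' print the population SD (denominator n); that is the default, with the
#' sample convention (n - 1) available.
#'
#' @param values Non-empty numeric vector.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return One-row tibble with `n`, `median`, `mean`, `sd`.
#' @examples
#' cohort_summary(c(1, 2, 4))
#' @export
cohort_summary <- function(values, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(values) == 0) abort("`values` must be non-empty.")
  if (any(!is.finite(values))) abort("`values` must be finite.")
  n <- length(values)
  s <- if (n == 1) 0 else if (sd_type == "sample") sd(values) else
    sqrt(mean((values - mean(values))^2))
  tibble::tibble(n = n, median = median(values), mean = mean(values), sd = s)
}

#' Assemble a per-patient treatment plan
#'
#' Combines the organ dose result, lesion doses, and dose limits into the
#' planning quantities reported per patient: normalized organ doses, MTA
#' and limiting organ, per-organ MTAs, mean tumor dose, and therapeutic
#' indices (computed against red marrow and bone surfaces; kidneys are
#' customarily skipped when their dose is comparatively negligible, but an
#' index is reported for every limited organ with positive dose).
#'
#' @param dose_result An `organ_dose_result` from [organ_doses()], or a
#'   named vector of organ doses in Gy/GBq.
#' @param tumor_doses Numeric vector of per-lesion normalized doses,
#'   Gy/GBq; may be empty (no measurable lesions), in which case the
#'   therapeutic indices are absent and `no_lesions` is flagged.
#' @param limits [dose_limits()].
#' @return List of class `plan_result`: `organ_doses` (tibble), `mta_GBq`,
#'   `limiting_organ`, `per_organ_mta` (tibble), `mean_tumor_dose_Gy_per_GBq`,
#'   `therapeutic_indices` (tibble `organ`, `index`), `no_lesions`.
#' @export
plan_patient <- function(dose_result, tumor_doses = numeric(),
                         limits = dose_limits()) {
  doses <- if (inherits(dose_result, "organ_dose_result")) {
    setNames(dose_result$doses$dose_Gy_per_GBq, dose_result$doses$target)
  } else {
    dose_result
  }
  missing_lim <- setdiff(names(limits), names(doses))
  if (length(missing_lim)) {
    abort(sprintf("Dose result does not cover limited organ(s): %s.",
                  paste(missing_lim, collapse = ", ")))
  }
  mta <- max_tolerated_activity(doses, limits)
  no_lesions <- length(tumor_doses) == 0
  mean_tumor <- if (no_lesions) NA_real_ else mean(tumor_doses)
  ti <- if (no_lesions) {
    warn("No lesion doses supplied: therapeutic indices are absent.")
    tibble::tibble(organ = character(), index = numeric())
  } else {
    pos <- names(limits)[doses[names(limits)] > 0]
    tibble::tibble(organ = pos,
                   index = unname(therapeutic_index(mean_tumor, doses[pos])))
  }
  structure(
    list(organ_doses = tibble::tibble(organ = names(doses),
                                      dose_Gy_per_GBq = unname(doses)),
         mta_GBq = mta$mta_GBq, limiting_organ = mta$limiting_organ,
         per_organ_mta = mta$per_organ,
         mean_tumor_dose_Gy_per_GBq = mean_tumor,
         tumor_doses_Gy_per_GBq = tumor_doses,
         therapeutic_indices = ti, no_lesions = no_lesions),
    class = "plan_result"
  )
}

#' @export
print.plan_result <- function(x, ...) {
  cat(sprintf("<plan_result> MTA = %.2f GBq (limiting organ: %s)\n",
              x$mta_GBq, x$limiting_organ))
  print(x$organ_doses)
  if (!x$no_lesions) {
    cat(sprintf("mean tumor dose: %.2f Gy/GBq\n", x$mean_tumor_dose_Gy_per_GBq))
  }
  invisible(x)
}

#' @describeIn plan_patient One row per organ: dose, limit, per-organ MTA,
#'   therapeutic index, and whether it is the limiting organ.
#' @param x A `plan_result`.
#' @param ... Unused.
#' @method tidy plan_result
#' @export
tidy.plan_result <- function(x, ...) {
  x$per_organ_mta |>
    dplyr::left_join(x$therapeutic_indices,
                     by = c(organ = "organ")) |>
    dplyr::rename(therapeutic_index = "index") |>
    dplyr::mutate(limiting = .data$organ == x$limiting_organ)
}

#' @describeIn plan_patient One-row summary of the plan.
#' @method glance plan_result
#' @export
glance.plan_result <- function(x, ...) {
  tibble::tibble(
    mta_GBq = x$mta_GBq, limiting_organ = x$limiting_organ,
    mean_tumor_dose_Gy_per_GBq = x$mean_tumor_dose_Gy_per_GBq,
    n_lesions = length(x$tumor_doses_Gy_per_GBq)
  )
}
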