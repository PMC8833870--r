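#' Red-marrow activity from a blood concentration
#'
#' Blood-based red-marrow model: marrow activity is the blood activity
#' concentration times the red-marrow-to-blood activity-concentration ratio
#' (RMBLR) times the marrow volume,
#' \deqn{A_{rm} = AC_{blood} \times RMBLR \times 1500\,g / 1.05\,g\,mL^{-1}.}
#' Linear in both the concentration and the RMBLR.
#'
#' @param blood_conc Blood activity concentration(s), MBq/mL, `>= 0`.
#' @param constants [phantom_constants()].
#' @return Red-marrow activity, MBq (vectorized over `blood_conc`).
#' @examples
#' red_marrow_activity(0.07) # 100 MBq with RMBLR 1
#' @export
red_marrow_activity <- function(blood_conc, constants = phantom_constants()) {
  if (any(!is.finite(blood_conc)) || any(blood_conc < 0)) {
    abort("`blood_conc` must be finite and >= 0 (MBq/mL).")
  }
  blood_conc * constants$rmblr *
    constants$red_marrow_mass_g / constants$red_marrow_density_g_mL
}

#' Leg-scaling correction for a torso-limited field of view
#'
#' Whole-body SPECT fields of view that exclude the legs miss the leg
#' share of the skeleton (33.6% of total bone mass), so segmented skeleton
#' and total-body values are scaled by \eqn{1/(1 - 0.336) = 1.506}. Applies
#' to activities or cumulated activities alike (it is a pure scale factor).
#'
#' @param value Activity (MBq) or cumulated activity (MBq h), `>= 0`.
#' @param constants [phantom_constants()].
#' @return The scaled value(s).
#' @examples
#' scale_for_legs(66.4) # 100
#' @export
scale_for_legs <- function(value, constants = phantom_constants()) {
  if (constants$leg_bone_fraction >= 1) {
    abort("`leg_bone_fraction` must be < 1.")
  }
  if (any(value < 0)) abort("`value` must be >= 0.")
  value / (1 - constants$leg_bone_fraction)
}

#' Partition skeletal cumulated activity onto bone mineral surfaces
#'
#' Bisphosphonates bind to the bone mineral surface, so skeletal cumulated
#' activity is distributed between the cortical (80%) and trabecular (20%)
#' bone mineral surfaces. The two parts sum to the input exactly.
#'
#' @param skeleton_cumulated Skeletal cumulated activity, MBq h, `>= 0`.
#' @param constants [phantom_constants()].
#' @return Named numeric vector with `cortical_surface` and
#'   `trabecular_surface` components.
#' @examples
#' split_skeleton(100) # 80 / 20
#' @export
split_skeleton <- function(skeleton_cumulated, constants = phantom_constants()) {
  if (any(skeleton_cumulated < 0)) abort("`skeleton_cumulated` must be >= 0.")
  cortical <- constants$cortical_fraction * skeleton_cumulated
  # remainder rather than 0.2 * x: conservation is then exact by construction
  c(cortical_surface = cortical,
    trabecular_surface = skeleton_cumulated - cortical)
}

#' Tumor activity and mass from concentration and volume
#'
#' Lesion activity is the mean activity concentration times the lesion
#' volume; lesion mass uses the cortical-bone density of 1.92 g/mL
#' (osteoblastic metastases are mineralized).
#'
#' @param mean_conc Mean activity concentration, MBq/mL, `>= 0`.
#' @param volume Lesion volume, mL, `> 0`.
#' @param constants [phantom_constants()].
#' @return A tibble with `activity_MBq` and `mass_g`.
#' @examples
#' tumor_activity_and_mass(2, 1) # 2 MBq, 1.92 g
#' @export
tumor_activity_and_mass <- function(mean_conc, volume,
                                    constants = phantom_constants()) {
  if (any(volume <= 0)) abort("`volume` must be > 0 mL.")
  if (any(mean_conc < 0)) abort("`mean_conc` must be >= 0.")
  tibble::tibble(activity_MBq = mean_conc * volume,
                 mass_g = volume * constants$tumor_density_g_mL)
}

#' Kidney mass from CT volume
#'
#' Total kidney mass (both kidneys) from the CT-derived volume, assuming a
#' density of 1.06 g/mL; used to patient-adapt the kidney self-dose.
#'
#' @param volume Kidney volume, mL, `> 0`.
#' @param constants [phantom_constants()].
#' @return Mass in g.
#' @examples
#' kidney_mass(100) # 106 g
#' @export
kidney_mass <- function(volume, constants = phantom_constants()) {
  if (any(volume <= 0)) abort("`volume` must be > 0 mL.")
  volume * constants$kidney_density_g_mL
}

#' Remainder-of-body curve by pointwise subtraction
#'
#' Subtracts the summed source-organ curves from the total-body curve at
#' each imaging time. Negative differences (possible with segmentation
#' noise) are clamped to zero and the clamp events recorded in the
#' `clamped` column. The total-body curve must already be leg-scaled; all
#' curves must share the same time grid.
#'
#' @param total_body Tibble with `time_h`, `value` for the total body.
#' @param sources List of tibbles (`time_h`, `value`) to subtract.
#' @return A tibble `region = "remainder"`, `time_h`, `value`, `clamped`.
#' @examples
#' tb <- tibble::tibble(time_h = c(1, 2), value = c(100, 90))
#' s1 <- tibble::tibble(time_h = c(1, 2), value = c(60, 50))
#' remainder_curve(tb, list(s1))
#' @export
remainder_curve <- function(total_body, sources) {
  grid <- total_body$time_h
  for (s in sources) {
    if (length(s$time_h) != length(grid) || any(abs(s$time_h - grid) > 1e-9)) {
      abort("All source curves must share the total-body time grid.")
    }
  }
  subtracted <- total_body$value -
    Reduce(`+`, lapply(sources, `[[`, "value"), rep(0, length(grid)))
  clamped <- subtracted < 0
  if (any(clamped)) {
    warn(sprintf("Remainder clamped to 0 at %d time point(s).", sum(clamped)))
  }
  tibble::tibble(region = "remainder", time_h = grid,
                 value = pmax(subtracted, 0), clamped = clamped)
}

# Linear interpolation of a curve onto the imaging grid; only used when a
# curve (e.g. blood) is sampled on a denser schedule. With 5 imaging points
# anything higher-order would overfit.
interp_to_grid <- function(data, grid) {
  if (length(data$time_h) == length(grid) &&
      all(abs(data$time_h - grid) < 1e-9)) return(data$value)
  if (min(grid) < min(data$time_h) - 1e-9 || max(grid) > max(data$time_h) + 1e-9) {
    abort("Cannot interpolate: imaging grid extends beyond the sampled range.")
  }
  stats::approx(data$time_h, data$value, xout = grid, rule = 1)$y
}

#' Build the MIRD source-organ set from a patient bundle
#'
#' Converts a patient measurement bundle into the six MIRD source regions:
#' cortical and trabecular bone mineral surface (via leg scaling of the
#' skeleton curve and the 80/20 surface partition, applied downstream of
#' integration), red marrow (blood model), kidneys, urinary bladder
#' content, and remainder of body (leg-scaled total body minus the other
#' sources). Tumor activity is excluded from the skeleton by the
#' segmentation; `tumors_in_bone = TRUE` adds the summed lesion activity
#' back onto the skeleton curve, which bounds the additional marrow
#' cross-dose from bone-adjacent lesions.
#'
#' @param bundle A patient bundle as returned by [generate_patient()] or
#'   [read_patient_bundle()]: a list with `patient_id`,
#'   `injected_activity_MBq`, `kidney_volume_mL`, `curves` (tibble with
#'   `region`, `time_h`, `value`, `mode`; regions `skeleton`, `kidneys`,
#'   `bladder_content`, `total_body`, `blood`), and `lesions` (tibble with
#'   `id`, `volume_mL`; per-lesion concentration curves live in `curves`
#'   as regions `tumor:<id>`).
#' @param constants [phantom_constants()].
#' @param tumors_in_bone Re-include lesion activity in the skeleton curve.
#' @return A list of class `source_set`: `curves` (tibble of the six source
#'   regions on the imaging grid, activities in MBq), `provenance` (tibble
#'   of per-region construction notes), `injected_activity_MBq`,
#'   `kidney_mass_g`, `tumors` (per-lesion tibble with `id`, `volume_mL`,
#'   `mass_g` and concentration curves kept in `tumor_curves`).
#' @export
build_source_set <- function(bundle, constants = phantom_constants(),
                             tumors_in_bone = FALSE) {
  curves <- bundle$curves
  need <- c("skeleton", "kidneys", "bladder_content", "total_body", "blood")
  for (r in need) {
    if (!r %in% curves$region) {
      abort(sprintf("Patient bundle is missing the '%s' curve.", r))
    }
  }
  get <- function(r) dplyr::arrange(dplyr::filter(curves, .data$region == r),
                                    .data$time_h)
  grid <- get("skeleton")$time_h

  skeleton <- scale_for_legs(get("skeleton")$value, constants)
  total_body <- scale_for_legs(get("total_body")$value, constants)
  kidneys <- interp_to_grid(get("kidneys"), grid)
  bladder <- interp_to_grid(get("bladder_content"), grid)
  # marrow is kept on the blood schedule (its 5-min first sample resolves
  # the fast blood phase that has already cleared by the first image);
  # the imaging-grid version is only used for the remainder subtraction
  blood <- get("blood")
  marrow_full <- tibble::tibble(
    region = "red_marrow", time_h = blood$time_h,
    value = red_marrow_activity(blood$value, constants))
  marrow <- interp_to_grid(marrow_full, grid)

  tumor_ids <- unique(curves$region[grepl("^tumor:", curves$region)])
  tumor_curves <- dplyr::filter(curves, grepl("^tumor:", .data$region))
  tumor_total <- rep(0, length(grid))
  if (length(tumor_ids)) {
    lesions <- bundle$lesions
    for (id in tumor_ids) {
      vol <- lesions$volume_mL[paste0("tumor:", lesions$id) == id]
      tumor_total <- tumor_total +
        interp_to_grid(get(id), grid) * vol
    }
  }
  if (tumors_in_bone) skeleton <- skeleton + tumor_total

  mk <- function(region, value) tibble::tibble(region = region, time_h = grid,
                                               value = value)
  rem <- remainder_curve(
    mk("total_body", total_body),
    list(mk("skeleton", skeleton), mk("kidneys", kidneys),
         mk("bladder_content", bladder), mk("red_marrow", marrow),
         if (!tumors_in_bone) mk("tumor", tumor_total) else mk("tumor", rep(0, length(grid))))
  )

  source_curves <- dplyr::bind_rows(
    mk("skeleton", skeleton),
    marrow_full,
    mk("kidneys", kidneys),
    mk("bladder_content", bladder),
    mk("remainder", rem$value)
  )

  provenance <- tibble::tibble(
    region = c("skeleton", "red_marrow", "kidneys", "bladder_content", "remainder"),
    note = c(
      sprintf("leg-scaled by %.4f%s", 1 / (1 - constants$leg_bone_fraction),
              if (tumors_in_bone) "; lesion activity re-included" else "; lesions excluded"),
      sprintf("blood model, RMBLR = %g", constants$rmblr),
      "measured", "measured",
      sprintf("total body minus sources; %d point(s) clamped", sum(rem$clamped))
    )
  )

  structure(
    list(curves = source_curves, provenance = provenance,
         injected_activity_MBq = bundle$injected_activity_MBq,
         kidney_mass_g = kidney_mass(bundle$kidney_volume_mL, constants),
         tumors = bundle$lesions, tumor_curves = tumor_curves,
         tumors_in_bone = tumors_in_bone),
    class = "source_set"
  )
}

#' Residence times for a source set
#'
#' Integrates every source curve ([cumulated_activity()]), applies the
#' cortical/trabecular partition to the skeleton, and normalizes by the
#' injected activity.
#'
#' @param source_set A `source_set` from [build_source_set()].
#' @param constants [phantom_constants()].
#' @inheritParams cumulated_activity
#' @return A tibble with `region`, `cumulated_MBq_h`, `residence_h` for the
#'   six MIRD source regions.
#' @export
source_residence_times <- function(source_set, policy = c("fit", "hybrid"),
                                   constants = phantom_constants(),
                                   lu_constants = lu177_constants(),
                                   max_terms = 2) {
  policy <- match.arg(policy)
  cum <- cumulated_activity(source_set$curves, policy = policy,
                            max_terms = max_terms, constants = lu_constants)
  skel <- cum$cumulated[cum$region == "skeleton"]
  parts <- split_skeleton(skel, constants)
  out <- cum |>
    dplyr::filter(.data$region != "skeleton") |>
    dplyr::select("region", cumulated_MBq_h = "cumulated") |>
    dplyr::bind_rows(tibble::tibble(region = names(parts),
                                    cumulated_MBq_h = unname(parts)))
  out$residence_h <- normalized_cumulated_activity(
    out$cumulated_MBq_h, source_set$injected_activity_MBq)
  dplyr::arrange(out, match(.data$region,
                            c("cortical_surface", "trabecular_surface",
                              "red_marrow", "kidneys", "bladder_content",
                              "remainder")))
}
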