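#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end pipeline: the S-value matrix and
#' sphere table, phantom and decay constants, dose limits, tissue weights,
#' the curve-integration policy, and the lesion-in-bone option.
#'
#' @param smat [s_matrix()]; defaults to the packaged illustrative matrix.
#' @param sphere [sphere_table()].
#' @param phantom [phantom_constants()].
#' @param lu [lu177_constants()].
#' @param limits [dose_limits()].
#' @param weights Tissue weighting factors for the effective dose.
#' @param policy Curve-integration policy, `"fit"` or `"hybrid"`.
#' @param max_terms Maximum exponential terms per fit.
#' @param tumors_in_bone Re-include lesion activity in the skeleton source.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(smat = default_s_matrix(),
                            sphere = default_sphere_table(),
                            phantom = phantom_constants(),
                            lu = lu177_constants(),
                            limits = dose_limits(),
                            weights = default_tissue_weights(),
                            policy = c("fit", "hybrid"),
                            max_terms = 2,
                            tumors_in_bone = FALSE) {
  policy <- match.arg(policy)
  structure(
    list(smat = smat, sphere = sphere, phantom = phantom, lu = lu,
         limits = limits, weights = weights, policy = policy,
         max_terms = max_terms, tumors_in_bone = tumors_in_bone),
    class = "pipeline_config"
  )
}

# One patient end-to-end: bundle -> sources -> residence times -> organ
# doses (patient kidney mass) -> lesion sphere doses -> plan.
analyze_patient <- function(bundle, config) {
  ss <- build_source_set(bundle, constants = config$phantom,
                         tumors_in_bone = config$tumors_in_bone)
  rt <- source_residence_times(ss, policy = config$policy,
                               constants = config$phantom,
                               lu_constants = config$lu,
                               max_terms = config$max_terms)
  dr <- organ_doses(rt, config$smat,
                    patient_masses = c(kidneys = ss$kidney_mass_g))
  eff <- effective_dose(
    setNames(dr$doses$dose_Gy_per_GBq, dr$doses$target), config$weights)

  tumor_doses <- numeric()
  lesion_tbl <- tibble::tibble(lesion = integer(), dose_Gy_per_GBq = numeric())
  if (nrow(ss$tumor_curves) > 0) {
    cum <- cumulated_activity(ss$tumor_curves, policy = config$policy,
                              max_terms = config$max_terms,
                              constants = config$lu)
    les <- ss$tumors
    les$region <- paste0("tumor:", les$id)
    les <- dplyr::inner_join(les, cum, by = "region")
    mass <- tumor_activity_and_mass(1, les$volume_mL, config$phantom)$mass_g
    rt_les <- normalized_cumulated_activity(
      les$cumulated * les$volume_mL, bundle$injected_activity_MBq)
    tumor_doses <- sphere_dose(rt_les, mass, config$sphere)
    lesion_tbl <- tibble::tibble(lesion = les$id,
                                 dose_Gy_per_GBq = tumor_doses)
  }

  plan <- plan_patient(
    c(setNames(dr$doses$dose_Gy_per_GBq, dr$doses$target)),
    tumor_doses = tumor_doses, limits = config$limits)

  list(patient_id = bundle$patient_id, source_set = ss,
       residence_times = rt, dose_result = dr,
       effective_dose_mSv_per_MBq = eff, lesions = lesion_tbl, plan = plan)
}

#' Run the full dosimetry pipeline over a cohort
#'
#' Applies the measurement-to-plan pipeline to every patient bundle and
#' assembles cohort report tables in the layout of a clinical dosimetry
#' publication: an organ table (organs as rows, patients as columns, with
#' Median/Mean/SD appended, plus effective-dose and MTA rows) and a lesion
#' table (lesions as rows, patients as columns, with per-patient
#' Median/Mean/SD). A patient whose analysis fails at any stage is excluded
#' and listed with the reason; the report still covers the others.
#'
#' @param bundles List of patient bundles (each the `bundle` element of
#'   [generate_patient()], or read via [read_patient_bundle()]).
#' @param config [pipeline_config()].
#' @return A list of class `cohort_report`: `patients` (per-patient
#'   results, see [plan_patient()]), `organ_table`, `lesion_table`,
#'   `plan_summary` (tibble of per-patient MTA/limiting organ/indices),
#'   `excluded` (tibble `patient_id`, `reason`).
#' @export
run_pipeline <- function(bundles, config = pipeline_config()) {
  if (length(bundles) == 0) abort("`bundles` must be a non-empty list.")
  if (!is.null(bundles$curves)) bundles <- list(bundles)  # single bundle

  results <- list()
  excluded <- tibble::tibble(patient_id = character(), reason = character())
  for (b in bundles) {
    res <- tryCatch(
      analyze_patient(b, config),
      error = function(e) {
        excluded <<- dplyr::bind_rows(
          excluded,
          tibble::tibble(patient_id = b$patient_id %||% "<unnamed>",
                         reason = conditionMessage(e)))
        NULL
      })
    if (!is.null(res)) results[[res$patient_id]] <- res
  }
  if (length(results) == 0) abort("Every patient failed; nothing to report.")

  ids <- names(results)
  organ_long <- purrr::imap(results, function(r, id) {
    dplyr::bind_rows(
      dplyr::rename(r$dose_result$doses, quantity = "target",
                    value = "dose_Gy_per_GBq"),
      tibble::tibble(quantity = "effective_dose_mSv_per_MBq",
                     value = r$effective_dose_mSv_per_MBq),
      tibble::tibble(quantity = "mta_GBq", value = r$plan$mta_GBq)
    ) |> dplyr::mutate(patient_id = id)
  }) |> purrr::list_rbind()

  summarize_rows <- function(long, key) {
    long |>
      dplyr::group_by(.data[[key]]) |>
      dplyr::summarise(Median = median(.data$value),
                       Mean = mean(.data$value),
                       SD = sqrt(mean((.data$value - mean(.data$value))^2)),
                       .groups = "drop")
  }
  organ_table <- organ_long |>
    tidyr::pivot_wider(names_from = "patient_id", values_from = "value") |>
    dplyr::left_join(summarize_rows(organ_long, "quantity"), by = "quantity")

  lesion_long <- purrr::imap(results, function(r, id) {
    dplyr::mutate(r$lesions, patient_id = id)
  }) |> purrr::list_rbind()
  lesion_table <- if (nrow(lesion_long)) {
    wide <- lesion_long |>
      tidyr::pivot_wider(names_from = "patient_id",
                         values_from = "dose_Gy_per_GBq")
    stats_rows <- lesion_long |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(Median = median(.data$dose_Gy_per_GBq),
                       Mean = mean(.data$dose_Gy_per_GBq),
                       SD = sqrt(mean((.data$dose_Gy_per_GBq -
                                         mean(.data$dose_Gy_per_GBq))^2)),
                       .groups = "drop")
    list(doses = wide, per_patient_stats = stats_rows)
  } else {
    list(doses = tibble::tibble(), per_patient_stats = tibble::tibble())
  }

  plan_summary <- purrr::imap(results, function(r, id) {
    ti <- r$plan$therapeutic_indices
    tibble::tibble(
      patient_id = id,
      injected_activity_MBq = r$source_set$injected_activity_MBq,
      mta_GBq = r$plan$mta_GBq,
      limiting_organ = r$plan$limiting_organ,
      mean_tumor_dose_Gy_per_GBq = r$plan$mean_tumor_dose_Gy_per_GBq,
      ti_red_marrow = ti$index[ti$organ == "red_marrow"][1],
      ti_bone_surfaces = ti$index[ti$organ == "bone_surfaces"][1]
    )
  }) |> purrr::list_rbind()

  structure(
    list(patients = results, organ_table = organ_table,
         lesion_table = lesion_table, plan_summary = plan_summary,
         excluded = excluded, config_policy = config$policy),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d patient(s), %d excluded\n",
              length(x$patients), nrow(x$excluded)))
  print(x$organ_table)
  invisible(x)
}

#' Write a cohort report to CSV and JSON
#'
#' Writes `organ_table.csv` and `lesion_table.csv` (organs/lesions as rows,
#' patients as columns, Median/Mean/SD appended; Gy/GBq rounded to three
#' decimals and GBq to one, half away from zero), `plan_summary.csv`, and a
#' machine-readable `report.json` with full precision. Reruns with the same
#' report produce byte-identical files.
#'
#' @param report A `cohort_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  round_tbl <- function(tbl, digits) {
    for (nm in names(tbl)) {
      if (is.numeric(tbl[[nm]])) tbl[[nm]] <- round_half_out(tbl[[nm]], digits)
    }
    tbl
  }
  # report-table rounding convention: one decimal for GBq, three for Gy/GBq
  organ_rounded <- report$organ_table
  gbq_row <- organ_rounded$quantity == "mta_GBq"
  for (nm in names(organ_rounded)) {
    if (is.numeric(organ_rounded[[nm]])) {
      organ_rounded[[nm]] <- ifelse(gbq_row,
                                    round_half_out(organ_rounded[[nm]], 1),
                                    round_half_out(organ_rounded[[nm]], 3))
    }
  }
  p_organ <- file.path(dir, "organ_table.csv")
  readr::write_csv(organ_rounded, p_organ)
  p_lesion <- file.path(dir, "lesion_table.csv")
  readr::write_csv(round_tbl(report$lesion_table$doses, 3), p_lesion)
  p_plan <- file.path(dir, "plan_summary.csv")
  readr::write_csv(round_tbl(report$plan_summary, 3), p_plan)
  p_json <- file.path(dir, "report.json")
  payload <- list(
    organ_table = report$organ_table,
    lesion_doses = report$lesion_table$doses,
    lesion_stats = report$lesion_table$per_patient_stats,
    plan_summary = report$plan_summary,
    excluded = report$excluded
  )
  jsonlite::write_json(payload, p_json, digits = NA, pretty = TRUE)
  invisible(c(p_organ, p_lesion, p_plan, p_json))
}

#' Read and write patient bundles as JSON
#'
#' The on-disk patient bundle is a JSON object with `patient_id`,
#' `injected_activity_MBq`, `kidney_volume_mL`, `curves` (records with
#' `region`, `time_h`, `value`, `mode`) and `lesions` (records with `id`,
#' `volume_mL`); lesion concentration curves live in `curves` under
#' regions `tumor:<id>`.
#'
#' @param path JSON file path.
#' @return `read_patient_bundle()`: a bundle list with tibble components.
#' @export
read_patient_bundle <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$curves <- tibble::as_tibble(raw$curves)
  raw$lesions <- tibble::as_tibble(raw$lesions)
  validate_tac(raw$curves |> dplyr::filter(.data$region == "skeleton"))
  if (!is.numeric(raw$injected_activity_MBq) || raw$injected_activity_MBq <= 0) {
    abort("Bundle `injected_activity_MBq` must be > 0.")
  }
  raw
}

#' @rdname read_patient_bundle
#' @param bundle A patient bundle list.
#' @export
write_patient_bundle <- function(bundle, path) {
  jsonlite::write_json(bundle, path, digits = NA, pretty = TRUE,
                       auto_unbox = TRUE, dataframe = "rows")
  invisible(path)
}
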