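#' S-value matrix for MIRD organ dose calculation
#'
#' An S-value is the absorbed dose in a target region per unit cumulated
#' activity in a source region, in Gy/(MBq h); it is phantom- and
#' nuclide-specific configuration, not something this package computes.
#' The constructor validates a long-format table of values plus reference
#' masses and returns the kernel used by [organ_doses()].
#'
#' @param values Tibble/data frame with columns `source`, `target`,
#'   `s_value_Gy_per_MBq_h` (all `>= 0`).
#' @param reference_masses Tibble/data frame with `region`, `mass_g`
#'   (positive); must cover every region that appears as both source and
#'   target (needed for patient mass scaling of self-dose terms).
#' @param phantom,nuclide,provenance Metadata strings carried along.
#' @return An object of class `s_matrix`.
#' @seealso [default_s_matrix()], [read_s_matrix()]
#' @export
s_matrix <- function(values, reference_masses,
                     phantom = "unspecified", nuclide = "Lu-177",
                     provenance = "user-supplied") {
  values <- tibble::as_tibble(values)
  reference_masses <- tibble::as_tibble(reference_masses)
  need <- c("source", "target", "s_value_Gy_per_MBq_h")
  if (!all(need %in% names(values))) {
    abort("`values` needs columns source, target, s_value_Gy_per_MBq_h.")
  }
  if (any(values$s_value_Gy_per_MBq_h < 0)) abort("S-values must be >= 0.")
  if (anyDuplicated(values[c("source", "target")])) {
    abort("Duplicate source-target pairs in the S-value table.")
  }
  if (!all(c("region", "mass_g") %in% names(reference_masses))) {
    abort("`reference_masses` needs columns region and mass_g.")
  }
  if (any(reference_masses$mass_g <= 0)) abort("Reference masses must be > 0.")
  both <- intersect(unique(values$source), unique(values$target))
  for (r in both) {
    s_rr <- values$s_value_Gy_per_MBq_h[values$source == r & values$target == r]
    if (length(s_rr) == 0 || s_rr <= 0) {
      abort(sprintf("Self S-value S(%s <- %s) must be present and > 0.", r, r))
    }
  }
  structure(
    list(values = values, reference_masses = reference_masses,
         sources = unique(values$source), targets = unique(values$target),
         phantom = phantom, nuclide = nuclide, provenance = provenance),
    class = "s_matrix"
  )
}

#' @export
print.s_matrix <- function(x, ...) {
  cat(sprintf("<s_matrix: %s / %s; %d sources x %d targets; %s>\n",
              x$phantom, x$nuclide, length(x$sources), length(x$targets),
              x$provenance))
  invisible(x)
}

#' Read an S-value matrix from configuration CSVs
#'
#' @param values_path CSV with header `source,target,s_value_Gy_per_MBq_h`.
#' @param masses_path CSV with header `region,mass_g`.
#' @inheritParams s_matrix
#' @return An `s_matrix` object.
#' @export
read_s_matrix <- function(values_path, masses_path,
                          phantom = "unspecified", nuclide = "Lu-177",
                          provenance = paste("read from", basename(values_path))) {
  s_matrix(readr::read_csv(values_path, show_col_types = FALSE),
           readr::read_csv(masses_path, show_col_types = FALSE),
           phantom = phantom, nuclide = nuclide, provenance = provenance)
}

#' Packaged illustrative Lu-177 S-value matrix
#'
#' A small synthetic S-value matrix for the six bone-therapy source organs
#' and four targets, built from the Lu-177 electron energy per decay
#' (Delta = 0.0853 Gy g/(MBq h)) and round-number absorbed fractions. It is
#' **not** a validated phantom kernel: it exists so the pipeline runs
#' offline end-to-end with clinically plausible magnitudes, and it is
#' clearly labelled as such. Swap in a real phantom matrix via
#' [read_s_matrix()] for any real analysis; doses are exactly linear in the
#' S-values, so nothing else changes.
#'
#' @return An `s_matrix` object.
#' @export
default_s_matrix <- function() {
  path <- system.file("extdata", package = "zoldose")
  read_s_matrix(
    file.path(path, "s_matrix_lu177_synthetic.csv"),
    file.path(path, "reference_masses_synthetic.csv"),
    phantom = "synthetic adult",
    provenance = "illustrative synthetic values, not a validated phantom"
  )
}

#' MIRD organ doses from residence times and an S-value matrix
#'
#' Computes the normalized absorbed dose of every target region as
#' \deqn{D(t) = \sum_s \tau_s \, S(t \leftarrow s)}
#' in Gy per MBq injected, reported as Gy/GBq (numerically equal to
#' mGy/MBq). When a patient-specific mass is supplied for a region, its
#' *self*-dose term is scaled by reference mass / patient mass (the
#' first-order mass correction; cross-fire terms are left untouched).
#'
#' @param rt Tibble with `region` and `residence_h` (normalized cumulated
#'   activities, h), e.g. from [source_residence_times()].
#' @param smat An [s_matrix()].
#' @param patient_masses Optional named vector/list of patient organ masses
#'   in g (e.g. `c(kidneys = 310)`).
#' @return An object of class `organ_dose_result`: list with `doses`
#'   (tibble `target`, `dose_Gy_per_GBq`) and `contributions` (tibble
#'   `target`, `source`, `dose_Gy_per_GBq`); per-target doses equal the sum
#'   of their contributions exactly.
#' @examples
#' rt <- tibble::tibble(region = "kidneys", residence_h = 0.5)
#' sm <- s_matrix(
#'   tibble::tibble(source = "kidneys", target = "kidneys",
#'                  s_value_Gy_per_MBq_h = 1),
#'   tibble::tibble(region = "kidneys", mass_g = 299))
#' tidy(organ_doses(rt, sm)) # 500 Gy/GBq
#' @export
organ_doses <- function(rt, smat, patient_masses = NULL) {
  if (!inherits(smat, "s_matrix")) abort("`smat` must be an `s_matrix`.")
  if (!all(c("region", "residence_h") %in% names(rt))) {
    abort("`rt` needs columns `region` and `residence_h`.")
  }
  if (any(rt$residence_h < 0)) abort("Residence times must be >= 0.")
  unknown <- setdiff(rt$region, smat$sources)
  if (length(unknown)) {
    abort(sprintf("Source region(s) not in the S-value matrix: %s.",
                  paste(unknown, collapse = ", ")))
  }
  pm <- unlist(patient_masses %||% numeric())
  if (length(pm) && (is.null(names(pm)) || any(pm <= 0))) {
    abort("`patient_masses` must be named and positive (g).")
  }

  ref_mass <- setNames(smat$reference_masses$mass_g,
                       smat$reference_masses$region)
  contrib <- smat$values |>
    dplyr::inner_join(rt, by = c(source = "region")) |>
    dplyr::mutate(
      scale = ifelse(
        .data$source == .data$target & .data$target %in% names(pm),
        ref_mass[.data$target] / pm[.data$target], 1),
      dose_Gy_per_GBq = .data$residence_h * .data$s_value_Gy_per_MBq_h *
        .data$scale * 1000
    ) |>
    dplyr::select("target", "source", "dose_Gy_per_GBq")

  doses <- contrib |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(dose_Gy_per_GBq = sum(.data$dose_Gy_per_GBq),
                     .groups = "drop")

  structure(list(doses = doses, contributions = contrib,
                 patient_masses = pm),
            class = "organ_dose_result")
}

#' @export
print.organ_dose_result <- function(x, ...) {
  cat("<organ_dose_result> normalized absorbed doses (Gy/GBq):\n")
  print(x$doses)
  invisible(x)
}

#' @describeIn organ_doses Per-target doses as a tibble.
#' @param x An `organ_dose_result`.
#' @param ... Unused.
#' @method tidy organ_dose_result
#' @export
tidy.organ_dose_result <- function(x, ...) x$doses

#' @describeIn organ_doses One-row summary: number of targets/sources and
#'   total (summed) normalized dose.
#' @method glance organ_dose_result
#' @export
glance.organ_dose_result <- function(x, ...) {
  tibble::tibble(
    n_targets = nrow(x$doses),
    n_sources = length(unique(x$contributions$source)),
    total_dose_Gy_per_GBq = sum(x$doses$dose_Gy_per_GBq)
  )
}

#' Per-source fractions of a target's dose
#'
#' Decomposes one target's absorbed dose into the fractional contribution
#' of each source region (e.g. the share of the red-marrow dose produced by
#' cross-irradiation from the bone surfaces). Fractions sum to 1; for a
#' zero total dose all fractions are reported as 0 with `zero_dose = TRUE`.
#'
#' @param result An `organ_dose_result`.
#' @param target Target region id.
#' @return Tibble with `source`, `fraction`, and attribute-free flag column
#'   `zero_dose`.
#' @export
dose_contributions <- function(result, target) {
  cc <- dplyr::filter(result$contributions, .data$target == !!target)
  if (nrow(cc) == 0) abort(sprintf("Target '%s' not in the result.", target))
  total <- sum(cc$dose_Gy_per_GBq)
  if (total == 0) {
    warn(sprintf("Target '%s' has zero dose; fractions reported as 0.", target))
    return(tibble::tibble(source = cc$source, fraction = 0, zero_dose = TRUE))
  }
  tibble::tibble(source = cc$source,
                 fraction = cc$dose_Gy_per_GBq / total,
                 zero_dose = FALSE)
}

#' Sphere-model absorbed-fraction table
#'
#' The tumor dose model treats each lesion as a sphere of known mass:
#' \eqn{D = \tau \, \Delta \, \phi(m) / m}, where \eqn{\Delta} is the mean
#' (electron) energy emitted per decay expressed in Gy g/(MBq h) and
#' \eqn{\phi(m)} the self-absorbed fraction, interpolated log-log in mass
#' and clamped to the end values outside the tabulated range.
#'
#' @param nodes Tibble/data frame with `mass_g` (increasing) and `phi`
#'   (non-decreasing in mass, within \[0, 1\]).
#' @param delta_Gy_g_per_MBq_h Mean energy per decay, electron component.
#'   The default 0.0853 corresponds to ~148 keV of electron energy per
#'   Lu-177 decay; the small photon component is omitted, as it is for
#'   lesion-scale spheres.
#' @param density_g_mL Tissue density carried as metadata.
#' @return An object of class `sphere_table`.
#' @seealso [default_sphere_table()], [sphere_dose()]
#' @export
sphere_table <- function(nodes, delta_Gy_g_per_MBq_h = 0.0853,
                         density_g_mL = 1.92) {
  nodes <- tibble::as_tibble(nodes)
  if (!all(c("mass_g", "phi") %in% names(nodes))) {
    abort("`nodes` needs columns mass_g and phi.")
  }
  if (is.unsorted(nodes$mass_g, strictly = TRUE)) {
    abort("`mass_g` must be strictly increasing.")
  }
  if (any(nodes$phi < 0 | nodes$phi > 1)) abort("phi must lie in [0, 1].")
  if (is.unsorted(nodes$phi)) {
    abort("phi must be non-decreasing in mass (larger spheres absorb more).")
  }
  if (delta_Gy_g_per_MBq_h <= 0) abort("Delta must be > 0.")
  structure(list(nodes = nodes, delta = delta_Gy_g_per_MBq_h,
                 density_g_mL = density_g_mL),
            class = "sphere_table")
}

#' Packaged illustrative Lu-177 sphere table
#'
#' Synthetic absorbed-fraction nodes for unit-to-bone-density spheres of
#' 0.1--1000 g; illustrative, not a validated kernel (see
#' [default_s_matrix()] for the same caveat).
#'
#' @return A `sphere_table`.
#' @export
default_sphere_table <- function() {
  path <- system.file("extdata", "sphere_phi_lu177_synthetic.csv",
                      package = "zoldose")
  sphere_table(readr::read_csv(path, show_col_types = FALSE))
}

# log-log interpolation of phi at the query mass, clamped to end values.
sphere_phi <- function(table, mass_g) {
  nodes <- table$nodes
  if (mass_g <= nodes$mass_g[1]) return(nodes$phi[1])
  if (mass_g >= nodes$mass_g[nrow(nodes)]) return(nodes$phi[nrow(nodes)])
  exp(stats::approx(log(nodes$mass_g), log(nodes$phi), xout = log(mass_g))$y)
}

#' Sphere-model tumor dose
#'
#' @param tumor_rt Lesion residence time (normalized cumulated activity), h.
#' @param tumor_mass Lesion mass, g, `> 0`.
#' @param table A [sphere_table()].
#' @return Normalized lesion dose, Gy/GBq.
#' @examples
#' tab <- sphere_table(tibble::tibble(mass_g = c(1, 100), phi = c(0.9, 0.99)))
#' sphere_dose(1, 10, tab)
#' @export
sphere_dose <- function(tumor_rt, tumor_mass, table = default_sphere_table()) {
  if (any(tumor_mass <= 0)) abort("`tumor_mass` must be > 0 g.")
  if (any(tumor_rt < 0)) abort("`tumor_rt` must be >= 0 h.")
  phi <- vapply(tumor_mass, function(m) sphere_phi(table, m), numeric(1))
  tumor_rt * table$delta * phi / tumor_mass * 1000
}

#' Default tissue weighting factors
#'
#' A partial ICRP-style weighting set covering the targets of the packaged
#' S-value matrix (red marrow 0.12, bone surfaces 0.01, bladder wall 0.04,
#' kidneys as a remainder-bucket share 0.0092). Weights over the provided
#' targets may sum to less than 1; uncovered tissues simply contribute
#' nothing, so the effective dose computed with this set is a partial-body
#' quantity.
#'
#' @return Named numeric vector of weights.
#' @export
default_tissue_weights <- function() {
  c(red_marrow = 0.12, bone_surfaces = 0.01, bladder_wall = 0.04,
    kidneys = 0.0092)
}

#' Effective dose from equivalent organ doses
#'
#' Tissue-weighted sum \eqn{E = \sum_T w_T H_T}. For beta/gamma emitters
#' the radiation weighting factor is 1, so equivalent doses in mSv/MBq are
#' numerically the normalized absorbed doses in Gy/GBq.
#'
#' @param equivalent_doses Named numeric vector (or tibble with `target`,
#'   `dose`) of equivalent doses, mSv/MBq.
#' @param weights Named numeric vector of tissue weighting factors; must be
#'   non-negative and sum to at most 1 over the provided targets.
#' @return Effective dose, mSv/MBq.
#' @examples
#' effective_dose(c(A = 1, B = 2), c(A = 0.12, B = 0.05)) # 0.22
#' @export
effective_dose <- function(equivalent_doses, weights = default_tissue_weights()) {
  if (is.data.frame(equivalent_doses)) {
    equivalent_doses <- setNames(equivalent_doses[[2]], equivalent_doses[[1]])
  }
  if (any(weights < 0)) abort("Tissue weights must be >= 0.")
  common <- intersect(names(equivalent_doses), names(weights))
  if (sum(weights[common]) > 1 + 1e-12) {
    abort("Tissue weights over the provided targets must sum to <= 1.")
  }
  sum(weights[common] * equivalent_doses[common])
}
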