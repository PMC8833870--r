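---
title: "Methods: MIRD dosimetry for a bone-seeking Lu-177 radiopharmaceutical"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MIRD dosimetry for a bone-seeking Lu-177 radiopharmaceutical}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zoldose)
```

## The problem

Radiolabelled bisphosphonates such as ¹⁷⁷Lu-DOTA-zoledronate bind avidly to
the bone mineral surface, which makes them attractive for treating
osteoblastic skeletal metastases — and makes the red bone marrow, sitting
inside the trabecular bone, the organ at risk. Treatment planning therefore
needs, per patient: the absorbed dose per unit injected activity for the
marrow, the kidneys and the bone surfaces; the absorbed dose to each tumor
lesion; the largest injectable activity that keeps every organ under its
tolerated dose; and tumor-to-organ dose ratios (therapeutic indices).

`zoldose` implements this pipeline in the MIRD schema:

1. **Kinetics** — fit measured time–activity curves (TACs) with constrained
   sums of exponentials and integrate them analytically from 0 to ∞ to get
   cumulated activities (MBq·h), then residence times (h) by dividing by
   the injected activity.
2. **Source mapping** — convert raw measurements to the six MIRD source
   regions: cortical and trabecular bone mineral surface (80%/20% split of
   skeletal activity), red marrow (from blood), kidneys, urinary bladder
   content, remainder of body.
3. **Dose engine** — organ doses $D(t) = \sum_s \tau_s\, S(t \leftarrow s)$
   from a configurable S-value matrix, with patient-specific self-dose mass
   scaling; lesion doses from a sphere model
   $D = \tau\, \Delta\, \phi(m) / m$.
4. **Safety planning** — per-organ maximum tolerated activity
   $\mathrm{MTA}_o = L_o / D_o$ under limits of 2 Gy (red marrow), 23 Gy
   (kidneys) and 10 Gy (bone surfaces); the planning MTA is the minimum,
   and the organ attaining it is dose-limiting.

A synthetic-patient generator with closed-form ground truth stands in for
clinical SPECT/blood data, which is not publicly available.

## Curve fitting

Measured curves are *not* corrected for physical decay, so the fitted model
$A(t) = \sum_i A_i e^{-\lambda_i t}$ integrates directly to the cumulated
activity $\sum_i A_i/\lambda_i$. Constraints encode the physics:

* every rate satisfies $\lambda_i \ge \lambda_{\mathrm{phys}}(1-10^{-3})$
  (biological clearance cannot be negative; `lu177_constants()` uses the
  standard half-life of 6.647 d, configurable for groups that round to
  6.7 d);
* at most one amplitude may be negative — a fast uptake term, so the model
  can be evaluated from $t = 0$ even though the first image is at 1.5 h;
* the model must be non-negative on a grid covering twice the sampled
  interval, and the slowest term's amplitude must be positive (the tail
  cannot go negative);
* adjacent rates must differ by at least a factor 1.3 and amplitudes are
  capped at 5× the curve maximum. These two are identifiability guards: on
  a 5-point schedule, pairs of near-equal rates with huge cancelling
  amplitudes (or a fast term that "spikes" inside the unobserved 0–1.5 h
  window) can fit the samples essentially perfectly while integrating to
  arbitrary values. Legitimate shapes in this domain stay below ~3.5× the
  observed maximum, so the cap costs nothing.

Amplitudes enter linearly, so they are profiled out by weighted linear
least squares (variable projection); only the rates are searched, on a
deterministic log-spaced multi-start grid refined by Nelder–Mead. The
constraints are enforced *inside* the objective (as a penalty), not only on
the final candidates — otherwise the refinement drifts into the degenerate
basins described above. There is no random state anywhere in the fit:
identical inputs give bit-identical models.

**Weighting.** The default is relative weighting ($w_i = 1/y_i^2$), the
maximum-likelihood choice under multiplicative lognormal measurement error
— the appropriate model for SPECT and well-counter data, whose errors are
roughly proportional. This matters: blood curves span five decades, and
under unweighted least squares the slow phase — which carries about half of
the marrow integral — is statistically invisible (we measured median
integral errors of ~40% at 5% noise). Unweighted (`"none"`) and `1/y`
(`"inverse"`) options are available. Weighting values are floored at
$10^{-4}$ of the curve maximum: no gamma counter resolves four decades
below peak, and unbounded weights on near-zero tail samples destroy the
conditioning of the weighted solve.

**Model selection.** Candidates with 1 and 2 terms (3 with at least 7
samples; free parameters never exceed samples) are compared with a
small-sample-corrected information criterion,
$n\log(\mathrm{RSS}/n) + 2p + 2p(p+1)/\max(n-p-1, 1)$. The flooring of the
correction denominator is deliberate: textbook AICc is undefined for a
2-term model at $n = 5$, yet the 5-point imaging schedule must support
biexponential fits; with the floor, the richer model is only selected on a
decisive RSS improvement. The RSS itself is floored at the square of
$10^{-9}\times$ the data scale so that, among models that all fit to
machine precision, the most parsimonious wins.

**Degenerate inputs.** An all-zero curve returns the zero model with a
warning flag and integrates to 0. If no feasible model exists at all, the
fit sets a fallback flag and `cumulated_activity()` switches to the
`"hybrid"` rule: linear rise from $(0,0)$ to the first sample, trapezoid
across the samples, physical-decay tail $A_{\mathrm{last}}/\lambda_{\mathrm{phys}}$
from the last sample.

## Source-organ construction

* **Red marrow**: $A_{rm} = AC_{blood} \times \mathrm{RMBLR} \times 1500\,\mathrm{g}/1.05\,\mathrm{g\,mL^{-1}}$,
  with the conservative RMBLR of 1.0 by default (0.36 is used by some
  groups; `rmblr_sensitivity()` quantifies the consequence). The marrow
  residence time is fitted on the 8-point *blood* schedule — the 5-minute
  sample is what makes the fast blood phase identifiable; by the first
  image at 1.5 h it has completely cleared, and a marrow curve interpolated
  onto the imaging grid would understate the integral by ~18%. The
  imaging-grid marrow values are used only for the remainder subtraction.
* **Leg scaling**: torso-limited fields of view miss the legs (33.6% of
  bone mass), so skeleton and total-body values are multiplied by
  $1/0.664 = 1.506$. Only these two regions are scaled.
* **Skeleton partition**: skeletal cumulated activity is split 80%/20%
  onto the cortical and trabecular bone mineral surfaces, where
  bisphosphonates bind.
* **Remainder**: leg-scaled total body minus the other sources, pointwise
  on the imaging grid, clamped at zero with logged clamp events
  (segmentation noise can make sources exceed the total). Interpolation
  onto the grid is linear — five points cannot support anything stiffer.
* **Lesions**: activity = mean concentration × volume; mass = volume ×
  1.92 g/mL (cortical-bone density, appropriate for mineralized
  osteoblastic lesions); kidney mass = CT volume × 1.06 g/mL, used to
  scale the kidney self-dose. Lesion activity is excluded from the skeleton
  by segmentation; `tumors_in_bone = TRUE` adds it back, which bounds the
  extra marrow cross-dose from bone-adjacent lesions (the remainder is
  computed after this choice, and with zero lesion uptake both settings
  coincide exactly).
* **Bladder content** is integrated like any other region; no voiding
  model is applied (none is identifiable from five images).

## Dose engine

S-values are **configuration, not code**: the commercial engines used in
clinical work embed phantom kernels that this package does not attempt to
reproduce. The packaged matrix (`default_s_matrix()`) is an illustrative
synthetic one — built from the Lu-177 electron energy per decay
($\Delta = 0.0853$ Gy·g/(MBq·h), ≈148 keV/decay) and round-number absorbed
fractions — so that the pipeline runs offline with clinically plausible
magnitudes. It is labelled as such in its filename, provenance string and
documentation, and absolute doses computed from it are never compared
against published patient values. Swapping in a real phantom matrix via
`read_s_matrix()` changes doses linearly and nothing else.

Patient mass overrides scale the *self*-dose term by reference/patient
mass — the standard first-order correction; cross-fire terms are
geometry-dominated and left untouched. Equivalent dose equals absorbed
dose (radiation weighting factor 1 for β/γ), so Gy/GBq and mSv/MBq align
numerically before tissue weighting; the packaged tissue-weight set is
partial (marrow 0.12, bone surfaces 0.01, bladder 0.04, kidneys 0.0092),
making the effective dose a partial-body quantity. The sphere model
interpolates the absorbed fraction log-log in mass and omits the photon
component by default — for lesion-sized spheres of a medium-energy β
emitter the electron term dominates.

## The synthetic generator

Each compartment follows an uptake–washout form
$A(t) = A_{inj}\, f\, (1-e^{-k_u t})\, e^{-(\lambda_{phys}+k_b) t}$;
blood is biexponential times physical decay; a soft-tissue pool holding
the full injection at $t=0$ drains with fast and slow components
(implicitly feeding bone uptake and urinary excretion); lesions share the
uptake–washout form as concentrations. Defaults were back-solved once,
analytically, from the published biodistribution magnitudes for this
compound class and then frozen:

* skeleton: peak ≈ 9.6×10⁻³ %IA/g (5500 g bone) at ~2 h and ≈3.5×10⁻³ at
  170 h give an effective decay of 0.0060 h⁻¹, hence biological loss
  $k_b = 0.00166$ h⁻¹, uptake $k_u = 3.1$ h⁻¹ (peak position), and uptake
  fraction $f_s = 0.535$ — about half the injection, typical for a
  bisphosphonate in extensive metastatic disease;
* blood: marrow ≈1.4×10⁻³ %IA/g at 1.5 h and ≈9.7×10⁻⁵ at 24 h give
  $b_1 = 1.6\times10^{-4}$/mL at $k_1 = 2.0$ h⁻¹ and
  $b_2 = 7.8\times10^{-6}$/mL at $k_2 = 0.08$ h⁻¹ (≈71% of the injection
  in a 5 L blood pool at 5 min, clearing fast);
* lesions: ≈2.1×10⁻² %IA/g at 6 h and ≈1×10⁻² at 170 h imply negligible
  biological washout ($k_b \sim 3\times10^{-4}$ h⁻¹) and concentration
  scale ≈4.2×10⁻⁴ mL⁻¹ per injected MBq;
* kidneys: low uptake ($f = 0.02$) with fast clearance for the typical
  patient; a `high_kidney` preset ($f = 0.12$, slow clearance) mimics the
  minority with visible renal retention;
* injected activity: Normal(5780, 329) MBq truncated positive.

Noise is multiplicative lognormal, mean-corrected
($\exp(\sigma Z - \sigma^2/2)$, expectation exactly 1), applied per
sample; σ defaults to 0.05. Sampling uses the nominal protocol times (five
images at 1.5/6/24/48/170 h, eight blood samples from 5 min to 170 h);
jitter within the protocol windows is available but off by default for
reproducibility. Cohorts jitter the kinetic parameters lognormally (15% CV
by default) with per-patient seeds derived deterministically from a master
seed.

**What the generator does *not* emulate**: partial-volume and
reconstruction effects, coregistration error, additive counting noise on
late blood samples, voiding, and inter-lesion heterogeneity beyond rate
jitter. Passing recovery tests therefore demonstrates that the estimation
chain is correct and stable under realistic *multiplicative* noise at the
study's sampling schedules — not that clinical accuracy of any particular
magnitude is guaranteed on real images.

**Accuracy claims.** With σ = 0, every region whose true kinetics are one
or two exponentials (skeleton, kidneys, bladder, blood/marrow, lesions)
recovers its cumulated activity to better than 10⁻⁶ relative; the
remainder region is a four-exponential composite minus the marrow curve,
which a two-term model cannot represent on five samples, and recovers to
within 10% (observed ≈7%). With σ = 0.05, median recovery errors over 200
seeded replicates are ≈3% (skeleton) and ≈1% (marrow), bounded at 10% in
the tests. These replicate counts, and the 8-patient demonstration cohort,
are the problem sizes used throughout the test-suite and documentation.

## Planning conventions

* Cohort tables report the median (midpoint rule), mean, and **population**
  SD (denominator $n$) — the convention that matches published clinical
  dosimetry tables of this kind; sample SD is available by option.
* Report tables round half away from zero: one decimal for GBq, three for
  Gy/GBq. (Planning arithmetic itself is never rounded.)
* Organs with zero dose would tolerate unlimited activity; they are
  excluded from the MTA minimum with a warning, never silently reported as
  infinite. MTA ties break in the fixed order red marrow, kidneys, bone
  surfaces.
* Therapeutic indices are reported for every limited organ with positive
  dose; in practice the kidney index is ignored clinically when the kidney
  dose is negligible.

## A worked cohort

```{r, eval = FALSE}
cohort <- generate_cohort(8, master_seed = 20, noise_sigma = 0.05)
report <- run_pipeline(lapply(cohort, `[[`, "bundle"))
report$organ_table
report$plan_summary
write_cohort_report(report, "report")
```

With the packaged illustrative S matrix this yields marrow doses around
0.35–0.48 Gy/GBq, bone-surface doses around 2 Gy/GBq, MTAs of roughly 4–6
GBq, and the red marrow as the limiting organ for every patient — the
qualitative clinical picture for this compound class. The published cohort
tables themselves (`zol_reference_doses()`, `zol_reference_tumor_doses()`)
are used to exercise the planning arithmetic end-to-end against printed
values.

## Known limitations

* The packaged S matrix and sphere table are synthetic illustrations;
  absolute organ doses from the default configuration are not clinically
  validated numbers.
* `max_terms` is capped at 3 and requires 7 samples; richer kinetics
  (e.g. enterohepatic recirculation) are out of scope.
* The marrow model assumes a spatially uniform RMBLR; lesion-infiltrated
  marrow violates it.
* The remainder region inherits every upstream segmentation error and its
  recovery bound is accordingly looser (10%).
* No biologically effective dose, multi-cycle scheduling, or
  tumor-control modelling.
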