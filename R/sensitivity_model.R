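#' Point-wise sensitivity model
#'
#' The linear structure/function model that generates (and is recovered from)
#' point-wise sensitivity: a fixed-effect linear predictor over topographic
#' biomarkers plus a Gaussian random intercept per patient and Gaussian
#' residual noise,
#'
#' PWS = b0 + b_dev 1(MAIA) + b_run 1(run 2) + b_age age
#'       + (b_onl + R b_onl_ecc) ONL + (b_ez + R b_ez_ecc) EZ
#'       + b_drusen drusen + b_hrf HRF + b_sdd SDD + u_patient + e
#'
#' with R the stimulus eccentricity in degrees, thicknesses in um and deposit
#' volumes in nl. Defaults are the published final-model estimates where an
#' estimate exists and 0 otherwise (age and run were selected out; SDD was
#' excluded from the final multivariable model). The intercept (21 dB) and
#' the variance components (random-intercept SD 1.7 dB, residual SD 2.4 dB)
#' are calibration choices made once so that the default synthetic cohort
#' reproduces the published device means and marginal R-squared.
#'
#' @param intercept Baseline sensitivity in dB for MP-3, run 1, all
#'   biomarkers zero.
#' @param device_offset dB shift of MAIA relative to MP-3 (-3.553).
#' @param run_offset dB shift of run 2 relative to run 1.
#' @param age_slope dB per year of age.
#' @param drusen,hrf,sdd Volume effects in dB/nl.
#' @param onl,ez Thickness effects at 0 degrees eccentricity in dB/um.
#' @param onl_ecc,ez_ecc Thickness-by-eccentricity interactions in
#'   dB/um/degree.
#' @param random_intercept_sd,residual_sd Variance components in dB.
#' @return A `sensitivity_model` list of coefficients.
#' @export
sensitivity_model <- function(intercept = 21,
                              device_offset = -3.553,
                              run_offset = 0,
                              age_slope = 0,
                              drusen = -0.632,
                              hrf = -9.535,
                              sdd = 0,
                              onl = 0.016,
                              ez = 0.148,
                              onl_ecc = 0.008,
                              ez_ecc = -0.025,
                              random_intercept_sd = 1.7,
                              residual_sd = 2.4) {
  assert_that(random_intercept_sd >= 0 && residual_sd >= 0,
              "variance components must be >= 0")
  structure(list(
    intercept = intercept, device_offset = device_offset,
    run_offset = run_offset, age_slope = age_slope,
    drusen = drusen, hrf = hrf, sdd = sdd,
    onl = onl, ez = ez, onl_ecc = onl_ecc, ez_ecc = ez_ecc,
    random_intercept_sd = random_intercept_sd, residual_sd = residual_sd
  ), class = "sensitivity_model")
}

#' True (noise-free) threshold at a stimulus
#'
#' Evaluates the fixed-effect linear predictor of a [sensitivity_model()] at
#' one stimulus given its quantified biomarker features, plus an optional
#' patient random effect. This is the ground-truth threshold that the
#' staircase procedure estimates.
#'
#' @param features A list or one-row data frame with `ecc_deg`, `onl_um`,
#'   `ez_um`, `drusen_nl`, `hrf_nl`, `sdd_nl` (missing entries count as 0).
#' @param model A [sensitivity_model()].
#' @param device `"MP3"` or `"MAIA"`.
#' @param run Run index, 1 or 2.
#' @param age Patient age in years (only matters if `age_slope != 0`).
#' @param patient_effect Patient-level random intercept in dB.
#' @return Threshold in dB (unclamped; may exceed the device range).
#' @export
true_threshold <- function(features, model, device = "MP3", run = 1,
                           age = 0, patient_effect = 0) {
  device <- match.arg(device, c("MP3", "MAIA"))
  f <- function(name) {
    v <- features[[name]]
    if (is.null(v) || length(v) == 0 || is.na(v[1])) 0 else as.numeric(v[1])
  }
  r <- f("ecc_deg")
  model$intercept +
    model$device_offset * (device == "MAIA") +
    model$run_offset * (run == 2) +
    model$age_slope * age +
    (model$onl + r * model$onl_ecc) * f("onl_um") +
    (model$ez + r * model$ez_ecc) * f("ez_um") +
    model$drusen * f("drusen_nl") +
    model$hrf * f("hrf_nl") +
    model$sdd * f("sdd_nl") +
    patient_effect
}

## vectorized linear predictor over an analysis table (used by the cohort
## simulator); `patient_effect` recycled per row
threshold_linear_predictor <- function(tab, model) {
  r <- tab$ecc_deg %||% tab$eccentricity_deg
  model$intercept +
    model$device_offset * (tab$device == "MAIA") +
    model$run_offset * (tab$run == 2) +
    model$age_slope * (tab$age %||% 0) +
    (model$onl + r * model$onl_ecc) * tab$onl_um +
    (model$ez + r * model$ez_ecc) * tab$ez_um +
    model$drusen * tab$drusen_nl +
    model$hrf * tab$hrf_nl +
    model$sdd * tab$sdd_nl
}
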