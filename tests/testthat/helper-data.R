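# lightweight synthetic analysis tables for the stats-module tests: features
# drawn from simple distributions (no image pipeline), outcome from a known
# random-intercept linear model

make_lmm_table <- function(n_patients = 8, n_per = 40, seed = 1,
                           model = sensitivity_model(),
                           sd_u = model$random_intercept_sd,
                           sd_e = model$residual_sd) {
  octmp:::with_seed(seed, {
    rows <- lapply(seq_len(n_patients), function(p) {
      u <- rnorm(1, 0, sd_u)
      ecc <- sample(c(0, 1.5, 2.5, 5.2), n_per, replace = TRUE)
      tab <- data.frame(
        patient_id = p, device = sample(c("MP3", "MAIA"), n_per, TRUE),
        run = sample(1:2, n_per, TRUE), point_id = seq_len(n_per),
        eccentricity_deg = ecc, age = rnorm(1, 76, 7),
        ez_um = pmax(0, rnorm(n_per, 29, 7)),
        onl_um = pmax(0, 89 - 8 * ecc + rnorm(n_per, 0, 12)),
        drusen_nl = ifelse(runif(n_per) < 0.4, rexp(n_per, 1 / 0.3), 0),
        sdd_nl = ifelse(runif(n_per) < 0.25, rexp(n_per, 1 / 0.3), 0),
        hrf_nl = ifelse(runif(n_per) < 0.05, rexp(n_per, 1 / 0.1), 0),
        included = TRUE
      )
      tab$pws_db <- octmp:::threshold_linear_predictor(tab, model) + u +
        rnorm(n_per, 0, sd_e)
      tab
    })
    do.call(rbind, rows)
  })
}

# a tiny deterministic geometry for exactness tests: 11 x 11 pixels at
# isotropic 10 um spacing, fovea at the centre
tiny_geometry <- function(n = 11, spacing = 10) {
  oct_geometry(n_bscans = n, n_ascans = n, field_deg = (n - 1) * spacing / 288,
               um_per_deg = 288)
}
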