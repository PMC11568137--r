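#' Default run configuration
#'
#' The full stated world of a pipeline run in one serializable list:
#' cohort size, seed, sensitivity mode, geometry, grid layout, phenotype,
#' model coefficients, observer, quantification settings, registration
#' route and model-selection toggle.
#'
#' @return A nested list (all values YAML-serializable).
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    n_patients = 20,
    mode = "direct", # or "psychophysical"
    registration = "oracle", # "oracle" = hidden true transforms, or "image"
    export_maps = FALSE,
    geometry = list(n_bscans = 97, n_ascans = 512, field_deg = 20,
                    um_per_deg = 288),
    grid = default_grid_layout(),
    phenotype = list(preset = "default"),
    model = as.list(unclass(sensitivity_model())),
    observer = list(sigma_psy = 1, false_positive_rate = 0.03,
                    false_negative_rate = 0.03),
    quantify = list(radius_um = 70, hrf_threshold_nl = 0.06,
                    maia_floor_adjust = TRUE),
    selection = list(enabled = FALSE)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML config, fills unset keys with defaults and rejects unknown
#' keys. An empty file yields the full default configuration.
#'
#' @param path Path to a YAML file.
#' @return A validated config list.
#' @export
load_config <- function(path) {
  assert_that(file.exists(path), "config file not found: ", path,
              class = "octmp_config_error")
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  validate_config(user)
}

#' @rdname load_config
#' @param config A (possibly partial) config list.
#' @export
validate_config <- function(config = list()) {
  defaults <- default_run_config()
  bad <- setdiff(names(config), names(defaults))
  assert_that(length(bad) == 0, "unknown config keys: ",
              paste(bad, collapse = ", "), class = "octmp_config_error")
  for (sub in c("geometry", "grid", "phenotype", "model", "observer",
                "quantify", "selection")) {
    if (!is.null(config[[sub]])) {
      extra <- setdiff(names(config[[sub]]),
                       unique(c(names(defaults[[sub]]),
                                if (sub == "phenotype") names(phenotype_config()))))
      assert_that(length(extra) == 0, "unknown config keys in ", sub, ": ",
                  paste(extra, collapse = ", "), class = "octmp_config_error")
    }
  }
  cfg <- modifyList(defaults, config)
  assert_that(cfg$n_patients >= 1, "n_patients must be >= 1",
              class = "octmp_config_error")
  assert_that(cfg$mode %in% c("direct", "psychophysical"),
              "mode must be 'direct' or 'psychophysical'",
              class = "octmp_config_error")
  assert_that(cfg$registration %in% c("oracle", "image"),
              "registration must be 'oracle' or 'image'",
              class = "octmp_config_error")
  assert_that(cfg$quantify$radius_um > 0, "quantify$radius_um must be > 0",
              class = "octmp_config_error")
  assert_that(cfg$quantify$hrf_threshold_nl >= 0,
              "quantify$hrf_threshold_nl must be >= 0",
              class = "octmp_config_error")
  cfg
}

#' Save a configuration as YAML
#' @param config A config list.
#' @param path Output path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_objects <- function(cfg) {
  list(
    geometry = oct_geometry(cfg$geometry$n_bscans, cfg$geometry$n_ascans,
                            cfg$geometry$field_deg, cfg$geometry$um_per_deg),
    grid = build_stimulus_grid(cfg$grid),
    phenotype = do.call(phenotype_config,
                        c(list(preset = cfg$phenotype$preset %||% "default"),
                          cfg$phenotype[setdiff(names(cfg$phenotype), "preset")])),
    model = do.call(sensitivity_model, cfg$model),
    observer = do.call(observer_model, cfg$observer),
    quantify = do.call(quant_config, cfg$quantify)
  )
}

#' Run the full pipeline
#'
#' Simulate -> register -> quantify -> analyze, writing all artifacts to a
#' run directory: per-acquisition device exports, registration JSONs, the
#' long analysis CSV, model coefficient tables (CSV + JSON) and a manifest
#' capturing the configuration. Fully deterministic for a fixed config;
#' rerunning reproduces byte-identical analysis output.
#'
#' @param config A config list (see [default_run_config()] /
#'   [load_config()]).
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the `table`, final `fit`, registration
#'   summary and `out_dir`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempfile("octmp_run_")) {
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_octmp("stage '", name, "' failed: ", conditionMessage(e),
                 class = "octmp_stage_error")
    })
  }

  obj <- stage("simulate", config_objects(cfg))
  cohort <- stage("simulate", {
    simulate_cohort(cfg$n_patients, cfg$seed, obj$geometry, obj$grid,
                    obj$phenotype, obj$model, obj$observer, mode = cfg$mode,
                    render_fundus = cfg$registration == "image")
  })
  stage("simulate", {
    for (pat in cohort$patients) {
      if (cfg$export_maps) {
        export_eye_maps(pat$eye$maps,
                        file.path(out_dir, "exports",
                                  sprintf("patient%02d", pat$patient_id), "oct"))
      }
      for (acq in pat$acquisitions) {
        export_acquisition(acq, file.path(
          out_dir, "exports", sprintf("patient%02d", pat$patient_id),
          sprintf("%s_run%d", acq$device, acq$run)))
      }
    }
  })

  registrations <- stage("register", {
    if (cfg$registration == "oracle") NULL else {
      lapply(cohort$patients, function(pat) {
        lapply(seq_along(pat$acquisitions), function(ai) {
          acq <- pat$acquisitions[[ai]]
          reg <- register_acquisition(
            acq$fundus$device, acq$fundus$nir,
            seed = derive_seed(cfg$seed, "reg", pat$patient_id, ai))
          registration_to_json(reg, file.path(
            out_dir, "exports", sprintf("patient%02d", pat$patient_id),
            sprintf("%s_run%d", acq$device, acq$run), "registration.json"))
          reg
        })
      })
    }
  })

  tab <- stage("quantify", {
    t0 <- assemble_table(cohort, registrations, obj$quantify)
    write_analysis_table(t0, file.path(out_dir, "analysis.csv"))
    t0
  })

  fit <- stage("analyze", {
    spec <- final_model_spec("REML")
    if (isTRUE(cfg$selection$enabled)) {
      cand <- enumerate_candidates(model_spec(
        c("device", "onl", "ez", "ecc", "drusen", "hrf"),
        list(c("ecc", "onl"), c("ecc", "ez"))))
      sel <- select_by_bic(tab, cand)
      write.csv(sel$ranking, file.path(out_dir, "candidate_ranking.csv"),
                row.names = FALSE)
      sel$best_fit
    } else {
      fit_lmm(tab, spec)
    }
  })
  stage("analyze", {
    write.csv(fit$coefficients, file.path(out_dir, "model_coefficients.csv"),
              row.names = FALSE)
    jsonlite::write_json(list(
      coefficients = fit$coefficients, varcomp = as.list(fit$varcomp),
      logLik = fit$logLik, bic = fit$bic, n_obs = fit$n_obs,
      marginal_r2 = fit$marginal_r2
    ), file.path(out_dir, "model_fit.json"), auto_unbox = TRUE, digits = NA)
    write.csv(descriptive_summary(tab), file.path(out_dir, "summary.csv"),
              row.names = FALSE)
  })

  jsonlite::write_json(list(
    package_version = as.character(utils::packageVersion("octmp")),
    r_version = R.version.string,
    config = cfg
  ), file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(table = tab, fit = fit, registrations = registrations,
                 out_dir = out_dir))
}
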