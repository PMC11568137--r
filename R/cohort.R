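#' Simulate a study cohort
#'
#' Generates `n_patients` synthetic eyes and, for each, four microperimetry
#' acquisitions: two consecutive runs on each of two devices (MP-3 photopic,
#' MAIA mesopic), device order randomized per patient, run 2 reusing the
#' identical stimulus grid (the device "follow-up" function). Each
#' acquisition carries its own hidden device-to-OCT similarity transform
#' (ground truth for registration); the stimulus pixel coordinates exported
#' by the device are the grid positions pushed through the inverse of that
#' transform.
#'
#' Two sensitivity modes are supported. `"direct"` draws each point-wise
#' sensitivity from the linear structure/function model plus the patient
#' random intercept and Gaussian residual noise (the mode used by the
#' statistical estimator checks). `"psychophysical"` instead runs the full
#' 4-2 staircase against the observer model, adding the staircase's 2 dB
#' quantization. In both modes raw values below the floor are recorded as 0
#' (MP-3) or -1 (MAIA raw; adjusted downstream).
#'
#' @param n_patients Number of patients (one eye each, >= 1).
#' @param seed Master seed; every stream below is derived from it.
#' @param geometry,grid,phenotype,model See the respective constructors.
#' @param observer Observer model for `"psychophysical"` mode.
#' @param mode `"direct"` or `"psychophysical"`.
#' @param render_fundus Also render the fundus image pair per acquisition
#'   (needed for image-based registration; off by default for speed).
#' @param mean_age,sd_age Patient age distribution (76 +/- 7 years).
#' @return A `cohort` list: `patients` (each with `patient_id`, `age`,
#'   `patient_effect`, `eye`, `acquisitions` of 4 records) plus the
#'   generating configuration.
#' @export
simulate_cohort <- function(n_patients = 20, seed = 1,
                            geometry = oct_geometry(),
                            grid = build_stimulus_grid(),
                            phenotype = phenotype_config(),
                            model = sensitivity_model(),
                            observer = observer_model(),
                            mode = c("direct", "psychophysical"),
                            render_fundus = FALSE,
                            mean_age = 76, sd_age = 7) {
  mode <- match.arg(mode)
  assert_that(n_patients >= 1, "need n_patients >= 1")
  patients <- vector("list", n_patients)
  for (p in seq_len(n_patients)) {
    eye <- generate_eye(derive_seed(seed, "eye", p), geometry, phenotype)
    patients[[p]] <- with_seed(derive_seed(seed, "patient", p), {
      age <- rnorm(1, mean_age, sd_age)
      u <- rnorm(1, 0, model$random_intercept_sd)
      devices <- sample(c("MP3", "MAIA")) # randomized device order
      ## ground-truth features at the true grid positions (shared by all
      ## four acquisitions: the follow-up reuses the identical grid)
      pts_um <- grid_points_um(grid, geometry)
      feats <- lapply(seq_len(grid$n_points), function(k) {
        point_features(eye$maps, pts_um[k, ], eye$fovea_xy_um)
      })
      acqs <- list()
      for (device in devices) for (run in 1:2) {
        tf <- random_device_transform(device, geometry)
        pts_px <- apply_transform(invert_transform(tf), pts_um)
        cfg <- staircase_config(device)
        raw <- vapply(seq_len(grid$n_points), function(k) {
          thr <- true_threshold(feats[[k]], model, device = device, run = run,
                                age = age, patient_effect = u)
          if (mode == "direct") {
            v <- thr + rnorm(1, 0, model$residual_sd)
            if (v < 0) cfg$raw_floor else min(v, cfg$range_db[2])
          } else {
            run_staircase(thr, observer, cfg)$estimate_db
          }
        }, numeric(1))
        rec <- list(
          patient_id = p, eye_side = "OD", device = device, run = run,
          points = data.frame(point_id = grid$points$point_id,
                              x_px = pts_px[, 1], y_px = pts_px[, 2],
                              sensitivity_db = raw),
          true_transform = tf
        )
        if (render_fundus) {
          rec$fundus <- render_fundus_images(eye$vessel_tree, geometry,
                                             device = device,
                                             true_transform = tf)
        }
        acqs[[length(acqs) + 1L]] <- rec
      }
      list(patient_id = p, age = age, patient_effect = u, eye = eye,
           acquisitions = acqs)
    })
  }
  structure(list(patients = patients, seed = seed, mode = mode,
                 geometry = geometry, grid = grid, phenotype = phenotype,
                 model = model, observer = observer),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n <- length(x$patients)
  cat(sprintf("<cohort> %d patients, %d stimuli x 4 acquisitions = %d PWS values (%s mode)\n",
              n, x$grid$n_points, n * x$grid$n_points * 4, x$mode))
  invisible(x)
}

## hidden ground-truth transform: device pixels -> en-face micrometres.
## Scales correspond to realistic fundus pixel sizes; the translation keeps
## the fovea near the device image centre with a small per-acquisition
## offset (follow-up / eye-tracking jitter).
random_device_transform <- function(device, geometry,
                                    device_px = 320) {
  base_scale <- if (device == "MAIA") 16 else 18 # um per device pixel
  s <- base_scale * runif(1, 0.98, 1.02)
  th <- rnorm(1, 0, 2 * pi / 180)
  ctr_px <- c(device_px / 2, device_px / 2) + rnorm(2, 0, 5)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tr <- geometry$fovea_xy_um - s * as.numeric(R %*% ctr_px)
  similarity_transform(s, th, tr)
}

#' Export one acquisition to a run directory
#'
#' Writes the device-export layout: `points.csv` (`point_id,x_px,y_px,
#' sensitivity_db`, one row per stimulus, raw dB values — a raw MAIA -1 is
#' stored as -1; the range adjustment happens at quantification),
#' `meta.json`, and when fundus images are attached `fundus_device.png` /
#' `fundus_nir.png` (8-bit grayscale).
#'
#' @param record One acquisition record from [simulate_cohort()].
#' @param out_dir Writable output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
export_acquisition <- function(record, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(record$points[, c("point_id", "x_px", "y_px", "sensitivity_db")],
            file.path(out_dir, "points.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    patient_id = record$patient_id, eye_side = record$eye_side,
    device = record$device, run = record$run
  ), file.path(out_dir, "meta.json"), auto_unbox = TRUE)
  if (!is.null(record$fundus)) {
    write_gray_png(record$fundus$device, file.path(out_dir, "fundus_device.png"))
    write_gray_png(record$fundus$nir, file.path(out_dir, "fundus_nir.png"))
  }
  invisible(out_dir)
}

#' Re-import an exported acquisition
#' @param dir Directory written by [export_acquisition()].
#' @return An acquisition record (without the hidden true transform).
#' @export
read_acquisition <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  rec <- list(patient_id = meta$patient_id, eye_side = meta$eye_side,
              device = meta$device, run = meta$run,
              points = read.csv(file.path(dir, "points.csv")))
  for (nm in c("device", "nir")) {
    f <- file.path(dir, paste0("fundus_", nm, ".png"))
    if (file.exists(f)) rec$fundus[[nm]] <- read_gray_png(f)
  }
  rec
}

#' Export per-eye en-face biomarker maps as a CSV bundle
#'
#' One CSV per map (row = B-scan, column = A-scan), an `hrf_components.csv`
#' voxel table and a `geometry.json`; the layout round-trips through
#' [read_eye_maps()].
#'
#' @param maps `biomarker_maps` from [generate_eye()].
#' @param out_dir Output directory.
#' @return The directory, invisibly.
#' @export
export_eye_maps <- function(maps, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("ez_um", "onl_um", "drusen_height_um", "sdd_height_um")) {
    write.table(maps[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                sep = ",", row.names = FALSE, col.names = FALSE)
  }
  hrf <- if (length(maps$hrf_components)) {
    do.call(rbind, lapply(maps$hrf_components, function(c0) {
      cbind(component = c0$id, c0$pixels, total_nl = c0$total_nl)
    }))
  } else {
    data.frame(component = integer(0), bscan = integer(0), ascan = integer(0),
               x_um = numeric(0), y_um = numeric(0), vol_nl = numeric(0),
               total_nl = numeric(0))
  }
  write.csv(hrf, file.path(out_dir, "hrf_components.csv"), row.names = FALSE)
  g <- maps$geometry
  jsonlite::write_json(list(
    n_bscans = g$n_bscans, n_ascans = g$n_ascans, field_deg = g$field_deg,
    um_per_deg = g$um_per_deg, fovea_xy_um = g$fovea_xy_um
  ), file.path(out_dir, "geometry.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @rdname export_eye_maps
#' @param dir Directory written by [export_eye_maps()].
#' @export
read_eye_maps <- function(dir) {
  g <- jsonlite::read_json(file.path(dir, "geometry.json"), simplifyVector = TRUE)
  geometry <- oct_geometry(g$n_bscans, g$n_ascans, g$field_deg, g$um_per_deg,
                           g$fovea_xy_um)
  rd <- function(nm) as.matrix(read.csv(file.path(dir, paste0(nm, ".csv")),
                                        header = FALSE))
  hrf_tab <- read.csv(file.path(dir, "hrf_components.csv"))
  comps <- lapply(split(hrf_tab, hrf_tab$component), function(d) {
    list(id = d$component[1],
         pixels = d[, c("bscan", "ascan", "x_um", "y_um", "vol_nl")],
         total_nl = d$total_nl[1])
  })
  structure(list(
    ez_um = unname(rd("ez_um")), onl_um = unname(rd("onl_um")),
    drusen_height_um = unname(rd("drusen_height_um")),
    sdd_height_um = unname(rd("sdd_height_um")),
    hrf_components = unname(comps), geometry = geometry
  ), class = "biomarker_maps")
}
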