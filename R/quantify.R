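#' Quantification configuration
#'
#' @param radius_um Quantification radius around each stimulus centre
#'   (default 70 um).
#' @param hrf_threshold_nl Feature-level HRF volume threshold: connected
#'   components with total volume at or below this are discarded before any
#'   in-disc accounting (default 0.06 nl).
#' @param maia_floor_adjust Map raw MAIA -1 dB values to 0 dB (default TRUE).
#' @param hrf_disc_level Apply the HRF threshold to the in-disc volume
#'   instead of the component total (alternative reading; default FALSE).
#' @return A `quant_config` list.
#' @export
quant_config <- function(radius_um = 70, hrf_threshold_nl = 0.06,
                         maia_floor_adjust = TRUE, hrf_disc_level = FALSE) {
  assert_that(radius_um > 0, "radius must be positive")
  assert_that(hrf_threshold_nl >= 0, "threshold must be >= 0")
  structure(list(radius_um = radius_um, hrf_threshold_nl = hrf_threshold_nl,
                 maia_floor_adjust = maia_floor_adjust,
                 hrf_disc_level = hrf_disc_level),
            class = "quant_config")
}

#' En-face pixels within a stimulus disc
#'
#' All en-face pixels whose centres lie within `radius_um` of a stimulus
#' centre, honouring the anisotropic pixel spacing (at defaults ~11.3 um
#' between A-scans versus 60 um between B-scans, so a 70 um disc spans about
#' 13 A-scans but only 3 B-scan rows). Membership is centre-in-circle with
#' no partial-area weighting.
#'
#' @param center_um Stimulus centre, en-face `c(x, y)` in um.
#' @param geometry An [oct_geometry()].
#' @param radius_um Disc radius in um.
#' @return Data frame with `bscan`, `ascan` (1-based indices) — zero rows if
#'   the disc lies entirely outside the scan.
#' @export
disc_pixels <- function(center_um, geometry, radius_um = 70) {
  assert_that(radius_um > 0, "radius must be positive")
  cx <- center_um[1]; cy <- center_um[2]
  dx <- geometry$ascan_spacing_um; dy <- geometry$bscan_spacing_um
  j0 <- max(1L, floor((cx - radius_um) / dx) + 1L)
  j1 <- min(geometry$n_ascans, ceiling((cx + radius_um) / dx) + 1L)
  i0 <- max(1L, floor((cy - radius_um) / dy) + 1L)
  i1 <- min(geometry$n_bscans, ceiling((cy + radius_um) / dy) + 1L)
  if (j0 > j1 || i0 > i1) return(data.frame(bscan = integer(0), ascan = integer(0)))
  js <- j0:j1; is <- i0:i1
  d2 <- outer((bscan_y_um(geometry, is) - cy)^2,
              (ascan_x_um(geometry, js) - cx)^2, `+`)
  idx <- which(d2 <= radius_um^2 + 1e-9, arr.ind = TRUE)
  data.frame(bscan = is[idx[, 1]], ascan = js[idx[, 2]])
}

#' Mean thickness over a disc
#'
#' Arithmetic mean of a thickness raster over the disc pixels (thickness is
#' an intensive quantity, so the disc aggregate is a mean, not a sum).
#'
#' @param raster Thickness matrix in um (B-scan rows x A-scan columns).
#' @param disc Pixel set from [disc_pixels()].
#' @return Mean thickness in um, or `NA` for an empty disc.
#' @export
mean_thickness <- function(raster, disc) {
  if (nrow(disc) == 0) return(NA_real_)
  mean(raster[cbind(disc$bscan, disc$ascan)])
}

#' Deposit volume within a disc
#'
#' Integrates a height map over the disc: sum of height x pixel area,
#' converted to nanolitres (1 nl = 1e6 um^3).
#'
#' @param height_raster Height map in um.
#' @param disc Pixel set from [disc_pixels()].
#' @param geometry An [oct_geometry()] (supplies the pixel area).
#' @return Volume in nl, or `NA` for an empty disc.
#' @export
volume_in_disc <- function(height_raster, disc, geometry) {
  if (nrow(disc) == 0) return(NA_real_)
  sum(height_raster[cbind(disc$bscan, disc$ascan)]) * pixel_area_um2(geometry) / 1e6
}

#' HRF volume within a disc
#'
#' Connected HRF components whose *total* volume is at or below the feature
#' threshold (0.06 nl) are discarded globally; surviving components
#' contribute the volume of their voxels that fall inside the disc (so a
#' 0.10 nl component with 40% of its voxel volume in the disc contributes
#' 0.04 nl). Set `hrf_disc_level` in the config to threshold the in-disc
#' volume instead.
#'
#' @param hrf_components Component list from [generate_eye()] (each with
#'   `pixels` data frame carrying `bscan`, `ascan`, `vol_nl`, and
#'   `total_nl`).
#' @param disc Pixel set from [disc_pixels()].
#' @param config A [quant_config()].
#' @return In-disc HRF volume in nl (0 when nothing qualifies; `NA` for an
#'   empty disc).
#' @export
hrf_volume_in_disc <- function(hrf_components, disc, config = quant_config()) {
  if (nrow(disc) == 0) return(NA_real_)
  if (!length(hrf_components)) return(0)
  ## integer pixel keys avoid string building in this hot path
  key <- disc$bscan * 100000L + disc$ascan
  total <- 0
  for (comp in hrf_components) {
    if (!config$hrf_disc_level && comp$total_nl <= config$hrf_threshold_nl) next
    inside <- (comp$pixels$bscan * 100000L + comp$pixels$ascan) %in% key
    v <- sum(comp$pixels$vol_nl[inside])
    if (config$hrf_disc_level && v <= config$hrf_threshold_nl) v <- 0
    total <- total + v
  }
  total
}

#' Stimulus eccentricity in degrees
#'
#' Euclidean en-face distance from the fovea divided by the retinal scale.
#'
#' @param point_um En-face `c(x, y)` in um.
#' @param fovea_um Foveal centre `c(x, y)` in um.
#' @param geometry An [oct_geometry()] (supplies `um_per_deg`).
#' @return Eccentricity in degrees.
#' @export
eccentricity_deg <- function(point_um, fovea_um, geometry) {
  sqrt(sum((as.numeric(point_um) - as.numeric(fovea_um))^2)) / geometry$um_per_deg
}

#' Adjust raw device sensitivities
#'
#' Maps the raw MAIA floor value of -1 dB to 0 dB (for consistency with the
#' MP-3 measurement range) and clamps to the device range. Values outside
#' the raw device range are a data error.
#'
#' @param raw_db Numeric vector of raw sensitivities.
#' @param device `"MP3"` or `"MAIA"`.
#' @param config A [quant_config()].
#' @return Adjusted dB vector.
#' @export
adjust_sensitivity <- function(raw_db, device = c("MP3", "MAIA"),
                               config = quant_config()) {
  device <- match.arg(device)
  lo <- if (device == "MAIA") -1 else 0
  hi <- if (device == "MAIA") 36 else 34
  assert_that(all(raw_db >= lo - 1e-9 & raw_db <= hi + 1e-9),
              "raw sensitivity outside the ", device, " range [", lo, ", ", hi, "]",
              class = "octmp_data_error")
  out <- raw_db
  if (device == "MAIA" && config$maia_floor_adjust) out[out < 0] <- 0
  pmin(pmax(out, 0), hi)
}

## all biomarker features at one en-face stimulus centre (um)
point_features <- function(maps, center_um, fovea_um, config = quant_config()) {
  g <- maps$geometry
  disc <- disc_pixels(center_um, g, config$radius_um)
  list(
    ecc_deg = eccentricity_deg(center_um, fovea_um, g),
    ez_um = mean_thickness(maps$ez_um, disc),
    onl_um = mean_thickness(maps$onl_um, disc),
    drusen_nl = volume_in_disc(maps$drusen_height_um, disc, g),
    sdd_nl = volume_in_disc(maps$sdd_height_um, disc, g),
    hrf_nl = hrf_volume_in_disc(maps$hrf_components, disc, config),
    n_pixels = nrow(disc)
  )
}

## features for a whole matrix of stimulus centres -> data frame (hot path)
points_features <- function(maps, centers_um, fovea_um, config = quant_config()) {
  n <- nrow(centers_um)
  out <- data.frame(ecc_deg = numeric(n), ez_um = numeric(n),
                    onl_um = numeric(n), drusen_nl = numeric(n),
                    sdd_nl = numeric(n), hrf_nl = numeric(n),
                    n_pixels = integer(n))
  for (k in seq_len(n)) {
    fe <- point_features(maps, centers_um[k, ], fovea_um, config)
    out$ecc_deg[k] <- fe$ecc_deg
    out$ez_um[k] <- fe$ez_um; out$onl_um[k] <- fe$onl_um
    out$drusen_nl[k] <- fe$drusen_nl; out$sdd_nl[k] <- fe$sdd_nl
    out$hrf_nl[k] <- fe$hrf_nl; out$n_pixels[k] <- fe$n_pixels
  }
  out
}

#' Assemble the long-format analysis table
#'
#' One row per patient x device x run x stimulus: maps each acquisition's
#' stimulus pixel coordinates into OCT en-face space through its
#' registration transform, quantifies every biomarker within the 70 um
#' disc, adjusts raw sensitivities, and flags records whose stimulus centre
#' falls outside the scanned OCT area as excluded (discs partially off-scan
#' use their available pixels). Each acquisition is registered
#' independently, so biomarker values may differ slightly between runs.
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @param registrations Optional nested list
#'   `registrations[[patient]][[acquisition]]` of transforms
#'   ([similarity_transform()] or `registration_result`). `NULL` uses each
#'   acquisition's hidden true transform (direct/oracle mode).
#' @param config A [quant_config()].
#' @return Data frame of class `analysis_table` with columns `patient_id`,
#'   `device`, `run`, `point_id`, `eccentricity_deg`, `age`, `ez_um`,
#'   `onl_um`, `drusen_nl`, `sdd_nl`, `hrf_nl`, `pws_db`, `included`;
#'   attribute `n_included` reports the inclusion count.
#' @export
assemble_table <- function(cohort, registrations = NULL,
                           config = quant_config()) {
  rows <- vector("list", 0)
  for (pi in seq_along(cohort$patients)) {
    pat <- cohort$patients[[pi]]
    maps <- pat$eye$maps
    fovea <- pat$eye$fovea_xy_um
    for (ai in seq_along(pat$acquisitions)) {
      acq <- pat$acquisitions[[ai]]
      tf <- if (is.null(registrations)) {
        acq$true_transform
      } else {
        r <- registrations[[pi]][[ai]]
        assert_that(!is.null(r), "missing registration for patient ", pi,
                    " acquisition ", ai, class = "octmp_data_error")
        if (inherits(r, "registration_result")) r$transform else r
      }
      centers <- apply_transform(tf, cbind(acq$points$x_px, acq$points$y_px))
      adj_db <- adjust_sensitivity(acq$points$sensitivity_db, acq$device, config)
      fe <- points_features(maps, centers, fovea, config)
      in_area <- vapply(seq_len(nrow(centers)), function(k) {
        point_in_scan(centers[k, ], maps$geometry)
      }, logical(1))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pat$patient_id, device = acq$device, run = acq$run,
        point_id = acq$points$point_id,
        eccentricity_deg = fe$ecc_deg, age = pat$age,
        ez_um = fe$ez_um, onl_um = fe$onl_um,
        drusen_nl = fe$drusen_nl, sdd_nl = fe$sdd_nl, hrf_nl = fe$hrf_nl,
        pws_db = adj_db,
        included = in_area & fe$n_pixels > 0
      )
    }
  }
  tab <- do.call(rbind, rows)
  attr(tab, "n_included") <- sum(tab$included)
  class(tab) <- c("analysis_table", "data.frame")
  tab
}

#' Write / read the analysis table as CSV (fixed column order)
#' @param tab An `analysis_table`.
#' @param path Output CSV path.
#' @return The path (write) or the table (read), invisibly for write.
#' @export
write_analysis_table <- function(tab, path) {
  cols <- c("patient_id", "device", "run", "point_id", "eccentricity_deg",
            "age", "ez_um", "onl_um", "drusen_nl", "sdd_nl", "hrf_nl",
            "pws_db", "included")
  write.csv(tab[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_analysis_table
#' @export
read_analysis_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tab$included <- as.logical(tab$included)
  attr(tab, "n_included") <- sum(tab$included)
  class(tab) <- c("analysis_table", "data.frame")
  tab
}
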