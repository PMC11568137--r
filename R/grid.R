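#' Build the microperimetry stimulus grid
#'
#' Constructs the customized 45-point macular grid used by both devices: one
#' central stimulus plus concentric rings of evenly spaced points. Coordinates
#' are in degrees relative to the fovea, x = r cos(theta), y = r sin(theta)
#' with theta measured from the positive x axis; each ring may carry its own
#' angular offset. The default layout places 1 central point and rings of
#' 12, 16 and 16 points at 1.5, 2.5 and 5.2 degrees eccentricity — the
#' eccentricities at which per-degree sensitivity slopes are reported.
#'
#' @param layout A list with elements `center` (0 or 1 central points) and
#'   `rings`, a list of rings each with `n` (point count), `radius_deg` and
#'   optional `offset_deg` (default 0). Defaults to [default_grid_layout()].
#' @param stimulus_diameter_deg Stimulus diameter in degrees (Goldmann III,
#'   0.43).
#' @return A `stimulus_grid`: data frame `points` with columns `point_id`,
#'   `x_deg`, `y_deg`, `ecc_deg`, plus `n_points` and the stimulus size.
#' @examples
#' g <- build_stimulus_grid()
#' table(g$points$ecc_deg)
#' @export
build_stimulus_grid <- function(layout = default_grid_layout(),
                                stimulus_diameter_deg = 0.43) {
  center <- layout$center %||% 0
  rings <- layout$rings %||% list()
  n_total <- center + sum(vapply(rings, function(r) r$n, numeric(1)))
  expected <- layout$n_points %||% n_total
  assert_that(n_total == expected,
              "grid layout point counts sum to ", n_total,
              " but n_points = ", expected, class = "octmp_config_error")
  xs <- ys <- numeric(0)
  if (center >= 1) {
    xs <- rep(0, center); ys <- rep(0, center)
  }
  for (ring in rings) {
    assert_that(ring$n >= 1 && ring$radius_deg > 0,
                "ring needs n >= 1 and positive radius",
                class = "octmp_config_error")
    off <- (ring$offset_deg %||% 0) * pi / 180
    theta <- off + 2 * pi * (seq_len(ring$n) - 1) / ring$n
    xs <- c(xs, ring$radius_deg * cos(theta))
    ys <- c(ys, ring$radius_deg * sin(theta))
  }
  pts <- data.frame(
    point_id = seq_along(xs),
    x_deg = xs,
    y_deg = ys,
    ecc_deg = sqrt(xs^2 + ys^2)
  )
  structure(list(
    points = pts,
    n_points = nrow(pts),
    stimulus_diameter_deg = stimulus_diameter_deg
  ), class = "stimulus_grid")
}

#' Default 45-point grid layout
#'
#' One central point, 12 points at 1.5 degrees, 16 at 2.5 degrees and 16 at
#' 5.2 degrees (45 total). The middle ring is rotated by half its angular
#' step so that adjacent rings interleave.
#'
#' @return A layout list accepted by [build_stimulus_grid()].
#' @export
default_grid_layout <- function() {
  list(
    center = 1,
    rings = list(
      list(n = 12, radius_deg = 1.5, offset_deg = 0),
      list(n = 16, radius_deg = 2.5, offset_deg = 11.25),
      list(n = 16, radius_deg = 5.2, offset_deg = 0)
    ),
    n_points = 45
  )
}

#' @export
print.stimulus_grid <- function(x, ...) {
  cat(sprintf("<stimulus_grid> %d points, Goldmann stimulus %.2f deg\n",
              x$n_points, x$stimulus_diameter_deg))
  ecc <- sort(unique(round(x$points$ecc_deg, 6)))
  cat("  eccentricities (deg):", paste(ecc, collapse = ", "), "\n")
  invisible(x)
}

## grid point positions in en-face um for a given geometry (fovea-anchored)
grid_points_um <- function(grid, geometry) {
  cbind(
    x = geometry$fovea_xy_um[1] + grid$points$x_deg * geometry$um_per_deg,
    y = geometry$fovea_xy_um[2] + grid$points$y_deg * geometry$um_per_deg
  )
}
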