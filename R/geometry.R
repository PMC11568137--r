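#' OCT acquisition geometry
#'
#' Describes the en-face sampling grid of a macular OCT cube: `n_bscans`
#' B-scans of `n_ascans` A-scans each covering a `field_deg` square field.
#' The en-face frame has its origin at the scan corner, the x axis along the
#' A-scan direction and the y axis along the B-scan direction, both in
#' micrometres. At the default retinal scale of 288 um/degree a 97 x 512 cube
#' over 20 x 20 degrees samples every 60 um between B-scans and every
#' ~11.3 um between A-scans.
#'
#' @param n_bscans Number of B-scans (rows of en-face rasters). Default 97.
#' @param n_ascans Number of A-scans per B-scan (columns). Default 512.
#' @param field_deg Field of view in degrees, length-2 `c(x, y)` or scalar.
#'   Default 20.
#' @param um_per_deg Retinal scale in micrometres per degree. Default 288
#'   (schematic eye); configurable because published degree-to-mm
#'   conversions vary.
#' @param fovea_xy_um En-face coordinates of the fovea in um; defaults to the
#'   centre of the field.
#' @return An object of class `oct_geometry` with derived pixel spacings
#'   `ascan_spacing_um` and `bscan_spacing_um` (field extent divided by
#'   n - 1, so the first and last sample sit on the field edges).
#' @examples
#' g <- oct_geometry()
#' g$bscan_spacing_um  # 60
#' @export
oct_geometry <- function(n_bscans = 97, n_ascans = 512, field_deg = 20,
                         um_per_deg = 288, fovea_xy_um = NULL) {
  assert_that(n_bscans >= 2 && n_ascans >= 2, "geometry needs >= 2 scans per axis")
  assert_that(um_per_deg > 0, "um_per_deg must be positive")
  field_deg <- rep(field_deg, length.out = 2)
  assert_that(all(field_deg > 0), "field_deg must be positive")
  extent_um <- field_deg * um_per_deg # c(x extent, y extent)
  if (is.null(fovea_xy_um)) fovea_xy_um <- extent_um / 2
  g <- structure(list(
    n_bscans = as.integer(n_bscans),
    n_ascans = as.integer(n_ascans),
    field_deg = field_deg,
    um_per_deg = um_per_deg,
    extent_um = extent_um,
    ascan_spacing_um = extent_um[1] / (n_ascans - 1),
    bscan_spacing_um = extent_um[2] / (n_bscans - 1),
    fovea_xy_um = as.numeric(fovea_xy_um)
  ), class = "oct_geometry")
  assert_that(g$ascan_spacing_um > 0 && g$bscan_spacing_um > 0,
              "pixel spacings must be positive")
  g
}

#' @export
print.oct_geometry <- function(x, ...) {
  cat(sprintf(
    "<oct_geometry> %d B-scans x %d A-scans over %.0f x %.0f deg (%.0f um/deg)\n",
    x$n_bscans, x$n_ascans, x$field_deg[1], x$field_deg[2], x$um_per_deg))
  cat(sprintf("  spacing: %.2f um (A-scan) x %.2f um (B-scan); fovea at (%.0f, %.0f) um\n",
              x$ascan_spacing_um, x$bscan_spacing_um,
              x$fovea_xy_um[1], x$fovea_xy_um[2]))
  invisible(x)
}

## en-face x coordinate (um) of A-scan column j (1-based), y of B-scan row i
ascan_x_um <- function(geometry, j) (j - 1) * geometry$ascan_spacing_um
bscan_y_um <- function(geometry, i) (i - 1) * geometry$bscan_spacing_um

## pixel footprint area in um^2
pixel_area_um2 <- function(geometry) {
  geometry$ascan_spacing_um * geometry$bscan_spacing_um
}

#' Locate an en-face point on the B-scan grid
#'
#' Maps an en-face point in micrometres (scan-corner origin) to the nearest
#' (B-scan, A-scan) sample, using a round-half-down tie rule: a point exactly
#' between two scans is assigned to the lower index. Points outside the
#' scanned field return an out-of-area marker rather than an error.
#'
#' Indices are 1-based (R convention): the foveal centre of a default
#' centred 97 x 512 geometry maps to B-scan 49, A-scan 256.
#'
#' @param point_um Numeric length-2 `c(x, y)` in en-face micrometres.
#' @param geometry An [oct_geometry()].
#' @return A list with `bscan`, `ascan` (1-based integer indices, `NA` when
#'   out of area) and logical `in_area`.
#' @export
enface_to_bscan <- function(point_um, geometry) {
  assert_that(length(point_um) == 2 && all(is.finite(point_um)),
              "point must be finite c(x, y)")
  x <- point_um[1]; y <- point_um[2]
  tol <- 1e-9
  if (x < -tol || y < -tol ||
      x > geometry$extent_um[1] + tol || y > geometry$extent_um[2] + tol) {
    return(list(bscan = NA_integer_, ascan = NA_integer_, in_area = FALSE))
  }
  i0 <- round_half_down(y / geometry$bscan_spacing_um) # 0-based
  j0 <- round_half_down(x / geometry$ascan_spacing_um)
  i0 <- min(max(i0, 0), geometry$n_bscans - 1)
  j0 <- min(max(j0, 0), geometry$n_ascans - 1)
  list(bscan = as.integer(i0 + 1), ascan = as.integer(j0 + 1), in_area = TRUE)
}

## TRUE when an en-face point (um) lies inside the scanned field
point_in_scan <- function(point_um, geometry) {
  x <- point_um[1]; y <- point_um[2]
  tol <- 1e-9
  x >= -tol && y >= -tol &&
    x <= geometry$extent_um[1] + tol && y <= geometry$extent_um[2] + tol
}
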