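#' Render the fundus image pair for one acquisition
#'
#' Produces (a) the OCT-NIR en-face raster in the OCT frame and (b) the
#' device fundus raster (MAIA-NIR or MP-3 colour fundus photo rendered as
#' grayscale) in device-pixel coordinates, both showing the same vessel
#' tree. The device raster is related to the OCT frame by `true_transform`
#' (device-px -> en-face-um), which is retained as hidden ground truth for
#' evaluating registration only. Modality-specific contrast and additive
#' Gaussian noise are applied; noiseless ground-truth vessel masks are
#' returned alongside.
#'
#' @param vessel_tree Vessel tree from [generate_eye()] (segments in en-face
#'   micrometres).
#' @param geometry An [oct_geometry()].
#' @param device `"MP3"` or `"MAIA"` (cosmetic contrast differences only).
#' @param true_transform A [similarity_transform()] mapping device pixels to
#'   en-face micrometres.
#' @param noise_sd Additive Gaussian noise SD on [0, 1] intensities
#'   (default 0.05; 0 disables noise).
#' @param nir_px Side length of the square NIR raster (default 288, i.e.
#'   20 um per pixel for the default field).
#' @param device_px Side length of the square device raster (default 320).
#' @return A list with `nir`, `device` (intensity matrices in [0, 1] with
#'   attributes `px_size_um`/`frame`), `nir_mask`, `device_mask` (ground
#'   truth), `junctions_nir_um`, `junctions_device_px`, `true_transform`.
#' @export
render_fundus_images <- function(vessel_tree, geometry = oct_geometry(),
                                 device = "MP3",
                                 true_transform = similarity_transform(),
                                 noise_sd = 0.05, nir_px = 288,
                                 device_px = 320) {
  assert_that(true_transform$scale > 1e-6,
              "degenerate (near-zero scale) transform",
              class = "octmp_registration_error")
  segs <- vessel_tree$segments
  ext <- geometry$extent_um
  nir_px_size <- ext[1] / nir_px
  nir_mask <- rasterize_vessels(segs, nir_px, nir_px, px_size = nir_px_size)

  inv <- invert_transform(true_transform)
  p0 <- apply_transform(inv, cbind(segs$x0, segs$y0))
  p1 <- apply_transform(inv, cbind(segs$x1, segs$y1))
  dev_segs <- data.frame(x0 = p0[, 1], y0 = p0[, 2],
                         x1 = p1[, 1], y1 = p1[, 2],
                         width_um = segs$width_um / true_transform$scale)
  dev_mask <- rasterize_vessels(dev_segs, device_px, device_px, px_size = 1)

  shade <- function(mask, bg, fg, blur_sigma) {
    img <- bg + (fg - bg) * gaussian_blur(mask + 0, blur_sigma)
    if (noise_sd > 0) img <- img + matrix(rnorm(length(img), 0, noise_sd),
                                          nrow(img), ncol(img))
    pmin(pmax(img, 0), 1)
  }
  nir_img <- shade(nir_mask, bg = 0.20, fg = 0.85, blur_sigma = 0.8)
  dev_img <- shade(dev_mask, bg = if (device == "MAIA") 0.25 else 0.30,
                   fg = if (device == "MAIA") 0.90 else 0.80, blur_sigma = 0.8)
  attr(nir_img, "px_size_um") <- nir_px_size
  attr(nir_img, "frame") <- "oct-enface-um"
  attr(dev_img, "px_size_um") <- NA_real_
  attr(dev_img, "frame") <- "device-px"

  jn <- vessel_tree$junctions
  jd <- if (nrow(jn)) apply_transform(inv, cbind(jn$x_um, jn$y_um)) else
    matrix(numeric(0), 0, 2)
  list(nir = nir_img, device = dev_img,
       nir_mask = nir_mask, device_mask = dev_mask,
       junctions_nir_um = jn,
       junctions_device_px = data.frame(x_px = jd[, 1], y_px = jd[, 2]),
       true_transform = true_transform)
}

## raster (matrix in [0,1]) <-> 8-bit grayscale PNG
write_gray_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), target = path)
  invisible(path)
}

read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a
}
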