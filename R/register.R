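#' Segment retinal vessels in a fundus raster
#'
#' Multi-scale ridge (vesselness) filtering followed by hysteresis
#' thresholding, the automated first step of stimulus-to-OCT
#' co-registration. Vessels are assumed brighter than background (synthetic
#' renders follow this convention; invert real images as needed).
#'
#' @param raster Grayscale image matrix in [0, 1].
#' @param scales Gaussian scales in pixels for the ridge filter.
#' @param low,high Hysteresis thresholds as image-wide vesselness quantiles.
#' @param intensity_gate Weight of the brightness gate: pixels must also
#'   exceed background + gate * (peak - background) after light denoising,
#'   which trims the halo the ridge filter leaves around vessel edges.
#' @return Logical vessel mask of the same shape. A constant image yields an
#'   empty mask with a warning.
#' @export
segment_vessels <- function(raster, scales = c(1, 2, 3),
                            low = 0.90, high = 0.96, intensity_gate = 0.4) {
  img <- as.matrix(raster)
  if (max(img) - min(img) < 1e-9) {
    warning("constant image: returning empty vessel mask")
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  v <- vesselness(img, scales)
  if (max(v) <= 0) {
    warning("no ridge response: returning empty vessel mask")
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  mask <- hysteresis(v, quantile(v, low), quantile(v, high))
  if (intensity_gate > 0) {
    b <- gaussian_blur(img, 0.5)
    bg <- quantile(b, 0.25)
    mask <- mask & (b > bg + intensity_gate * (max(b) - bg))
  }
  mask
}

#' Detect vessel junction points
#'
#' Skeletonizes a binary vessel mask (Zhang-Suen thinning) and marks
#' skeleton pixels whose 8-neighbourhood contains three or more distinct
#' skeleton branches (crossing number >= 3). Nearby junction pixels are
#' merged into cluster centroids.
#'
#' @param mask Logical vessel mask.
#' @param merge_radius_px Junctions closer than this are merged (default 5).
#' @param prune_px Skeleton spurs up to this length are shaved off before
#'   junction counting (default 4).
#' @return A [point_set()] in pixel units (`x` = column, `y` = row, pixel
#'   centres at half-integers), frame `"mask-px"`. Empty mask gives an empty
#'   set.
#' @export
detect_junctions <- function(mask, merge_radius_px = 5, prune_px = 4) {
  if (!any(mask)) return(point_set(numeric(0), numeric(0), "mask-px"))
  sk <- skeletonize(mask)
  ## prune short spurs: repeatedly shave endpoint pixels so that stubby
  ## side-branches (segmentation noise) do not masquerade as junctions
  for (p in seq_len(prune_px)) {
    ends <- sk & neighbour_count(sk) <= 1L
    if (!any(ends)) break
    sk <- sk & !ends
  }
  ## crossing number: 0->1 transitions around the 8-neighbour ring
  p2 <- shift_mat_zero(sk, 1, 0);  p3 <- shift_mat_zero(sk, 1, -1)
  p4 <- shift_mat_zero(sk, 0, -1); p5 <- shift_mat_zero(sk, -1, -1)
  p6 <- shift_mat_zero(sk, -1, 0); p7 <- shift_mat_zero(sk, -1, 1)
  p8 <- shift_mat_zero(sk, 0, 1);  p9 <- shift_mat_zero(sk, 1, 1)
  A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
    (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
    (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
  jx <- which(sk & A >= 3, arr.ind = TRUE)
  if (!nrow(jx)) return(point_set(numeric(0), numeric(0), "mask-px"))
  pts <- cbind(x = jx[, 2] - 0.5, y = jx[, 1] - 0.5)
  if (nrow(pts) > 1) {
    cl <- cutree(hclust(dist(pts), method = "single"), h = merge_radius_px)
    pts <- do.call(rbind, lapply(split(seq_len(nrow(pts)), cl), function(i) {
      colMeans(pts[i, , drop = FALSE])
    }))
  }
  point_set(pts[, 1], pts[, 2], "mask-px")
}

#' Match junction point sets by RANSAC over similarity transforms
#'
#' Finds a robust correspondence between two junction sets with unknown
#' pairing: repeatedly samples one source pair and one destination pair
#' (pruned by a scale plausibility gate), estimates the implied similarity,
#' and scores it by mutual-nearest-neighbour inliers within `gate` (in
#' destination units). The best model is refit on its inliers. Deterministic
#' for a fixed seed.
#'
#' @param src,dst [point_set()]s (non-empty).
#' @param gate Inlier distance gate in destination units (default 50, i.e.
#'   50 um when the destination frame is en-face micrometres).
#' @param min_inliers Minimum inlier count for success (default 4).
#' @param n_iter RANSAC iterations (default 1500).
#' @param seed RANSAC seed (fixed default for determinism).
#' @param scale_range Plausible scale interval for sample pruning.
#' @return A list: `pairs` (data frame src_x, src_y, dst_x, dst_y),
#'   `transform` (inlier refit), `rmse`, `n_inliers`. Raises an
#'   `octmp_registration_error` ("manual correction needed") when no model
#'   reaches `min_inliers`.
#' @export
match_junctions <- function(src, dst, gate = 50, min_inliers = 4,
                            n_iter = 4000, seed = 20240101,
                            scale_range = c(0.2, 5)) {
  assert_that(nrow(src) >= 2 && nrow(dst) >= 2,
              "need at least 2 junctions in each set",
              class = "octmp_registration_error")
  s <- as.matrix(src[, c("x", "y")]); d <- as.matrix(dst[, c("x", "y")])
  best <- NULL
  ## complex-number form: a 2-point similarity is z -> a z + t with
  ## a = (d_l - d_k) / (s_j - s_i), t = d_k - a s_i
  zs <- complex(real = s[, 1], imaginary = s[, 2])
  zd <- complex(real = d[, 1], imaginary = d[, 2])
  dp <- expand.grid(k = seq_along(zd), l = seq_along(zd))
  dp <- dp[dp$k != dp$l, , drop = FALSE]
  delta_d <- zd[dp$l] - zd[dp$k]
  with_seed(seed, {
    ## anchor source pairs: random sample, longer pairs preferred for
    ## numerical stability; capped so the sweep stays bounded
    sp <- expand.grid(i = seq_along(zs), j = seq_along(zs))
    sp <- sp[sp$i < sp$j, , drop = FALSE]
    len <- Mod(zs[sp$j] - zs[sp$i])
    sp <- sp[len >= stats::median(len) & len > 1e-9, , drop = FALSE]
    n_anchor <- min(nrow(sp), max(20L, ceiling(n_iter / 100)))
    sp <- sp[sample.int(nrow(sp), n_anchor), , drop = FALSE]
    for (an in seq_len(nrow(sp))) {
      i <- sp$i[an]; j <- sp$j[an]
      a <- delta_d / (zs[j] - zs[i])
      keep <- Mod(a) >= scale_range[1] & Mod(a) <= scale_range[2]
      if (!any(keep)) next
      a_k <- a[keep]
      t_k <- zd[dp$k[keep]] - a_k * zs[i]
      ## probe filter: two extra source points must land near some dst point
      others <- setdiff(seq_along(zs), c(i, j))
      if (length(others) >= 2) {
        for (pz in zs[sample(others, 2)]) {
          w <- a_k * pz + t_k
          hit <- vapply(w, function(wi) min(Mod(zd - wi)) <= gate, logical(1))
          a_k <- a_k[hit]; t_k <- t_k[hit]
          if (!length(a_k)) break
        }
      }
      for (ci in seq_along(a_k)) {
        ts <- a_k[ci] * zs + t_k[ci]
        inl <- mutual_nn_inliers(cbind(Re(ts), Im(ts)), d, gate)
        if (is.null(best) || nrow(inl) > best$n) {
          best <- list(n = nrow(inl), inl = inl)
        }
      }
    }
  })
  if (is.null(best) || best$n < min_inliers) {
    stop_octmp("junction matching failed (< ", min_inliers,
               " inliers): manual correction needed",
               class = "octmp_registration_error")
  }
  ## refit on inliers, then refresh the inlier set once with the better model
  for (rep in 1:2) {
    fit <- estimate_similarity(s[best$inl$i, , drop = FALSE],
                               d[best$inl$j, , drop = FALSE])
    inl <- mutual_nn_inliers(apply_transform(fit$transform, s), d, gate)
    if (nrow(inl) < min_inliers) break
    best$inl <- inl
  }
  fit <- estimate_similarity(s[best$inl$i, , drop = FALSE],
                             d[best$inl$j, , drop = FALSE])
  list(pairs = data.frame(src_x = s[best$inl$i, 1], src_y = s[best$inl$i, 2],
                          dst_x = d[best$inl$j, 1], dst_y = d[best$inl$j, 2]),
       transform = fit$transform, rmse = fit$rmse,
       n_inliers = nrow(best$inl))
}

## mutual nearest neighbours of transformed source vs destination within gate
mutual_nn_inliers <- function(ts, d, gate) {
  d2 <- outer(rowSums(ts^2), rep(1, nrow(d))) +
    outer(rep(1, nrow(ts)), rowSums(d^2)) - 2 * ts %*% t(d)
  d2[d2 < 0] <- 0
  nn_s <- apply(d2, 1, which.min)
  nn_d <- apply(d2, 2, which.min)
  i <- which(nn_d[nn_s] == seq_len(nrow(ts)) &
               sqrt(d2[cbind(seq_len(nrow(ts)), nn_s)]) <= gate)
  data.frame(i = i, j = nn_s[i])
}

#' Register one acquisition's fundus pair
#'
#' Composes the automated co-registration chain: vessel segmentation in both
#' rasters, junction detection, robust junction matching and least-squares
#' similarity estimation. The result maps device pixels into OCT en-face
#' micrometres. Low-quality results (RMSE above `rmse_gate` or fewer than 4
#' inliers) are flagged for the manual-correction path rather than silently
#' accepted.
#'
#' @param device_raster Device fundus image matrix (device-pixel frame).
#' @param nir_raster OCT-NIR image matrix (en-face frame); its physical
#'   pixel size is taken from the `px_size_um` attribute or `nir_px_size_um`.
#' @param seed RANSAC seed.
#' @param nir_px_size_um Micrometres per NIR pixel (used when the attribute
#'   is absent; default 20).
#' @param rmse_gate Quality gate in micrometres (default 35, half the 70 um
#'   quantification radius).
#' @param gate Inlier gate passed to [match_junctions()] (um).
#' @param scale_range Plausible um-per-device-pixel interval used to prune
#'   RANSAC samples (default 4-80 um/px covers common fundus cameras).
#' @return A `registration_result`: `transform` (device-px -> en-face-um),
#'   `pairs`, `rmse_um`, `n_inliers`, `quality_ok`.
#' @export
register_acquisition <- function(device_raster, nir_raster, seed = 20240101,
                                 nir_px_size_um = 20, rmse_gate = 35,
                                 gate = 50, scale_range = c(4, 80)) {
  px <- attr(nir_raster, "px_size_um") %||% nir_px_size_um
  if (is.na(px)) px <- nir_px_size_um
  dev_j <- detect_junctions(segment_vessels(device_raster))
  nir_j <- detect_junctions(segment_vessels(nir_raster))
  assert_that(nrow(dev_j) >= 2 && nrow(nir_j) >= 2,
              "too few junctions detected for registration",
              class = "octmp_registration_error")
  nir_um <- point_set(nir_j$x * px, nir_j$y * px, "oct-enface-um")
  m <- match_junctions(dev_j, nir_um, gate = gate, seed = seed,
                       scale_range = scale_range)
  structure(list(
    transform = m$transform, pairs = m$pairs,
    rmse_um = m$rmse, n_inliers = m$n_inliers,
    quality_ok = m$rmse <= rmse_gate && m$n_inliers >= 4
  ), class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> RMSE %.2f um, %d inliers, quality %s\n",
              x$rmse_um, x$n_inliers, if (x$quality_ok) "OK" else "FLAGGED"))
  print(x$transform)
  invisible(x)
}

## serialize a registration result to JSON (matrix, rmse, inliers, flag)
registration_to_json <- function(reg, path) {
  jsonlite::write_json(list(
    matrix = transform_matrix(reg$transform),
    scale = reg$transform$scale,
    rotation_rad = reg$transform$rotation,
    translation = reg$transform$translation,
    rmse_um = reg$rmse_um,
    n_inliers = reg$n_inliers,
    quality_ok = reg$quality_ok
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
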