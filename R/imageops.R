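## Minimal grayscale image operations used by the fundus rendering and
## vessel registration stages. Images are plain numeric matrices in [0, 1]
## with row = image y, column = image x.

## 1-D Gaussian kernel (normalized)
gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k / sum(k)
}

## shift a matrix by (dr, dc), replicating edges
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

## separable convolution with a symmetric 1-D kernel (edge replication)
conv_sep <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_mat(m, i - 1L - r, 0L)
  m2 <- out
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_mat(m2, 0L, i - 1L - r)
  out
}

gaussian_blur <- function(m, sigma) conv_sep(m, gaussian_kernel(sigma))

## Frangi-style vesselness for bright ridges at one scale
vesselness_scale <- function(img, sigma, beta = 0.5) {
  g <- gaussian_blur(img, sigma)
  # scale-normalized Hessian by central differences
  gxx <- shift_mat(g, 0, -1) - 2 * g + shift_mat(g, 0, 1)
  gyy <- shift_mat(g, -1, 0) - 2 * g + shift_mat(g, 1, 0)
  gxy <- (shift_mat(g, -1, -1) + shift_mat(g, 1, 1) -
            shift_mat(g, -1, 1) - shift_mat(g, 1, -1)) / 4
  s2 <- sigma^2
  gxx <- gxx * s2; gyy <- gyy * s2; gxy <- gxy * s2
  tmp <- sqrt((gxx - gyy)^2 + 4 * gxy^2)
  l1 <- (gxx + gyy + tmp) / 2 # larger (signed)
  l2 <- (gxx + gyy - tmp) / 2 # smaller: strongly negative on bright ridges
  hi <- pmin(abs(l1), abs(l2)); lo <- pmax(abs(l1), abs(l2))
  rb2 <- (hi / pmax(lo, 1e-12))^2
  S2 <- l1^2 + l2^2
  c2 <- max(S2) / 4
  v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * pmax(c2, 1e-12))))
  v[l2 > 0] <- 0
  v
}

## multi-scale vesselness (pixelwise max over scales)
vesselness <- function(img, scales = c(1, 2, 3)) {
  v <- matrix(0, nrow(img), ncol(img))
  for (s in scales) v <- pmax(v, vesselness_scale(img, s))
  v
}

## hysteresis threshold: keep weak pixels 8-connected to strong pixels
hysteresis <- function(v, low, high) {
  strong <- v >= high
  weak <- v >= low
  cur <- strong & weak
  repeat {
    grown <- cur
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      grown <- grown | shift_mat(cur, dr, dc)
    }
    grown <- grown & weak
    if (identical(grown, cur)) break
    cur <- grown
  }
  cur
}

## number of 8-neighbours set, for a logical matrix
neighbour_count <- function(b) {
  n <- matrix(0L, nrow(b), ncol(b))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    n <- n + shift_mat_zero(b, dr, dc)
  }
  n
}

## shift with zero padding (logical -> integer)
shift_mat_zero <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- seq_len(nr); cs <- seq_len(nc)
  rdst <- rs[rs + dr >= 1 & rs + dr <= nr]
  cdst <- cs[cs + dc >= 1 & cs + dc <= nc]
  out[rdst + dr, cdst + dc] <- m[rdst, cdst] + 0L
  out
}

## Zhang-Suen thinning of a binary mask to a 1-px skeleton
skeletonize <- function(mask) {
  b <- mask + 0L
  p <- function(m, dr, dc) shift_mat_zero(m, dr, dc)
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- p(b, 1, 0);  p3 <- p(b, 1, -1); p4 <- p(b, 0, -1)
      p5 <- p(b, -1, -1); p6 <- p(b, -1, 0); p7 <- p(b, -1, 1)
      p8 <- p(b, 0, 1);  p9 <- p(b, 1, 1)
      ## p2..p9 are N, NE, E, SE, S, SW, W, NW neighbours (row 1 = top)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (pass == 1) {
        cond <- b == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- b == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        b[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  b == 1L
}

## rasterize vessel segments into a binary mask; coordinates of segment
## endpoints are in the same units as px_size; pixel (i, j) centre at
## ((j - 0.5) px, (i - 0.5) px)
rasterize_vessels <- function(segments, nx, ny, px_size = 1) {
  mask <- matrix(FALSE, ny, nx)
  for (k in seq_len(nrow(segments))) {
    sx0 <- segments$x0[k] / px_size; sy0 <- segments$y0[k] / px_size
    sx1 <- segments$x1[k] / px_size; sy1 <- segments$y1[k] / px_size
    hw <- segments$width_um[k] / px_size / 2
    j0 <- max(1L, floor(min(sx0, sx1) - hw)); j1 <- min(nx, ceiling(max(sx0, sx1) + hw) + 1L)
    i0 <- max(1L, floor(min(sy0, sy1) - hw)); i1 <- min(ny, ceiling(max(sy0, sy1) + hw) + 1L)
    if (j0 > j1 || i0 > i1) next
    xs <- (j0:j1) - 0.5; ys <- (i0:i1) - 0.5
    vx <- sx1 - sx0; vy <- sy1 - sy0
    len2 <- vx^2 + vy^2
    px <- matrix(xs, length(ys), length(xs), byrow = TRUE) - sx0
    py <- matrix(ys, length(ys), length(xs)) - sy0
    t_par <- if (len2 > 0) pmin(pmax((px * vx + py * vy) / len2, 0), 1) else 0
    d2 <- (px - t_par * vx)^2 + (py - t_par * vy)^2
    mask[i0:i1, j0:j1] <- mask[i0:i1, j0:j1] | (d2 <= hw^2)
  }
  mask
}

#' Dice overlap of two binary masks
#' @param a,b Logical matrices of identical shape.
#' @return Dice coefficient in [0, 1] (1 when both masks are empty).
#' @export
dice_coefficient <- function(a, b) {
  assert_that(all(dim(a) == dim(b)), "mask shapes differ")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
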