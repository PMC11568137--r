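#' Tagged 2-D point set
#'
#' A set of (x, y) coordinates carrying the name of the frame they live in
#' (`"device-px"` or `"oct-enface-um"`). Frame tags make unit mistakes loud:
#' operations that combine point sets check them.
#'
#' @param x,y Numeric coordinate vectors (finite, equal length).
#' @param frame Frame tag string.
#' @return A `point_set` data frame with attribute `frame`.
#' @export
point_set <- function(x, y, frame) {
  assert_that(length(x) == length(y), "x and y lengths differ")
  assert_that(all(is.finite(x)) && all(is.finite(y)), "coordinates must be finite")
  assert_that(is.character(frame) && nzchar(frame), "frame tag required")
  structure(data.frame(x = as.numeric(x), y = as.numeric(y)),
            frame = frame, class = c("point_set", "data.frame"))
}

ps_frame <- function(ps) attr(ps, "frame") %||% "unknown"

#' Similarity transform (scale, rotation, translation)
#'
#' T(p) = s R(theta) p + t, the transform family used to map device fundus
#' pixels into OCT en-face micrometres. Equivalent 2 x 3 matrix available via
#' [transform_matrix()].
#'
#' @param scale Positive scalar.
#' @param rotation Rotation angle in radians (counter-clockwise).
#' @param translation Length-2 numeric.
#' @return A `similarity_transform`.
#' @export
similarity_transform <- function(scale = 1, rotation = 0, translation = c(0, 0)) {
  assert_that(scale > 0, "scale must be positive")
  structure(list(scale = scale, rotation = rotation,
                 translation = as.numeric(translation)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> scale %.6g, rotation %.4f rad, translation (%.3f, %.3f)\n",
              x$scale, x$rotation, x$translation[1], x$translation[2]))
  invisible(x)
}

#' 2 x 3 matrix form of a similarity transform
#' @param tf A [similarity_transform()].
#' @return A 2 x 3 matrix `[sR | t]`.
#' @export
transform_matrix <- function(tf) {
  R <- matrix(c(cos(tf$rotation), sin(tf$rotation),
                -sin(tf$rotation), cos(tf$rotation)), 2, 2)
  cbind(tf$scale * R, tf$translation)
}

#' Apply a similarity transform to points
#' @param tf A [similarity_transform()].
#' @param pts An n x 2 matrix, data frame or length-2 vector.
#' @return Transformed coordinates, same shape (n x 2 matrix).
#' @export
apply_transform <- function(tf, pts) {
  p <- as.matrix(if (is.null(dim(pts))) matrix(pts, 1) else pts[, 1:2])
  M <- transform_matrix(tf)
  out <- p %*% t(M[, 1:2]) + matrix(M[, 3], nrow(p), 2, byrow = TRUE)
  colnames(out) <- c("x", "y")
  out
}

#' Invert a similarity transform
#' @param tf A [similarity_transform()].
#' @return The inverse `similarity_transform`.
#' @export
invert_transform <- function(tf) {
  s <- 1 / tf$scale
  th <- -tf$rotation
  Rinv <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  similarity_transform(s, th, as.numeric(-s * Rinv %*% tf$translation))
}

#' Least-squares similarity estimation (orthogonal Procrustes with scale)
#'
#' Closed-form solution of the "least square error" transform used during
#' manual and automatic co-registration: finds the similarity minimizing
#' sum ||T(src_i) - dst_i||^2 over matched point pairs (Umeyama's method,
#' rotation constrained to be proper). Exact on noiseless consistent pairs.
#'
#' @param src,dst n x 2 matrices / data frames of corresponding points
#'   (n >= 2, not all coincident).
#' @return A list: `transform` ([similarity_transform()]), `rmse` (root mean
#'   square residual in dst units) and `residuals` (per-pair distances).
#' @export
estimate_similarity <- function(src, dst) {
  s <- as.matrix(src)[, 1:2, drop = FALSE]
  d <- as.matrix(dst)[, 1:2, drop = FALSE]
  assert_that(nrow(s) == nrow(d), "src and dst must pair up")
  assert_that(nrow(s) >= 2, "need at least 2 point pairs",
              class = "octmp_registration_error")
  mu_s <- colMeans(s); mu_d <- colMeans(d)
  sc <- sweep(s, 2, mu_s); dc <- sweep(d, 2, mu_d)
  var_s <- sum(sc^2) / nrow(s)
  assert_that(var_s > 1e-12, "source points are coincident; transform undetermined",
              class = "octmp_registration_error")
  C <- t(dc) %*% sc / nrow(s)
  sv <- svd(C)
  S <- diag(c(1, sign(det(sv$u %*% t(sv$v)))))
  R <- sv$u %*% S %*% t(sv$v)
  scale <- sum(diag(diag(sv$d) %*% S)) / var_s
  assert_that(is.finite(scale) && scale > 0,
              "degenerate configuration: non-positive scale",
              class = "octmp_registration_error")
  t_vec <- mu_d - scale * as.numeric(R %*% mu_s)
  tf <- similarity_transform(scale, atan2(R[2, 1], R[1, 1]), t_vec)
  res <- sqrt(rowSums((apply_transform(tf, s) - d)^2))
  list(transform = tf, rmse = sqrt(mean(res^2)), residuals = res)
}

#' Transform from manually marked junction pairs
#'
#' Human-correction entry point: identical mathematics to
#' [estimate_similarity()], reading pairs as marked on both images.
#'
#' @param pairs Data frame with columns `src_x`, `src_y`, `dst_x`, `dst_y`
#'   (or an n x 4 matrix in that order).
#' @return As [estimate_similarity()].
#' @export
manual_pairs_to_transform <- function(pairs) {
  p <- as.matrix(pairs)
  assert_that(ncol(p) >= 4, "pairs need 4 columns: src_x, src_y, dst_x, dst_y")
  estimate_similarity(p[, 1:2, drop = FALSE], p[, 3:4, drop = FALSE])
}
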