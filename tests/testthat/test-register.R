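test_that("similarity estimation solves the worked 3-pair example exactly", {
  src <- rbind(c(0, 0), c(1, 0), c(0, 1))
  dst <- rbind(c(10, 10), c(10, 12), c(8, 10))
  fit <- estimate_similarity(src, dst)
  expect_equal(fit$transform$scale, 2, tolerance = 1e-12)
  expect_equal(fit$transform$rotation, pi / 2, tolerance = 1e-12)
  expect_equal(fit$transform$translation, c(10, 10), tolerance = 1e-12)
  expect_equal(fit$rmse, 0, tolerance = 1e-12)
  expect_equal(apply_transform(fit$transform, src), dst,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("identity, degeneracy and the manual entry point behave", {
  pts <- cbind(runif(5), runif(5))
  fit <- estimate_similarity(pts, pts)
  expect_equal(fit$transform$scale, 1, tolerance = 1e-12)
  expect_equal(fit$rmse, 0, tolerance = 1e-12)

  expect_error(estimate_similarity(pts[1, , drop = FALSE], pts[1, , drop = FALSE]),
               class = "octmp_registration_error")
  same <- matrix(1, 3, 2)
  expect_error(estimate_similarity(same, same + 5),
               class = "octmp_registration_error")

  manual <- manual_pairs_to_transform(cbind(pts, apply_transform(
    similarity_transform(3, 0.4, c(5, -2)), pts)))
  expect_equal(manual$transform$scale, 3, tolerance = 1e-9)
  expect_equal(manual$transform$rotation, 0.4, tolerance = 1e-9)
})

test_that("noiseless transform recovery and round trip hold to 1e-9", {
  set.seed(4)
  for (rep in 1:10) {
    tf <- similarity_transform(runif(1, 0.3, 4), runif(1, -pi, pi),
                               runif(2, -100, 100))
    src <- cbind(runif(8, -50, 50), runif(8, -50, 50))
    fit <- estimate_similarity(src, apply_transform(tf, src))
    expect_equal(fit$transform$scale, tf$scale, tolerance = 1e-9)
    expect_equal(fit$transform$rotation, tf$rotation, tolerance = 1e-9)
    expect_equal(fit$transform$translation, tf$translation, tolerance = 1e-7)

    # estimating the reverse direction recovers the inverse parameters
    inv <- estimate_similarity(apply_transform(tf, src), src)$transform
    tfi <- invert_transform(tf)
    expect_equal(inv$scale, tfi$scale, tolerance = 1e-9)
    expect_equal(inv$rotation, tfi$rotation, tolerance = 1e-9)
    # composition: T^-1(T(p)) = p
    expect_equal(apply_transform(tfi, apply_transform(tf, src)), src,
                 tolerance = 1e-7, ignore_attr = TRUE)
  }
})

test_that("junction detection handles canonical strokes", {
  blank <- matrix(FALSE, 41, 41)
  # plus sign: one crossing
  plus <- blank; plus[21, 6:36] <- TRUE; plus[6:36, 21] <- TRUE
  j <- detect_junctions(plus, prune_px = 0)
  expect_equal(nrow(j), 1)
  expect_equal(unname(unlist(j[1, c("x", "y")])), c(20.5, 20.5),
               tolerance = 1.5)
  # Y bifurcation: one junction
  y <- blank
  y[21:36, 21] <- TRUE
  for (k in 0:14) { y[21 - k, 21 - k] <- TRUE; y[21 - k, 21 + k] <- TRUE }
  expect_equal(nrow(detect_junctions(y, prune_px = 0)), 1)
  # straight stroke: none
  line <- blank; line[21, 4:38] <- TRUE
  expect_equal(nrow(detect_junctions(line, prune_px = 0)), 0)
  # empty mask: empty set
  expect_equal(nrow(detect_junctions(blank)), 0)
})

test_that("constant images segment to empty masks with a warning", {
  expect_warning(m <- segment_vessels(matrix(0.5, 32, 32)), "constant")
  expect_false(any(m))
})

test_that("vessel segmentation reaches the Dice targets on renders", {
  eye <- generate_eye(3)
  tf <- octmp:::random_device_transform("MP3", oct_geometry())
  set.seed(1)
  clean <- render_fundus_images(eye$vessel_tree, oct_geometry(), "MP3", tf,
                                noise_sd = 0)
  expect_gte(dice_coefficient(segment_vessels(clean$nir), clean$nir_mask), 0.9)
  set.seed(1)
  noisy <- render_fundus_images(eye$vessel_tree, oct_geometry(), "MP3", tf)
  expect_gte(dice_coefficient(segment_vessels(noisy$nir), noisy$nir_mask), 0.75)
  # identity transform and no noise: both modalities rasterize identically
  ident <- render_fundus_images(eye$vessel_tree, oct_geometry(), "MP3",
                                similarity_transform(20, 0, c(0, 0)),
                                noise_sd = 0, nir_px = 288, device_px = 288)
  expect_identical(ident$nir_mask, ident$device_mask)
})

test_that("junction recovery on a rendered tree is mostly complete", {
  # constructed tree with well-separated branch points at steep angles
  # (random arcade trees can displace skeleton junctions at very shallow
  # bifurcations; the recovery bound is a property of clean geometry)
  segs <- list(); gt <- list()
  for (t in 1:5) {
    y0 <- 700 + 1000 * (t - 1)
    segs[[length(segs) + 1L]] <- c(400, y0, 5300, y0, 50)
    for (xb in c(1800, 3600)) {
      dy <- if (t %% 2) 1 else -1
      segs[[length(segs) + 1L]] <- c(xb, y0, xb + 260, y0 + dy * 970, 40)
      gt[[length(gt) + 1L]] <- c(xb, y0)
    }
  }
  sm <- do.call(rbind, segs)
  tree <- list(segments = data.frame(x0 = sm[, 1], y0 = sm[, 2],
                                     x1 = sm[, 3], y1 = sm[, 4],
                                     width_um = sm[, 5]),
               junctions = data.frame(x_um = sapply(gt, `[`, 1),
                                      y_um = sapply(gt, `[`, 2)))
  set.seed(2)
  fun <- render_fundus_images(tree, oct_geometry(), "MP3",
                              similarity_transform(20, 0, c(0, 0)),
                              noise_sd = 0)
  det <- detect_junctions(segment_vessels(fun$nir))
  px <- attr(fun$nir, "px_size_um")
  hit <- vapply(seq_len(nrow(tree$junctions)), function(k) {
    min(sqrt((det$x * px - tree$junctions$x_um[k])^2 +
               (det$y * px - tree$junctions$y_um[k])^2)) <= 3 * px
  }, logical(1))
  expect_gte(mean(hit), 0.8)
})

test_that("junction matching is robust to outliers and refuses noise", {
  set.seed(8)
  src <- point_set(runif(25, 0, 300), runif(25, 0, 300), "device-px")
  tf <- similarity_transform(1.4, 0.3, c(40, -25))
  dstm <- apply_transform(tf, as.matrix(src))
  # perturb 20% into outliers
  out_idx <- 1:5
  dstm[out_idx, ] <- dstm[out_idx, ] + 400
  dst <- point_set(dstm[, 1], dstm[, 2], "oct-enface-um")
  m <- match_junctions(src, dst, gate = 10)
  expect_gte(m$n_inliers, 18)
  expect_lt(m$rmse, 10)
  expect_equal(m$transform$scale, tf$scale, tolerance = 1e-6)

  # exact identity: everything matches at zero error
  ident <- match_junctions(src, src, gate = 5)
  expect_equal(ident$n_inliers, 25)
  expect_equal(ident$rmse, 0, tolerance = 1e-9)

  # two unrelated clouds: matching must fail loudly
  set.seed(9)
  a <- point_set(runif(12, 0, 100), runif(12, 0, 100), "device-px")
  b <- point_set(runif(12, 5000, 9000), runif(12, -9000, -5000), "oct-enface-um")
  expect_error(match_junctions(a, b, gate = 2, scale_range = c(0.95, 1.05)),
               class = "octmp_registration_error")
})

test_that("end-to-end registration maps stimuli within budget", {
  g <- oct_geometry()
  grid <- build_stimulus_grid()
  pts_um <- octmp:::grid_points_um(grid, g)
  errs <- c()
  for (s in c(3, 4)) {
    eye <- generate_eye(s)
    set.seed(s)
    tf <- octmp:::random_device_transform(if (s %% 2) "MP3" else "MAIA", g)
    fun <- render_fundus_images(eye$vessel_tree, g, "MP3", tf)
    reg <- register_acquisition(fun$device, fun$nir)
    expect_true(reg$quality_ok)
    expect_lte(reg$rmse_um, 35)
    pts_px <- apply_transform(invert_transform(tf), pts_um)
    errs <- c(errs, sqrt(rowSums(
      (apply_transform(reg$transform, pts_px) - pts_um)^2)))
  }
  # mean stimulus-mapping error well under half the quantification radius
  expect_lt(mean(errs), 35)
  expect_gte(mean(errs <= 35), 0.95)
})

test_that("registration JSON serialization captures the quality surface", {
  reg <- structure(list(transform = similarity_transform(2, 0.1, c(1, 2)),
                        pairs = NULL, rmse_um = 12.5, n_inliers = 9,
                        quality_ok = TRUE), class = "registration_result")
  f <- withr::local_tempfile(fileext = ".json")
  octmp:::registration_to_json(reg, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$scale, 2)
  expect_equal(back$rmse_um, 12.5)
  expect_true(back$quality_ok)
})
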