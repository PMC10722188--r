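# all scenes are generated by the simulator with known cameras, so every
# stage has an exact oracle

stereo_scene <- function(seed = 1, n_cycles = 2, noise = 0, ...) {
  sim <- sim_clean(seed = seed, n_cycles = n_cycles)
  st <- project_stereo(sim$pose, stereo_rig("45"), pixel_noise_sd = noise,
                       seed = seed, ...)
  list(sim = sim, st = st)
}

line_endpoints <- function(lines, view) {
  do.call(rbind, lapply(lines[[view]], function(a)
    rbind(a[1, 1, ], a[1, 2, ], a[2, 1, ], a[2, 2, ])))
}

test_that("LMS fundamental matrix matches the true epipolar geometry", {
  sc <- stereo_scene()
  xL <- line_endpoints(sc$st$lines, "left")
  xR <- line_endpoints(sc$st$lines, "right")
  F <- estimate_fundamental(xL, xR, seed = 2)
  expect_lt(median(attr(F, "residuals")), 1e-8)
  Ftrue <- fundamental_from_cameras(sc$st$cameras$left, sc$st$cameras$right)
  # equality up to scale/sign
  s <- sign(sum(F * Ftrue))
  expect_lt(sqrt(sum((s * F - Ftrue)^2)), 1e-7)
  expect_error(estimate_fundamental(xL[1:7, ], xR[1:7, ]), "at least 8")
})

test_that("LMS excludes a gross outlier", {
  sc <- stereo_scene()
  xL <- line_endpoints(sc$st$lines, "left")
  xR <- line_endpoints(sc$st$lines, "right")
  xRo <- xR
  xRo[5, ] <- xRo[5, ] + c(180, -130)
  F <- estimate_fundamental(xL, xRo, seed = 2)
  expect_false(attr(F, "inliers")[5])
  res <- sampson_residual(F, xL, xR)    # residuals on the clean points
  expect_lt(median(res), 1e-8)
})

test_that("canonical camera pair reproduces F and rejects bad input", {
  sc <- stereo_scene()
  Ftrue <- fundamental_from_cameras(sc$st$cameras$left, sc$st$cameras$right)
  cams <- derive_camera_pair(Ftrue)
  expect_identical(cams$P_L, cbind(diag(3), 0))
  Fre <- fundamental_from_cameras(cams$P_L, cams$P_R)
  s <- sign(sum(Fre * Ftrue))
  expect_lt(sqrt(sum((s * Fre - Ftrue)^2)), 1e-9)
  expect_error(derive_camera_pair(diag(3)), "full rank")
})

test_that("triangulation recovers known 3D points from true cameras", {
  sc <- stereo_scene()
  P <- sc$st$cameras
  X <- rbind(c(10, 2, 0.5), c(30, 1, -0.5), c(50, 3, 0))
  xl <- t(apply(X, 1, function(p) {
    h <- P$left %*% c(p, 1); h[1:2] / h[3]
  }))
  xr <- t(apply(X, 1, function(p) {
    h <- P$right %*% c(p, 1); h[1:2] / h[3]
  }))
  got <- triangulate(P$left, P$right, xl, xr)
  expect_equal(unname(got), X, tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(max(attr(got, "reprojection")), 1e-6)
  # swapped correspondences leave a large reprojection residual
  swapped <- triangulate(P$left, P$right, xl, xr[c(2, 1, 3), ])
  expect_gt(max(attr(swapped, "reprojection")), 1)
})

test_that("opposed 90-degree cameras trigger the ill-conditioning warning", {
  sim <- sim_clean(n_cycles = 2)
  st <- project_stereo(sim$pose, stereo_rig("90"))
  xl <- flatten_pose(st$poseL)[1, ]
  xr <- flatten_pose(st$poseR)[1, ]
  expect_warning(
    triangulate(st$cameras$left, st$cameras$right,
                matrix(xl, ncol = 2, byrow = TRUE),
                matrix(xr, ncol = 2, byrow = TRUE)),
    "ill-conditioned")
})

test_that("metric upgrade straightens the calibration lines", {
  sc <- stereo_scene()
  xL <- line_endpoints(sc$st$lines, "left")
  xR <- line_endpoints(sc$st$lines, "right")
  cams <- derive_camera_pair(estimate_fundamental(xL, xR, seed = 1))
  mu <- metric_upgrade(cams$P_L, cams$P_R, sc$st$lines)
  dirs <- sapply(mu$lines3d, function(a) {
    d <- a[1, 2, ] - a[1, 1, ]
    d / sqrt(sum(d^2))
  })
  expect_lt(abs(sum(dirs[, 1] * dirs[, 2])), 1e-8)
  expect_lt(abs(sum(dirs[, 1] * dirs[, 3])), 1e-8)
  expect_lt(abs(sum(dirs[, 2] * dirs[, 3])), 1e-8)
  # axis labelling: beam to x, box edges to y, entrance edges to z
  expect_gt(dirs[1, 1], 0.999)
  expect_gt(dirs[2, 2], 0.999)
  expect_gt(dirs[3, 3], 0.999)
  # recovered intrinsics match the simulated pinhole camera
  expect_equal(mu$K_L[1, 1], 1000, tolerance = 1e-4)
  expect_equal(mu$K_L[1, 3], 640, tolerance = 1e-3)
})

test_that("degenerate calibration inputs are rejected", {
  sc <- stereo_scene()
  lines <- sc$st$lines
  for (v in c("left", "right")) lines[[v]]$box_z <- lines[[v]]$box_y
  xL <- line_endpoints(sc$st$lines, "left")
  xR <- line_endpoints(sc$st$lines, "right")
  cams <- derive_camera_pair(estimate_fundamental(xL, xR, seed = 1))
  expect_error(metric_upgrade(cams$P_L, cams$P_R, lines), "degenerate")
})

test_that("physical scaling recovers the 60 cm beam and scales linearly", {
  sc <- stereo_scene()
  xL <- line_endpoints(sc$st$lines, "left")
  xR <- line_endpoints(sc$st$lines, "right")
  cams <- derive_camera_pair(estimate_fundamental(xL, xR, seed = 1))
  mu <- metric_upgrade(cams$P_L, cams$P_R, sc$st$lines)
  b <- mu$lines3d$beam
  axis <- rbind((b[1, 1, ] + b[2, 1, ]) / 2, (b[1, 2, ] + b[2, 2, ]) / 2)
  got <- apply_physical_scale(axis, physical_scale(60, 0), b)
  expect_equal(sqrt(sum((got[2, ] - got[1, ])^2)), 60, tolerance = 1e-6)
  got2 <- apply_physical_scale(axis, physical_scale(120, 0), b)
  expect_equal(unname(got2), unname(2 * got), tolerance = 1e-9,
               ignore_attr = TRUE)
  # zero incline: shear is the identity (pure similarity)
  pts <- matrix(rnorm(30), 10, 3)
  s0 <- apply_physical_scale(pts, physical_scale(60, 0), b)
  sf <- attr(s0, "scale_factor")
  expect_equal(unname(s0),
               unname(sweep(pts, 2, axis[1, ]) * sf), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("45-degree reconstruction is exact on noiseless projections", {
  sc <- stereo_scene()
  rec <- reconstruct_45(sc$st$poseL, sc$st$poseR, sc$st$lines,
                        physical_scale(60, 0))
  expect_equal(pose_dims(rec), 3L)
  expect_lt(rms_vs_truth(rec, sc$sim$pose), 0.01 * 60)
  expect_lt(rms_vs_truth(rec, sc$sim$pose), 1e-9)
})

test_that("reconstruction degrades gracefully with pixel noise", {
  sc <- stereo_scene(noise = 0.5, seed = 4)
  rec <- reconstruct_45(sc$st$poseL, sc$st$poseR, sc$st$lines,
                        physical_scale(60, 0))
  expect_lt(rms_vs_truth(rec, sc$sim$pose), 0.02 * 60)
})

test_that("reconstruction rejects mismatched frame counts", {
  sc <- stereo_scene()
  expect_error(reconstruct_45(sc$st$poseL, sc$st$poseR, sc$st$lines,
                              physical_scale(60, 0), frame_offset = 3),
               "frame counts differ")
})

test_that("merging opposed 90-degree views averages out symmetric noise", {
  sim <- sim_clean(n_cycles = 3)
  st <- project_stereo(sim$pose, stereo_rig("90"), trace_order = "image")
  merged <- merge_90(st$poseL, st$poseR, st$lines, physical_scale(60, 0),
                     mirror = "x")
  expect_equal(pose_dims(merged), 2L)
  expect_lt(rms_vs_truth(merged, pose_project_xy(sim$pose)), 0.05)

  # symmetric perturbation of the two aligned views cancels in the mean
  stp <- st
  d <- 0.9
  stp$poseL$coords[, , 1] <- stp$poseL$coords[, , 1] + d
  stp$poseR$coords[, , 1] <- stp$poseR$coords[, , 1] + d   # mirrored x: cancels
  m2 <- merge_90(stp$poseL, stp$poseR, st$lines, physical_scale(60, 0),
                 mirror = "x")
  expect_equal(unname(apply(m2$coords, 3, c)),
               unname(apply(merged$coords, 3, c)), tolerance = 1e-9)

  # merging a view with an aligned copy of itself is the identity
  lines_ll <- structure(stats::setNames(st$lines["left"][c(1, 1)],
                                        c("left", "right")),
                        class = "calibration_lines")
  m3 <- suppressWarnings(merge_90(st$poseL, st$poseL, lines_ll,
                                  physical_scale(60, 0), mirror = "none"))
  one_view <- beamgait:::align_view_2d(flatten_pose(st$poseL),
                                       st$lines$left$beam, 60)
  expect_equal(unname(flatten_pose(m3)), unname(one_view))
  expect_lt(rms_vs_truth(m3, pose_project_xy(sim$pose)), 1)

  expect_warning(merge_90(st$poseL, st$poseR, st$lines, physical_scale(60, 0),
                          mirror = "none"),
                 "anti-correlated")
})
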