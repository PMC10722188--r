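test_that("simulation is deterministic and strictly periodic without noise", {
  a <- sim_clean(seed = 9)
  b <- sim_clean(seed = 9)
  expect_identical(a$pose$coords, b$pose$coords)
  expect_identical(a$truth$tau, b$truth$tau)

  sp <- speed_of(a)
  expect_equal(sp$values[1:20, ], sp$values[21:40, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # total forward advance = n_cycles * stride
  adv <- a$pose$coords[201, , 1] - a$pose$coords[1, , 1]
  expect_equal(unname(adv), rep(10 * 5, 18), tolerance = 1e-9)
})

test_that("stance follows the 2-3-3 support pattern", {
  spec <- gait_spec()
  sim <- simulate_gait(spec)
  sp <- speed_of(sim)
  grp <- component_groups(sp$config, 3)
  ax <- component_axes(sp$config, 3)
  fx <- sp$values[1:20, grp == "feet" & ax == "x"]
  stance_count <- rowSums(abs(fx) < 1e-9)
  # sub-phases: 2 stance feet (frames 1-6), then 3, then 3
  expect_equal(unname(stance_count), c(rep(2, 6), rep(3, 7), rep(3, 7)))
  # mirrored pattern swaps left and right feet
  simM <- simulate_gait(gait_spec(mirror_lateral = TRUE))
  fxm <- compute_speed(simM$pose)$values[1:20, grp == "feet" & ax == "x"]
  expect_equal(unname(fxm[, c(2, 1, 4, 3)]), unname(fx))
  expect_error(gait_spec(support_pattern = list(c("FL", "FL"), "FR", "RL")),
               "two simultaneous swing sets|exactly once")
  expect_error(gait_spec(support_pattern = list(c("FL", "RR"), "FR", "FR")),
               "two simultaneous swing sets|exactly once")
})

test_that("anomaly injection alters only what it claims to", {
  sim <- sim_clean(seed = 2)
  # magnitude 0 is the identity
  same <- inject_anomaly(sim$pose, sim$truth,
                         list(cycle = 4, type = "slip", magnitude = 0))
  expect_equal(same$pose$coords, sim$pose$coords)
  # stop inserts frames
  stp <- inject_anomaly(sim$pose, sim$truth,
                        list(cycle = 4, type = "stop", magnitude = 7))
  expect_equal(n_frames(stp$pose), n_frames(sim$pose) + 7L)
  expect_equal(stp$truth$t[4], sim$truth$t[4] + 7L)
  # slip touches one foot only, and positions recover within the cycle
  slp <- inject_anomaly(sim$pose, sim$truth,
                        list(cycle = 4, type = "slip", magnitude = 1.5,
                             foot = "FR"))
  d <- abs(flatten_pose(slp$pose) - flatten_pose(sim$pose))
  touched <- colnames(d)[colSums(d) > 1e-12]
  expect_true(all(grepl("^foot_FR", touched)))
  after <- sim$truth$t[5] + 1L
  expect_equal(slp$pose$coords[after:201, , ], sim$pose$coords[after:201, , ],
               tolerance = 1e-9)
  expect_true(any(slp$pose$coords[, "foot_FR", "y"] < -0.5))
  # phase shift preserves cycle-boundary postures
  ps <- inject_anomaly(sim$pose, sim$truth,
                       list(cycle = 4, type = "phase_shift", magnitude = 5,
                            foot = "RL"))
  bounds <- sim$truth$t + 1L
  expect_equal(ps$pose$coords[bounds, , ], sim$pose$coords[bounds, , ],
               tolerance = 1e-9)
  expect_error(inject_anomaly(sim$pose, sim$truth,
                              list(cycle = 4, type = "wobble")),
               "unknown anomaly")
  expect_error(inject_anomaly(sim$pose, sim$truth,
                              list(cycle = 40, type = "stop", magnitude = 2)),
               "out of range")
})

test_that("stereo projection is deterministic, noise grows residuals", {
  sim <- sim_clean(n_cycles = 2)
  a <- project_stereo(sim$pose, stereo_rig("45"), pixel_noise_sd = 0.5, seed = 5)
  b <- project_stereo(sim$pose, stereo_rig("45"), pixel_noise_sd = 0.5, seed = 5)
  expect_identical(a$poseL$coords, b$poseL$coords)

  clean <- project_stereo(sim$pose, stereo_rig("45"))
  res_at <- function(st) {
    rec <- reconstruct_45(st$poseL, st$poseR, st$lines, physical_scale(60, 0))
    mean(attr(rec, "reprojection"))
  }
  r0 <- res_at(clean)
  r1 <- res_at(project_stereo(sim$pose, stereo_rig("45"),
                              pixel_noise_sd = 0.5, seed = 5))
  r2 <- res_at(project_stereo(sim$pose, stereo_rig("45"),
                              pixel_noise_sd = 1.0, seed = 5))
  expect_lt(r0, r1)
  expect_lt(r1, r2)
})

test_that("90-degree projections are mirror-consistent in image x", {
  sim <- sim_clean(n_cycles = 2)
  st <- project_stereo(sim$pose, stereo_rig("90"))
  # a step forward along the beam moves the views' image x oppositely
  dxL <- diff(st$poseL$coords[, "nose_tip", "x"])
  dxR <- diff(st$poseR$coords[, "nose_tip", "x"])
  expect_lt(cor(dxL, dxR), -0.99)
})

test_that("fixtures round-trip through the readers", {
  sim <- sim_clean(n_cycles = 2)
  st <- project_stereo(sim$pose, stereo_rig("45"))
  dir <- withr::local_tempdir()
  paths <- write_fixture(dir, sim, st)
  rc <- read_run_config(paths$config)
  expect_equal(n_points(rc$config), 18L)
  expect_equal(rc$beam_length_cm, 60)
  back <- read_tracking_table(paths$trackL, rc$config, rc$fps)
  expect_identical(back$coords, st$poseL$coords)
  lines <- read_calibration_lines(paths$lines)
  expect_equal(lines, st$lines, ignore_attr = TRUE)
  truth <- jsonlite::fromJSON(paths$truth)
  expect_equal(truth$cycle_start, sim$truth$t)
  expect_equal(truth$cycle_period, sim$truth$tau)
})
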