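test_that("template selection copies the interval and validates bounds", {
  sp <- speed_of(sim_clean(n_cycles = 5))
  tm <- select_template(sp, 10, 30)
  expect_equal(nrow(tm$values), 20L)
  expect_identical(tm$values, sp$values[11:30, ])
  expect_error(select_template(sp, 10, 12), "at least 4 frames")
  expect_error(select_template(sp, -1, 20), "at least 4 frames|within")
})

test_that("template suggestion finds the simulated stride period", {
  sp <- speed_of(sim_clean(seed = 3))
  tw <- suggest_template(sp)
  tau0 <- tw[2] - tw[1]
  expect_gte(tau0, 19)
  expect_lte(tau0, 21)
  # white noise has no periodicity
  cfg <- default_mouse_config()
  set.seed(1)
  noise <- speed_series(matrix(rnorm(120 * 54), 120, 54), cfg, 30, 3L)
  expect_error(suggest_template(noise), "no periodicity")
  flat <- speed_series(matrix(1, 120, 54), cfg, 30, 3L)
  expect_error(suggest_template(flat), "no periodicity")
})

test_that("strictly periodic input is segmented and recovered exactly", {
  sim <- sim_clean()
  sp <- speed_of(sim)
  seg <- segment_cycles(sp, select_template(sp, 0, 20))
  expect_equal(seg$tau, rep(20L, 10), ignore_attr = TRUE)
  expect_equal(seg$t, cumsum(c(0, rep(20, 9))), ignore_attr = TRUE)
  expect_equal(seg$score, rep(1, 10), tolerance = 1e-12)
  swc <- compute_swc(sp, seg)
  expect_equal(swc$values, sim$truth$waveform, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(swc$weight, 10, tolerance = 1e-12)
})

test_that("segmentation is contiguous and bounded (Eq. 5 and period bounds)", {
  for (s in 1:5) {
    sim <- sim_clean(seed = s, period_jitter = 2, noise_sd = 0.05)
    sp <- speed_of(sim)
    seg <- segment_cycles(sp, select_template(sp, 0, sim$truth$tau[1]))
    expect_equal(seg$t, cumsum(c(0, seg$tau[-length(seg$tau)])),
                 ignore_attr = TRUE)
    expect_true(all(seg$tau >= ceiling(seg$tau0 / 2)))
    expect_true(all(seg$tau <= 2 * seg$tau0))
    # union of cycles plus discarded tail covers the culled domain
    expect_lte(max(seg$t + seg$tau), nrow(sp$values))
    expect_gt(max(seg$t + seg$tau),
              nrow(sp$values) - ceiling(seg$tau0 / 2))
  }
})

test_that("jittered periods are recovered by the exhaustive (dp) mode", {
  hit <- total <- 0
  for (s in 1:5) {
    sim <- sim_clean(seed = s, period_jitter = 2, noise_sd = 0.075)
    sp <- speed_of(sim)
    seg <- segment_cycles(sp, select_template(sp, 0, sim$truth$tau[1]),
                          method = "dp")
    n <- min(length(seg$tau), length(sim$truth$tau))
    hit <- hit + sum(abs(seg$tau[1:n] - sim$truth$tau[1:n]) <= 1)
    total <- total + n
  }
  expect_gte(hit / total, 0.9)
})

test_that("degenerate segmentation inputs error", {
  sp <- speed_of(sim_clean(n_cycles = 3))
  zero <- select_template(sp, 0, 20)
  zero$values[] <- 0
  expect_error(segment_cycles(sp, zero), "zero-norm template")
  short <- speed_series(sp$values[1:5, ], sp$config, 30, 3L)
  expect_error(segment_cycles(short, select_template(sp, 0, 20)),
               "shorter than the minimal period")
})

test_that("the SWC is a score-weighted average of rescaled cycles", {
  cfg <- default_mouse_config()
  # two hand-built cycles with known weights
  base <- matrix(0, 20, 36)
  base[, 1] <- sin(2 * pi * (1:20) / 20)
  v <- rbind(base, 2 * base)             # second cycle doubled -> score 2
  sp <- speed_series(v, cfg, 30, 2L)
  tm <- select_template(sp, 0, 20)
  seg <- segment_cycles(sp, tm)
  expect_equal(seg$score, c(1, 2), tolerance = 1e-12)
  swc <- compute_swc(sp, seg)
  # weighted mean: (1*1 + 2*2) / 3 = 5/3 times the base waveform
  expect_equal(swc$values[, 1], base[, 1] * 5 / 3, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(swc$weight, 3, tolerance = 1e-12)
  # the average lies within the per-sample envelope of the cycles
  env_lo <- pmin(base, 2 * base); env_hi <- pmax(base, 2 * base)
  expect_true(all(swc$values >= env_lo - 1e-12))
  expect_true(all(swc$values <= env_hi + 1e-12))

  neg <- speed_series(rbind(base, -base), cfg, 30, 2L)
  segn <- segment_cycles(neg, select_template(neg, 0, 20))
  expect_warning(compute_swc(neg, segn), "non-positive")
})

test_that("refinement is a running weighted average", {
  sims <- lapply(1:3, function(s) sim_clean(seed = s, n_cycles = 6))
  sps <- lapply(sims, speed_of)
  tmpl <- select_template(sps[[1]], 0, 20)
  swc <- compute_swc(sps[[1]], segment_cycles(sps[[1]], tmpl))
  w1 <- swc$weight
  # identical video: values unchanged, weight doubles
  again <- refine_swc(swc, sps[[1]])
  expect_equal(again$values, swc$values, tolerance = 1e-9)
  expect_equal(again$weight, 2 * w1, tolerance = 1e-9)

  # sequential refinement equals batch extraction over the concatenation
  seqn <- refine_swc(refine_swc(swc, sps[[2]]), sps[[3]])
  big <- speed_series(do.call(rbind, lapply(sps, `[[`, "values")),
                      sps[[1]]$config, 30, 3L)
  batch <- compute_swc(big, segment_cycles(big, tmpl))
  expect_equal(seqn$values, batch$values, tolerance = 1e-6)
  expect_equal(seqn$weight, batch$weight, tolerance = 1e-6)
})
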